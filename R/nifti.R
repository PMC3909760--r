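#' Write a 2D/3D image as NIfTI-1
#'
#' Minimal single-file (.nii) NIfTI-1 writer: float64 data, little-endian,
#' pixel spacing in `pixdim`. Covers exactly what the pipeline needs to
#' exchange maps and masks; it is not a general NIfTI implementation.
#'
#' @param img matrix or 3D array; `asl_image` spacing attributes are used
#'   when present.
#' @param path output path ending in `.nii`.
#' @param pixel_spacing_mm,slice_thickness_mm spacing overrides.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path,
                        pixel_spacing_mm = pixel_spacing(img),
                        slice_thickness_mm = attr(img, "slice_thickness_mm")) {
  dims <- dim(img)
  if (is.null(dims) || !(length(dims) %in% c(2, 3)))
    stop("only 2D and 3D images are supported")
  if (is.na(pixel_spacing_mm)) pixel_spacing_mm <- 1
  if (is.null(slice_thickness_mm) || is.na(slice_thickness_mm))
    slice_thickness_mm <- 1
  con <- file(path, "wb")
  on.exit(close(con))
  wI <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wF <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wI(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info
  dim8 <- c(length(dims), dims, rep(1L, 7 - length(dims)))
  wI(dim8, 2)                                   # dim[8]
  writeBin(raw(14), con)                        # intent_p1..intent_code
  wI(64L, 2)                                    # datatype = float64
  wI(64L, 2)                                    # bitpix
  wI(0L, 2)                                     # slice_start
  wF(c(1, pixel_spacing_mm, pixel_spacing_mm, slice_thickness_mm,
       1, 1, 1, 1))                             # pixdim[8]
  wF(352)                                       # vox_offset
  wF(1); wF(0)                                  # scl_slope, scl_inter
  writeBin(raw(224), con)                       # slice_end .. srow/intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # extension flag
  writeBin(as.numeric(img), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 image written by [write_nifti()]
#'
#' Round-trips array values bit-exactly and spacing to float32 precision.
#' Rejects files whose header is not a little-endian float64 NIfTI-1.
#'
#' @param path `.nii` file path.
#' @return matrix (2D) or array (3D); 2D results are `asl_image`s carrying
#'   the spacing.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, integer(), 1, size = 4, endian = "little")
  if (!identical(hdr_size, 348L))
    stop("not a little-endian NIfTI-1 file (bad sizeof_hdr): ", path)
  readBin(con, raw(), 36)
  dim8 <- readBin(con, integer(), 8, size = 2, endian = "little")
  ndim <- dim8[1]
  if (!(ndim %in% c(2L, 3L))) stop("unsupported dimensionality: ", ndim)
  dims <- dim8[2:(1 + ndim)]
  readBin(con, raw(), 14)
  datatype <- readBin(con, integer(), 1, size = 2, endian = "little")
  if (datatype != 64L) stop("unsupported datatype (need float64): ", datatype)
  readBin(con, integer(), 2, size = 2, endian = "little")
  pixdim <- readBin(con, numeric(), 8, size = 4, endian = "little")
  vox_offset <- readBin(con, numeric(), 1, size = 4, endian = "little")
  seek(con, vox_offset)
  vals <- readBin(con, numeric(), prod(dims), size = 8, endian = "little")
  if (length(vals) != prod(dims)) stop("truncated NIfTI data in ", path)
  if (ndim == 2L) {
    asl_image(matrix(vals, dims[1], dims[2]), pixdim[2], pixdim[4])
  } else {
    array(vals, dim = dims)
  }
}

#' Write a phantom dataset to disk
#'
#' Dumps a simulated series and its ground truth as NIfTI volumes (selective
#' and non-selective stacks, M0, T1 map, label map, perfusion truth) plus a
#' JSON sidecar recording the generating spec and seed.
#'
#' @param truth a [phantom_truth()].
#' @param series the matching [simulate_asl_series()] output.
#' @param outdir output directory, created if missing.
#' @return named vector of written paths, invisibly.
#' @export
write_phantom_dataset <- function(truth, series, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stack <- function(lst) array(unlist(lst), dim = c(dim(lst[[1]]),
                                                    length(lst)))
  paths <- c(
    selective = file.path(outdir, "selective.nii"),
    nonselective = file.path(outdir, "nonselective.nii"),
    m0 = file.path(outdir, "m0.nii"),
    t1 = file.path(outdir, "t1.nii"),
    labels = file.path(outdir, "labels.nii"),
    perfusion_truth = file.path(outdir, "perfusion_truth.nii"))
  sp <- truth$spec$pixel_spacing_mm
  th <- truth$spec$slice_thickness_mm
  write_nifti(stack(series$selective), paths["selective"], sp, th)
  write_nifti(stack(series$nonselective), paths["nonselective"], sp, th)
  write_nifti(series$m0_image, paths["m0"])
  write_nifti(truth$t1_map_truth, paths["t1"])
  write_nifti(truth$label_map, paths["labels"])
  write_nifti(truth$perfusion_map_truth, paths["perfusion_truth"])
  sidecar <- unclass(truth$spec)
  sidecar$motion_shifts_px <- if (is.null(sidecar$motion_shifts_px)) NULL
    else as.data.frame(sidecar$motion_shifts_px)
  jsonlite::write_json(sidecar, file.path(outdir, "phantom_spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
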