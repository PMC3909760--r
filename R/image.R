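#' Create a 2D image with physical spacing metadata
#'
#' Images throughout the package are plain numeric matrices carrying the
#' in-plane pixel spacing (mm) and, where relevant, the slice thickness (mm)
#' as attributes. Index convention is 0-based and half-open: the physical
#' coordinate of pixel centre `(i, j)` (0-based) is
#' `((i + 0.5) * spacing, (j + 0.5) * spacing)`.
#'
#' @param data numeric matrix of pixel intensities.
#' @param pixel_spacing_mm in-plane pixel size, mm (isotropic).
#' @param slice_thickness_mm through-plane thickness, mm (optional).
#' @return a matrix of class `asl_image` with spacing attributes.
#' @export
asl_image <- function(data, pixel_spacing_mm, slice_thickness_mm = NA_real_) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(pixel_spacing_mm) || length(pixel_spacing_mm) != 1 ||
      pixel_spacing_mm <= 0) {
    stop("pixel_spacing_mm must be a single positive number")
  }
  structure(data,
            pixel_spacing_mm = as.numeric(pixel_spacing_mm),
            slice_thickness_mm = as.numeric(slice_thickness_mm),
            class = c("asl_image", "matrix", "array"))
}

#' @export
print.asl_image <- function(x, ...) {
  cat(sprintf("<asl_image> %d x %d px, %.4g mm/px, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), attr(x, "pixel_spacing_mm"),
              min(x), max(x)))
  invisible(x)
}

#' Pixel spacing of an image in mm
#' @param img an `asl_image` or plain matrix.
#' @return spacing in mm, or `NA` if the matrix carries none.
#' @export
pixel_spacing <- function(img) {
  sp <- attr(img, "pixel_spacing_mm")
  if (is.null(sp)) NA_real_ else sp
}

# strip class/attrs, keep dims
as_plain_matrix <- function(img) {
  matrix(as.numeric(img), nrow = nrow(img), ncol = ncol(img))
}

#' Translate an image by a pixel shift
#'
#' Rigid in-plane translation. Integer shifts move pixels exactly with
#' constant fill at the exposed border; non-integer shifts use bilinear
#' interpolation. `shift = c(dr, dc)` moves content down `dr` rows and right
#' `dc` columns.
#'
#' @param img matrix.
#' @param shift numeric length-2, (rows, cols) in pixels.
#' @param fill value for pixels translated in from outside the grid.
#' @return shifted matrix with `img`'s attributes preserved.
#' @export
shift_image <- function(img, shift, fill = 0) {
  stopifnot(length(shift) == 2, all(is.finite(shift)))
  out <- img
  if (all(shift == round(shift))) {
    out[] <- shift_integer(as_plain_matrix(img), as.integer(round(shift)), fill)
  } else {
    out[] <- shift_bilinear(as_plain_matrix(img), shift, fill)
  }
  out
}

shift_integer <- function(m, s, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - s[1]
  src_c <- seq_len(nc) - s[2]
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

shift_bilinear <- function(m, s, fill) {
  nr <- nrow(m); nc <- ncol(m)
  r <- matrix(seq_len(nr), nr, nc) - s[1]
  c <- matrix(rep(seq_len(nc), each = nr), nr, nc) - s[2]
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  get <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- matrix(fill, nr, nc)
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  get(r0, c0) * (1 - fr) * (1 - fc) +
    get(r0 + 1, c0) * fr * (1 - fc) +
    get(r0, c0 + 1) * (1 - fr) * fc +
    get(r0 + 1, c0 + 1) * fr * fc
}
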