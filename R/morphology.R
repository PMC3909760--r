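#' Kidney dimensions from localiser measurements
#'
#' @param length_cm,width_cm,depth_cm the three principal measurements, cm.
#' @return list of class `kidney_dimensions`.
#' @export
kidney_dimensions <- function(length_cm, width_cm, depth_cm) {
  d <- c(length_cm, width_cm, depth_cm)
  if (length(d) != 3 || any(!is.finite(d)) || any(d <= 0))
    stop("all three dimensions must be positive and finite")
  structure(list(length_cm = length_cm, width_cm = width_cm,
                 depth_cm = depth_cm),
            class = "kidney_dimensions")
}

SPECIFIC_GRAVITY_G_PER_ML <- 1.05

volume_result <- function(volume_cm3, method) {
  structure(list(volume_cm3 = volume_cm3, method = method,
                 mass_g = volume_cm3 * SPECIFIC_GRAVITY_G_PER_ML),
            class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("<volume_result> %s: %.2f cm^3, mass %.2f g\n",
              x$method, x$volume_cm3, x$mass_g))
  invisible(x)
}

#' Kidney volume by the ellipsoid formula
#'
#' `V = length x width x depth x pi/6`, algebraically identical to
#' `4/3 pi (L/2)(W/2)(D/2)`. Mass follows at the specific gravity of renal
#' tissue, 1.05 g/ml.
#'
#' @param dims a [kidney_dimensions()].
#' @return a `volume_result` (volume in cm^3, mass in g).
#' @export
ellipsoid_volume <- function(dims) {
  stopifnot(inherits(dims, "kidney_dimensions"))
  v <- dims$length_cm * dims$width_cm * dims$depth_cm * pi / 6
  volume_result(v, "ellipsoid")
}

#' Kidney volume by voxel counting
#'
#' Total in-region pixel count across a multi-slice mask stack, times
#' in-plane pixel area, times slice thickness. Inputs in mm; output in cm^3.
#'
#' @param mask_stack list of binary matrices (or a single matrix), one per
#'   slice; nonzero marks kidney.
#' @param pixel_spacing_mm in-plane pixel size, mm.
#' @param slice_thickness_mm slice thickness, mm.
#' @return a `volume_result`.
#' @export
voxel_count_volume <- function(mask_stack, pixel_spacing_mm,
                               slice_thickness_mm) {
  if (is.matrix(mask_stack)) mask_stack <- list(mask_stack)
  stopifnot(pixel_spacing_mm > 0, slice_thickness_mm > 0)
  n_px <- sum(vapply(mask_stack, function(m) sum(m != 0), numeric(1)))
  if (n_px == 0) warning("empty mask stack: volume is zero")
  v_mm3 <- n_px * pixel_spacing_mm^2 * slice_thickness_mm
  volume_result(v_mm3 / 1000, "voxel_count")
}

#' Absolute perfusion of one kidney
#'
#' Converts tissue perfusion (per 100 g) to whole-organ flow:
#' `absolute = perfusion x mass / 100` in ml/min. Computed per kidney; cohort
#' summaries must average these per-kidney products, not multiply means.
#'
#' @param perfusion_ml_min_100g mean kidney perfusion, ml/min/100 g.
#' @param mass_g kidney mass, g.
#' @return absolute perfusion, ml/min.
#' @export
absolute_perfusion <- function(perfusion_ml_min_100g, mass_g) {
  stopifnot(all(perfusion_ml_min_100g >= 0 | is.na(perfusion_ml_min_100g)),
            all(mass_g >= 0 | is.na(mass_g)))
  perfusion_ml_min_100g * mass_g / 100
}

#' Total perfusion per participant
#'
#' Sum of the two kidneys' absolute perfusion. A missing kidney propagates
#' as `NA`, never as zero.
#'
#' @param left_abs,right_abs absolute perfusion of each kidney, ml/min.
#' @return total, ml/min.
#' @export
total_participant_perfusion <- function(left_abs, right_abs) {
  left_abs + right_abs
}
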