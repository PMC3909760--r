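#' Specify a digital kidney phantom
#'
#' The phantom is a 2D sagittal slice through the midpoint of an ellipsoidal
#' kidney: an outer cortical shell around a medullary core, on a zero
#' background. It is the ground-truth world against which every stage of the
#' quantification chain is validated by parameter recovery.
#'
#' Defaults mirror a single-slice FAIR acquisition at 3 T: a 256 x 256 grid
#' over a 380 mm field of view (1.484 mm/px), 10 mm slice, five label/control
#' pairs per acquisition repeated five times, inversion time 900 ms. Regional
#' defaults (cortical perfusion 320, medullary 120 ml/min/100 g; cortical T1
#' 1400, medullary 1650 ms) sit at the magnitudes reported for healthy human
#' kidney at 3 T.
#'
#' @param grid_shape integer length-2, pixels per axis.
#' @param pixel_spacing_mm in-plane pixel size (mm).
#' @param slice_thickness_mm slice thickness (mm).
#' @param kidney_semi_axes_mm length-3 semi-axes (L/2, W/2, D/2) in mm.
#' @param cortex_thickness_mm thickness of the cortical shell (mm); must be
#'   smaller than the smallest semi-axis.
#' @param perfusion_truth named vector, regional perfusion in ml/min/100 g.
#' @param t1_truth_ms named vector, regional T1 in ms.
#' @param m0_value equilibrium magnetisation inside the kidney (signal units).
#' @param n_pairs_per_acq selective/non-selective pairs per acquisition.
#' @param n_acquisitions number of repeated acquisitions.
#' @param noise_sd sd of additive Gaussian noise per image (signal units).
#' @param motion_shifts_px `n_acquisitions` x 2 matrix of per-acquisition
#'   (row, col) pixel shifts applied to every image of that acquisition;
#'   `NULL` means no motion.
#' @param vessel_fraction fraction of in-kidney pixels replaced by
#'   vessel-like extreme-intensity outliers.
#' @param seed integer RNG seed; drives every stochastic feature so that the
#'   same spec always yields bit-identical data.
#' @return a validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(256L, 256L),
                         pixel_spacing_mm = 380 / 256,
                         slice_thickness_mm = 10,
                         kidney_semi_axes_mm = c(55, 25, 20),
                         cortex_thickness_mm = 8,
                         perfusion_truth = c(cortex = 320, medulla = 120),
                         t1_truth_ms = c(cortex = 1400, medulla = 1650),
                         m0_value = 1000,
                         n_pairs_per_acq = 5L,
                         n_acquisitions = 5L,
                         noise_sd = 0,
                         motion_shifts_px = NULL,
                         vessel_fraction = 0,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               pixel_spacing_mm = pixel_spacing_mm,
               slice_thickness_mm = slice_thickness_mm,
               kidney_semi_axes_mm = kidney_semi_axes_mm,
               cortex_thickness_mm = cortex_thickness_mm,
               perfusion_truth = perfusion_truth,
               t1_truth_ms = t1_truth_ms,
               m0_value = m0_value,
               n_pairs_per_acq = as.integer(n_pairs_per_acq),
               n_acquisitions = as.integer(n_acquisitions),
               noise_sd = noise_sd,
               motion_shifts_px = motion_shifts_px,
               vessel_fraction = vessel_fraction,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  class(spec) <- "phantom_spec"
  spec
}

validate_phantom_spec <- function(s) {
  stopifnot(length(s$grid_shape) == 2, all(s$grid_shape >= 8))
  if (s$pixel_spacing_mm <= 0 || s$slice_thickness_mm <= 0)
    stop("pixel spacing and slice thickness must be positive")
  if (length(s$kidney_semi_axes_mm) != 3 || any(s$kidney_semi_axes_mm <= 0))
    stop("kidney_semi_axes_mm must be three positive lengths")
  if (s$cortex_thickness_mm <= 0)
    stop("cortex_thickness_mm must be > 0")
  if (s$cortex_thickness_mm >= min(s$kidney_semi_axes_mm))
    stop("cortex_thickness_mm must be smaller than the smallest semi-axis")
  need <- c("cortex", "medulla")
  if (!all(need %in% names(s$perfusion_truth)) ||
      !all(need %in% names(s$t1_truth_ms)))
    stop("perfusion_truth and t1_truth_ms need 'cortex' and 'medulla' entries")
  if (any(s$perfusion_truth < 0)) stop("perfusion_truth must be non-negative")
  if (any(s$t1_truth_ms <= 0) || s$m0_value <= 0)
    stop("T1 and M0 must be strictly positive")
  if (s$n_pairs_per_acq < 1 || s$n_acquisitions < 1)
    stop("n_pairs_per_acq and n_acquisitions must be >= 1")
  if (s$noise_sd < 0) stop("noise_sd must be >= 0")
  if (s$vessel_fraction < 0 || s$vessel_fraction > 0.5)
    stop("vessel_fraction must be in [0, 0.5]")
  if (!is.null(s$motion_shifts_px)) {
    m <- s$motion_shifts_px
    if (!is.matrix(m) || nrow(m) != s$n_acquisitions || ncol(m) != 2)
      stop("motion_shifts_px must be an n_acquisitions x 2 matrix")
  }
  # kidney (slice ellipse, axes 1-2) must fit inside the field of view
  fov_mm <- s$grid_shape * s$pixel_spacing_mm
  if (2 * s$kidney_semi_axes_mm[1] >= fov_mm[1] ||
      2 * s$kidney_semi_axes_mm[2] >= fov_mm[2])
    stop("kidney larger than the field of view; enlarge the grid or shrink it")
  invisible(s)
}

# Labels used across the package
LBL_BACKGROUND <- 0L
LBL_CORTEX <- 1L
LBL_MEDULLA <- 2L
LBL_VESSEL <- 3L

#' Generate the ground-truth label map of a phantom slice
#'
#' The slice is the mid-plane of the ellipsoid along its first two axes: an
#' ellipse with semi-axes (L/2, W/2) centred in the grid. Pixels are
#' classified by their centre: the outer `cortex_thickness_mm` shell is
#' cortex (1), the interior medulla (2), outside is background (0).
#' Deterministic for a fixed spec; vessel outliers (3) are a property of the
#' simulated series, not of the anatomy, and are added by
#' [phantom_truth()] when `vessel_fraction > 0`.
#'
#' @param spec a [phantom_spec()].
#' @return integer label matrix of class `asl_image`.
#' @export
generate_label_map <- function(spec) {
  validate_phantom_spec(spec)
  a <- spec$kidney_semi_axes_mm[1]
  b <- spec$kidney_semi_axes_mm[2]
  t <- spec$cortex_thickness_mm
  sp <- spec$pixel_spacing_mm
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  cx <- nr * sp / 2; cy <- nc * sp / 2
  x <- (seq_len(nr) - 0.5) * sp - cx
  y <- (seq_len(nc) - 0.5) * sp - cy
  X <- matrix(x, nr, nc)
  Y <- matrix(rep(y, each = nr), nr, nc)
  outer_in <- (X / a)^2 + (Y / b)^2 <= 1
  inner_in <- (X / (a - t))^2 + (Y / (b - t))^2 <= 1
  lab <- matrix(LBL_BACKGROUND, nr, nc)
  lab[outer_in] <- LBL_CORTEX
  lab[inner_in] <- LBL_MEDULLA
  asl_image(lab, sp, spec$slice_thickness_mm)
}

#' Build the full ground truth for a phantom
#'
#' Expands a [phantom_spec()] into per-pixel truth maps: the label map
#' (with `vessel_fraction` in-kidney pixels re-labelled as vessel outliers,
#' drawn reproducibly from `spec$seed`), the perfusion, T1 and M0 truth maps,
#' and the per-acquisition motion shifts. `region_map` keeps the pre-vessel
#' cortex/medulla anatomy so recovery tests can compare against outlier-free
#' truth; perfusion/T1 truth at vessel pixels remain the underlying tissue
#' values.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `phantom_truth` with elements `label_map`,
#'   `region_map`, `perfusion_map_truth`, `t1_map_truth`, `m0_map_truth`,
#'   `motion_shifts_px`, `spec`.
#' @export
phantom_truth <- function(spec) {
  region <- generate_label_map(spec)
  lab <- region
  inside <- which(region > 0)
  if (spec$vessel_fraction > 0) {
    n_vessel <- round(spec$vessel_fraction * length(inside))
    if (n_vessel > 0) {
      rng <- local_rng(spec$seed, "vessel-pixels")
      pick <- sample_rng(rng, inside, n_vessel)
      lab[pick] <- LBL_VESSEL
    }
  }
  fill_by_region <- function(vals) {
    m <- matrix(0, nrow(region), ncol(region))
    m[region == LBL_CORTEX] <- vals[["cortex"]]
    m[region == LBL_MEDULLA] <- vals[["medulla"]]
    asl_image(m, spec$pixel_spacing_mm, spec$slice_thickness_mm)
  }
  t1 <- fill_by_region(spec$t1_truth_ms)
  # T1 outside the kidney is irrelevant to quantification but must be
  # positive for a well-formed map
  t1[region == LBL_BACKGROUND] <- mean(spec$t1_truth_ms)
  m0 <- fill_by_region(c(cortex = spec$m0_value, medulla = spec$m0_value))
  shifts <- spec$motion_shifts_px
  if (is.null(shifts)) shifts <- matrix(0, spec$n_acquisitions, 2)
  structure(list(label_map = lab,
                 region_map = region,
                 perfusion_map_truth = fill_by_region(spec$perfusion_truth),
                 t1_map_truth = t1,
                 m0_map_truth = m0,
                 motion_shifts_px = shifts,
                 spec = spec),
            class = "phantom_truth")
}

# Isolated, stream-named RNG so independent stochastic features never share
# draws: seed is combined with a stream label, keeping everything below 2^31.
local_rng <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) * 1009L + as.integer(h %% 100003L)) %% 2147483647L
}

sample_rng <- function(rng_seed, x, size) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(rng_seed)
  sample(x, size)
}

rnorm_rng <- function(rng_seed, n, sd) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(rng_seed)
  stats::rnorm(n, mean = 0, sd = sd)
}

#' Simulate a FAIR ASL series from phantom ground truth
#'
#' Forward model, the exact algebraic inverse of the quantification chain:
#' per pixel the perfusion-weighted difference is
#' \deqn{\Delta M = f \cdot \frac{2\,TI}{\lambda} \cdot M_0 \cdot e^{-TI/T_1}}
#' with `f` in ml/g/s (regional truth in ml/min/100 g divided by 6000). The
#' non-selective (control) image is the M0-proportional baseline; the
#' selective (label) image is control + \eqn{\Delta M}, so that
#' selective − non-selective yields positive perfusion. Gaussian noise of sd
#' `noise_sd` is added independently to every image; each acquisition's rigid
#' shift is applied to both members of all of its pairs; vessel-outlier
#' pixels are overwritten in the selective images with intensities at
#' ±2 × the maximum in-kidney intensity, far outside the physiological range.
#'
#' @param truth a [phantom_truth()].
#' @param params a [quant_params()] supplying TI and lambda.
#' @param seed integer seed for noise and outlier signs (defaults to the
#'   spec's seed).
#' @return an [asl_series()] with attribute `dm_truth`, the noiseless
#'   motion-free \eqn{\Delta M} map.
#' @export
simulate_asl_series <- function(truth, params = quant_params(),
                                seed = truth$spec$seed) {
  stopifnot(inherits(truth, "phantom_truth"))
  spec <- truth$spec
  ti_s <- params$ti_ms / 1000
  lambda <- params$lambda_ml_per_g
  f_gs <- as_plain_matrix(truth$perfusion_map_truth) / 6000  # ml/g/s
  m0 <- as_plain_matrix(truth$m0_map_truth)
  t1_s <- as_plain_matrix(truth$t1_map_truth) / 1000
  dm_truth <- f_gs * (2 * ti_s / lambda) * m0 * exp(-ti_s / t1_s)
  baseline <- m0  # control image modelled as c * M0 with c = 1

  kid <- truth$label_map > 0
  vessel <- which(truth$label_map == LBL_VESSEL)
  n_img <- spec$n_acquisitions * spec$n_pairs_per_acq
  sel <- vector("list", n_img)
  nonsel <- vector("list", n_img)
  acq_idx <- integer(n_img)

  vessel_sign <- NULL
  if (length(vessel) > 0) {
    vessel_sign <- sign(rnorm_rng(local_rng(seed, "vessel-sign"),
                                  length(vessel), 1))
    vessel_sign[vessel_sign == 0] <- 1
  }
  max_kid <- max(abs(baseline[kid] + dm_truth[kid]))

  img_i <- 0L
  for (a in seq_len(spec$n_acquisitions)) {
    shift <- truth$motion_shifts_px[a, ]
    for (p in seq_len(spec$n_pairs_per_acq)) {
      img_i <- img_i + 1L
      s_img <- baseline + dm_truth
      n_img_mat <- baseline
      if (length(vessel) > 0) {
        s_img[vessel] <- vessel_sign * 2 * max_kid
      }
      if (any(shift != 0)) {
        s_img <- shift_bilinear_or_int(s_img, shift)
        n_img_mat <- shift_bilinear_or_int(n_img_mat, shift)
      }
      if (spec$noise_sd > 0) {
        s_img <- s_img + matrix(
          rnorm_rng(local_rng(seed, paste0("noise-s-", img_i)),
                    length(s_img), spec$noise_sd), nrow(s_img))
        n_img_mat <- n_img_mat + matrix(
          rnorm_rng(local_rng(seed, paste0("noise-n-", img_i)),
                    length(n_img_mat), spec$noise_sd), nrow(n_img_mat))
      }
      sel[[img_i]] <- s_img
      nonsel[[img_i]] <- n_img_mat
      acq_idx[img_i] <- a
    }
  }
  series <- asl_series(selective = sel, nonselective = nonsel,
                       m0_image = asl_image(m0, spec$pixel_spacing_mm,
                                            spec$slice_thickness_mm),
                       pixel_spacing_mm = spec$pixel_spacing_mm,
                       acquisition_index = acq_idx)
  attr(series, "dm_truth") <- dm_truth
  series
}

shift_bilinear_or_int <- function(m, shift) {
  if (all(shift == round(shift))) shift_integer(m, as.integer(round(shift)), 0)
  else shift_bilinear(m, shift, 0)
}

#' Generate a transverse mask stack over the whole ellipsoid
#'
#' Volumetry operates on multi-slice transverse masks, not the single ASL
#' slice. Slices are slabs perpendicular to the first (long) axis, covering
#' exactly the kidney extent `[-a, a]`: thickness `2a / n_slices`, sampled at
#' slab centres. Each slice's cross-section is the ellipse
#' `(y/b')^2 + (z/c')^2 <= 1` with semi-axes shrunk by the slice position;
#' pixels are counted by the centre-in-region rule. The analytic ellipsoid
#' volume `4/3 pi a b c` is returned alongside for recovery tests.
#'
#' @param spec a [phantom_spec()]; uses its semi-axes and pixel spacing.
#' @param n_slices number of transverse slices (default 22).
#' @param pixel_spacing_mm in-plane spacing of the transverse stack; defaults
#'   to the spec's ASL spacing.
#' @return list with `masks` (list of binary matrices), `pixel_spacing_mm`,
#'   `slice_thickness_mm`, `slice_positions_mm`, `analytic_volume_cm3`.
#' @export
generate_volume_stack <- function(spec, n_slices = 22L,
                                  pixel_spacing_mm = spec$pixel_spacing_mm) {
  validate_phantom_spec(spec)
  stopifnot(n_slices >= 1)
  a <- spec$kidney_semi_axes_mm[1]
  b <- spec$kidney_semi_axes_mm[2]
  cc <- spec$kidney_semi_axes_mm[3]
  thick <- 2 * a / n_slices
  centres <- -a + (seq_len(n_slices) - 0.5) * thick
  sp <- pixel_spacing_mm
  nr <- ceiling(2.2 * b / sp); nc <- ceiling(2.2 * cc / sp)
  y <- (seq_len(nr) - 0.5) * sp - nr * sp / 2
  z <- (seq_len(nc) - 0.5) * sp - nc * sp / 2
  Y <- matrix(y, nr, nc)
  Z <- matrix(rep(z, each = nr), nr, nc)
  masks <- lapply(centres, function(x0) {
    scale <- 1 - (x0 / a)^2
    if (scale <= 0) return(matrix(0L, nr, nc))
    bs <- b * sqrt(scale); cs <- cc * sqrt(scale)
    m <- matrix(0L, nr, nc)
    m[(Y / bs)^2 + (Z / cs)^2 <= 1] <- 1L
    m
  })
  list(masks = masks,
       pixel_spacing_mm = sp,
       slice_thickness_mm = thick,
       slice_positions_mm = centres,
       analytic_volume_cm3 = 4 / 3 * pi * a * b * cc / 1000)
}
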