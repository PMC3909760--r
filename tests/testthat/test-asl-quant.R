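test_that("perfusion formula matches hand-evaluated scalars", {
  p <- quant_params()  # lambda 0.8, TI 900 ms
  dm <- matrix(0.005 * 1000, 2, 2)
  m0 <- matrix(1000, 2, 2)
  t1 <- matrix(1400, 2, 2)
  valid <- matrix(TRUE, 2, 2)
  pm <- compute_perfusion_map(dm, m0, t1, valid, p)
  # 0.8/1.8 * 0.005 * exp(0.9/1.4) * 6000
  expect_equal(unique(as.numeric(pm$values)), 25.35876, tolerance = 1e-6)
  # dM = 0 -> f = 0
  pm0 <- compute_perfusion_map(dm * 0, m0, t1, valid, p)
  expect_true(all(pm0$values == 0))
})

test_that("perfusion map marks non-physical pixels invalid and counts them", {
  p <- quant_params()
  dm <- matrix(1, 2, 2); m0 <- matrix(1000, 2, 2); t1 <- matrix(1400, 2, 2)
  m0[1, 1] <- 0; t1[2, 2] <- -5
  pm <- compute_perfusion_map(dm, m0, t1, matrix(TRUE, 2, 2), p)
  expect_equal(pm$qc$n_invalid_m0_or_t1, 2)
  expect_true(is.na(pm$values[1, 1]) && is.na(pm$values[2, 2]))
})

test_that("linearity, M0 invariance and T1 monotonicity hold", {
  p <- quant_params()
  valid <- matrix(TRUE, 3, 3)
  dm <- matrix(runif(9, 1, 5), 3); m0 <- matrix(runif(9, 500, 1500), 3)
  t1 <- matrix(runif(9, 1000, 2000), 3)
  f1 <- compute_perfusion_map(dm, m0, t1, valid, p)$values
  expect_equal(compute_perfusion_map(3 * dm, m0, t1, valid, p)$values,
               3 * f1, tolerance = 1e-12)
  expect_equal(compute_perfusion_map(2 * dm, 2 * m0, t1, valid, p)$values,
               f1, tolerance = 1e-12)
  f_hi_t1 <- compute_perfusion_map(dm, m0, t1 + 200, valid, p)$values
  expect_true(all(f_hi_t1 < f1))
})

test_that("subtraction and averaging behave as arithmetic says", {
  a <- matrix(1:9, 3); b <- matrix(0, 3, 3)
  s <- asl_series(list(a, a + 59.2), list(a, a), m0_image = a + 10,
                  pixel_spacing_mm = 1)
  dm <- subtract_pairs(s)
  expect_true(all(dm[[1]] == 0))
  expect_true(all(abs(dm[[2]] - 59.2) < 1e-12))
  expect_identical(average_subtractions(dm[1]), dm[[1]])
  consts <- lapply(1:5, function(k) matrix(k, 2, 2))
  expect_true(all(average_subtractions(consts) == 3))
  expect_error(average_subtractions(list()), "no subtraction")
  # noiseless phantom: dM equals the simulator truth exactly
  tr <- phantom_truth(small_spec())
  se <- simulate_asl_series(tr)
  expect_equal(average_subtractions(subtract_pairs(se)),
               attr(se, "dm_truth"), tolerance = 1e-14)
})

test_that("averaging N noisy subtractions shrinks sd by sqrt(N)", {
  spec <- phantom_spec(perfusion_truth = c(cortex = 0, medulla = 0),
                       noise_sd = 10, seed = 21)
  se <- simulate_asl_series(phantom_truth(spec))
  dml <- subtract_pairs(se)
  expect_length(dml, 25)
  sd_one <- mean(vapply(dml, sd, numeric(1)))
  sd_mean <- sd(average_subtractions(dml))
  expect_lt(abs(sd_mean / (sd_one / 5) - 1), 0.10)
})

test_that("registration recovers known shifts and respects its contracts", {
  shifts <- rbind(c(0, 0), c(3, -2))
  spec <- small_spec(n_acquisitions = 2L, motion_shifts_px = shifts,
                     noise_sd = 5, seed = 4)
  se <- simulate_asl_series(phantom_truth(spec))
  reg <- register_series(se)
  r <- reg$report
  est2 <- colMeans(r[r$acquisition == 2, c("shift_row", "shift_col")])
  expect_lt(max(abs(est2 - c(3, -2))), 0.5)
  est1 <- colMeans(r[r$acquisition == 1, c("shift_row", "shift_col")])
  expect_lt(max(abs(est1)), 0.5)
  expect_true(all(r$sim_after >= r$sim_before - 1e-12))

  # structureless input: identity + warning flag, no crash
  noise <- lapply(1:2, function(i) matrix(rnorm(64^2), 64))
  sn <- asl_series(noise[1], noise[2], m0_image = matrix(1, 64, 64),
                   pixel_spacing_mm = 1)
  regn <- register_series(sn, reference = matrix(rnorm(64^2), 64))
  expect_true(all(regn$report$warning))
  expect_equal(regn$series$selective[[1]], noise[[1]])
})

test_that("extreme-pixel exclusion takes out the prescribed tail fraction", {
  # percentiles 0/100: nothing excluded
  m <- matrix(runif(1600), 40)
  mask <- matrix(TRUE, 40, 40)
  v <- exclude_extreme_pixels(m, mask, quant_params(
    exclusion_percentiles = c(0, 100)))
  expect_true(all(v))
  # 2.5/97.5 on 1000 uniform pixels: ~50 excluded
  m2 <- matrix(runif(1000), 40, 25)
  v2 <- exclude_extreme_pixels(m2, matrix(TRUE, 40, 25), quant_params())
  expect_lt(abs(sum(!v2) - 50), 5)
  # tiny mask: warn and skip
  small_mask <- matrix(FALSE, 40, 25); small_mask[1:3, 1:3] <- TRUE
  expect_warning(v3 <- exclude_extreme_pixels(m2, small_mask, quant_params()),
                 "fewer than 20")
  expect_identical(v3, small_mask)
})

test_that("default exclusion catches simulated vessel outliers", {
  spec <- small_spec(vessel_fraction = 0.02, noise_sd = 5, seed = 3)
  q <- quantify_phantom(spec)
  vessel <- q$truth$label_map == 3
  expect_gte(mean(!q$map$valid_mask[vessel]), 0.9)
})

test_that("unit self-consistency: ms and s parameterisations agree", {
  tr <- phantom_truth(small_spec())
  se <- simulate_asl_series(tr)
  dm <- average_subtractions(subtract_pairs(se))
  valid <- tr$label_map > 0
  p_ms <- quant_params(ti_ms = 900)
  f_ms <- compute_perfusion_map(dm, se$m0_image, tr$t1_map_truth, valid,
                                p_ms)$values
  # same computation done directly in seconds
  kid <- which(valid)
  f_s <- 0.8 / (2 * 0.9) * (dm[kid] / se$m0_image[kid]) *
    exp(0.9 / (tr$t1_map_truth[kid] / 1000)) * 6000
  expect_equal(f_ms[kid], f_s, tolerance = 1e-12)
})

test_that("quantify is deterministic and recovers a noisy cortex within 5%", {
  spec <- small_spec(noise_sd = 10, seed = 17)  # 1% of M0
  q1 <- quantify_phantom(spec)
  q2 <- quantify_phantom(spec)
  expect_identical(q1$map$values, q2$map$values)
  ctx <- roi_mean(q1$map$values, q1$truth$region_map, "cortex",
                  q1$map$valid_mask)
  expect_lt(abs(ctx$mean / 320 - 1), 0.05)
})
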