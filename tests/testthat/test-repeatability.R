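test_that("Bland-Altman reproduces the hand-computed example", {
  v1 <- c(10, 12, 14); v2 <- c(11, 13, 13)  # diffs -1, -1, 1
  ba <- bland_altman(v1, v2)
  expect_equal(ba$mean_diff, -1 / 3, tolerance = 1e-9)
  expect_equal(ba$sd_diff, sqrt(4 / 3), tolerance = 1e-9)
  expect_equal(ba$loa_low, -1 / 3 - 1.96 * sqrt(4 / 3), tolerance = 1e-9)
  expect_equal(ba$loa_high, -1 / 3 + 1.96 * sqrt(4 / 3), tolerance = 1e-9)
  expect_equal(ba$loa_low, -2.5966, tolerance = 1e-4)
  expect_equal(ba$loa_high, 1.9299, tolerance = 1e-4)
  # identical visits
  ba0 <- bland_altman(v1, v1)
  expect_equal(c(ba0$mean_diff, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman limits cover ~95% of large normal samples and are
           order invariant", {
  set.seed(31)
  v1 <- rnorm(20000, 229, 40)
  v2 <- v1 + rnorm(20000, 0, 16)
  ba <- bland_altman(v1, v2)
  d <- v1 - v2
  cover <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_lt(abs(cover - 0.95), 0.01)
  perm <- sample(20000)
  ba2 <- bland_altman(v1[perm], v2[perm])
  expect_equal(ba$loa_low, ba2$loa_low, tolerance = 1e-12)
})

test_that("ICC(2,1) matches the frozen ANOVA-by-hand oracle", {
  # two-way mean squares computed independently (and cross-checked against
  # a reference implementation): MSR 20066.667, MSC 16.667, MSE 66.667
  v1 <- c(100, 200, 300); v2 <- c(110, 190, 310)
  icc <- icc_two_way_random(v1, v2)
  expect_equal(icc$msr, 60200 / 3, tolerance = 1e-9)
  expect_equal(icc$msc, 50 / 3, tolerance = 1e-9)
  expect_equal(icc$mse, 200 / 3, tolerance = 1e-9)
  expect_equal(icc$icc, 0.9950248756218903, tolerance = 1e-9)
  expect_equal(icc$ci_low, 0.8868460668210977, tolerance = 1e-6)
  expect_equal(icc$ci_high, 0.9998725257602882, tolerance = 1e-6)
  # mean squares agree with aov() on the long layout
  df <- data.frame(y = c(v1, v2), unit = factor(rep(1:3, 2)),
                   visit = factor(rep(1:2, each = 3)))
  ms <- summary(stats::aov(y ~ unit + visit, df))[[1]][["Mean Sq"]]
  expect_equal(c(icc$msr, icc$msc, icc$mse), unname(ms), tolerance = 1e-9)
})

test_that("ICC degenerate and edge cases follow the contracts", {
  v <- c(100, 200, 300)
  expect_equal(icc_two_way_random(v, v)$icc, 1, tolerance = 1e-12)
  expect_error(icc_two_way_random(rep(5, 4), rep(5, 4)), "zero total")
  # anti-agreement can give a negative estimate, reported with a note
  neg <- icc_two_way_random(c(1, 2, 3, 4), c(4, 3, 2, 1) * 100)
  expect_lt(neg$icc, 0)
  expect_match(neg$note, "negative")
  tr <- icc_two_way_random(c(1, 2, 3, 4), c(4, 3, 2, 1) * 100,
                           truncate = TRUE)
  expect_gte(tr$icc, 0)
  verb <- icc_two_way_random(v, v + 10, verbose = TRUE)
  expect_true(all(c("icc_consistency", "icc_avg_absolute") %in% names(verb)))
  # a systematic shift hurts absolute agreement but not consistency
  expect_lt(verb$icc, verb$icc_consistency)
})

test_that("within-subject CV reproduces the hand example and is
           scale invariant", {
  v1 <- c(100, 110); v2 <- c(102, 108)  # diffs -2, 2; grand mean 105
  expect_equal(cv_within_subject(v1, v2), 100 * sqrt(8) / 105,
               tolerance = 1e-9)
  expect_equal(cv_within_subject(v1, v2), 2.6937, tolerance = 1e-4)
  expect_equal(cv_within_subject(v1, v1), 0)
  expect_equal(cv_within_subject(7 * v1, 7 * v2),
               cv_within_subject(v1, v2), tolerance = 1e-12)
  # conventional definition divides sd(d)/sqrt(2) by the mean
  expect_equal(cv_within_subject(v1, v2, conventional = TRUE),
               cv_within_subject(v1, v2) / sqrt(2), tolerance = 1e-12)
  expect_error(cv_within_subject(c(1, -1), c(1, -1)), "grand mean")
})

test_that("paired t and Pearson r match closed-form references", {
  v1 <- c(100, 200, 300); v2 <- c(110, 190, 310)
  tp <- paired_t_and_pearson(v1, v2)
  expect_equal(tp$t_stat, -0.5, tolerance = 1e-9)
  expect_equal(tp$p_value, 2 / 3, tolerance = 1e-9)
  expect_equal(tp$pearson_r, 0.9933992677987827, tolerance = 1e-9)
  # near-constant offset: r ~ 1 and p shrinks as n grows
  set.seed(6)
  v <- seq(100, 400, by = 4)
  tpo <- paired_t_and_pearson(v, v + 5 + rnorm(length(v), 0, 0.1))
  expect_gt(tpo$pearson_r, 0.9999)
  expect_lt(tpo$p_value, 1e-10)
  # exactly constant offset: r = 1 but zero-variance diffs flag t undefined
  tpc <- paired_t_and_pearson(v, v + 5)
  expect_equal(tpc$pearson_r, 1, tolerance = 1e-12)
  expect_true(is.na(tpc$t_stat))
  expect_match(tpc$note, "undefined")
  # identical visits: r = 1, mean diff 0
  tpi <- paired_t_and_pearson(v, v)
  expect_equal(tpi$pearson_r, 1, tolerance = 1e-12)
  expect_true(is.na(tpi$t_stat))
})

test_that("ICC and CV respond to noise as repeatability theory predicts", {
  set.seed(13)
  icc_lo <- icc_hi <- cv_lo <- cv_hi <- numeric(40)
  for (i in 1:40) {
    truthv <- rnorm(24, 229, 40)
    lo1 <- truthv + rnorm(24, 0, 8); lo2 <- truthv + rnorm(24, 0, 8)
    hi1 <- truthv + rnorm(24, 0, 32); hi2 <- truthv + rnorm(24, 0, 32)
    icc_lo[i] <- icc_two_way_random(lo1, lo2)$icc
    icc_hi[i] <- icc_two_way_random(hi1, hi2)$icc
    cv_lo[i] <- cv_within_subject(lo1, lo2)
    cv_hi[i] <- cv_within_subject(hi1, hi2)
  }
  expect_gt(mean(icc_lo), mean(icc_hi))
  expect_lt(mean(cv_lo), mean(cv_hi))
})

test_that("paired table validation and the battery over metrics", {
  df <- data.frame(subject = rep(1:4, each = 2),
                   kidney = rep(c("L", "R"), 4),
                   metric = "kidney_perfusion",
                   visit1 = c(220, 231, 204, 245, 259, 212, 238, 225),
                   visit2 = c(226, 228, 210, 240, 250, 220, 233, 229))
  pm <- paired_measurements(df)
  res <- repeatability_battery(pm)
  expect_equal(nrow(res), 1)
  expect_equal(res$n, 8)
  ba <- bland_altman(df$visit1, df$visit2)
  expect_equal(res$loa_low, ba$loa_low, tolerance = 1e-12)
  expect_equal(res$icc, icc_two_way_random(df$visit1, df$visit2)$icc,
               tolerance = 1e-12)
  expect_true(res$loa_low <= res$mean_diff & res$mean_diff <= res$loa_high)
  expect_lte(res$icc, 1)
  expect_gte(res$cv_ws_percent, 0)
  # subject-level aggregation halves the units
  res_s <- repeatability_battery(pm, unit = "subject")
  expect_equal(res_s$n, 4)
  # contract violations
  expect_error(paired_measurements(df[, -5]), "need columns")
  expect_error(paired_measurements(rbind(df, df[1, ])), "duplicated")
  dfna <- df; dfna$visit2[1] <- NA
  expect_error(paired_measurements(dfna), "finite")
})

test_that("bland_altman_plot returns a ggplot with the LoA layers", {
  set.seed(3)
  v1 <- rnorm(24, 229, 40); v2 <- v1 + rnorm(24, 0, 16)
  p <- bland_altman_plot(v1, v2)
  expect_s3_class(p, "ggplot")
  expect_gte(length(p$layers), 3)
})
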