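#' Validate a paired-measurements table
#'
#' Long-format inter-study table: one row per (subject, kidney, metric)
#' with the value at visit 1 and visit 2. Each kidney is an observational
#' unit (two kidneys per subject); subject-level aggregation is available in
#' [repeatability_battery()] because kidneys within a subject are not
#' independent.
#'
#' @param df data.frame with columns `subject`, `kidney`, `metric`,
#'   `visit1`, `visit2`.
#' @return the validated data.frame, class `paired_measurements`.
#' @export
paired_measurements <- function(df) {
  need <- c("subject", "kidney", "metric", "visit1", "visit2")
  if (!all(need %in% names(df)))
    stop("need columns: ", paste(need, collapse = ", "))
  key <- interaction(df$subject, df$kidney, df$metric, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicated (subject, kidney, metric) rows")
  if (any(!is.finite(df$visit1)) || any(!is.finite(df$visit2)))
    stop("both visits must be present and finite in every row")
  class(df) <- c("paired_measurements", class(df))
  df
}

#' Bland-Altman limits of agreement
#'
#' Mean inter-visit difference and the 95% limits of agreement,
#' \eqn{\bar d \pm 1.96\, sd(d)} with the n−1 denominator. Differences are
#' visit 1 − visit 2.
#'
#' @param visit1,visit2 paired numeric vectors, length >= 3.
#' @return list: `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(visit1, visit2) {
  stopifnot(length(visit1) == length(visit2))
  if (length(visit1) < 3) stop("Bland-Altman needs at least 3 pairs")
  d <- visit1 - visit2
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       n = length(d))
}

#' Two-way random-effects intraclass correlation, single measure,
#' absolute agreement
#'
#' ICC(2,1): both units (kidneys) and visits are random effects, and
#' systematic inter-visit shifts count against agreement. From the two-way
#' ANOVA mean squares (MSR rows/units, MSC columns/visits, MSE residual),
#' \deqn{ICC = \frac{MSR - MSE}{MSR + (k-1)\,MSE + \frac{k}{n}(MSC - MSE)}}
#' with the F-based 95% confidence interval of McGraw & Wong. Negative
#' estimates are reported as computed with a note; `truncate = TRUE` clips
#' the estimate and CI to [0, 1] for comparability with reports that assume
#' that range. `verbose = TRUE` adds the consistency and average-measure
#' forms, since published "two-way random" ICCs do not always state which
#' was used.
#'
#' @param visit1,visit2 paired numeric vectors, length >= 3.
#' @param conf confidence level (default 0.95).
#' @param truncate clip estimate and CI to [0, 1].
#' @param verbose also return ICC(C,1), ICC(A,k), ICC(C,k).
#' @return list: `icc`, `ci_low`, `ci_high`, mean squares, `note`; plus the
#'   alternative forms when `verbose`.
#' @export
icc_two_way_random <- function(visit1, visit2, conf = 0.95,
                               truncate = FALSE, verbose = FALSE) {
  stopifnot(length(visit1) == length(visit2))
  n <- length(visit1)
  if (n < 3) stop("ICC needs at least 3 units")
  Y <- cbind(visit1, visit2)
  k <- 2
  gm <- mean(Y)
  if (sum((Y - gm)^2) == 0)
    stop("zero total variance: ICC undefined")
  rm_ <- rowMeans(Y); cm_ <- colMeans(Y)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm_ - gm)^2) / (k - 1)
  sse <- sum((Y - gm)^2) - k * sum((rm_ - gm)^2) - n * sum((cm_ - gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # McGraw & Wong F-based CI for single-measure absolute agreement
  alpha <- 1 - conf
  if (mse > 0) {
    fj <- msc / mse
    r <- icc
    vn <- ((k - 1) * (n - 1) *
             (k * r * fj + n * (1 + (k - 1) * r) - k * r)^2) /
      ((n - 1) * k^2 * r^2 * fj^2 + (n * (1 + (k - 1) * r) - k * r)^2)
    fl <- stats::qf(1 - alpha / 2, n - 1, vn)
    fu <- stats::qf(1 - alpha / 2, vn, n - 1)
    ci_low <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    ci_high <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  } else {
    ci_low <- ci_high <- icc  # perfect agreement: degenerate CI
  }
  note <- if (icc < 0) "negative ICC estimate reported as computed" else ""
  if (truncate) {
    icc <- min(max(icc, 0), 1)
    ci_low <- min(max(ci_low, 0), 1)
    ci_high <- min(max(ci_high, 0), 1)
  }
  out <- list(icc = icc, ci_low = ci_low, ci_high = ci_high,
              msr = msr, msc = msc, mse = mse, n = n, k = k,
              form = "two-way random, single measure, absolute agreement",
              note = note)
  if (verbose) {
    out$icc_consistency <- (msr - mse) / (msr + (k - 1) * mse)
    out$icc_avg_absolute <- (msr - mse) / (msr + (msc - mse) / n)
    out$icc_avg_consistency <- (msr - mse) / msr
  }
  out
}

#' Within-subject coefficient of variation, inter-visit
#'
#' As defined for this repeatability battery: the sd of the inter-visit
#' differences divided by the grand mean of all measurements, as a
#' percentage. Note this differs from the conventional within-subject-sd
#' CV, which divides \eqn{sd(d)/\sqrt2} by the mean; `conventional = TRUE`
#' returns that instead.
#'
#' @param visit1,visit2 paired numeric vectors, length >= 2.
#' @param conventional use the within-subject-sd form.
#' @return CV in percent.
#' @export
cv_within_subject <- function(visit1, visit2, conventional = FALSE) {
  stopifnot(length(visit1) == length(visit2))
  if (length(visit1) < 2) stop("CV needs at least 2 pairs")
  gm <- mean(c(visit1, visit2))
  if (gm == 0) stop("grand mean is zero: CV undefined")
  s <- stats::sd(visit1 - visit2)
  if (conventional) s <- s / sqrt(2)
  100 * s / gm
}

#' Paired t-test and Pearson correlation of two visits
#'
#' Two-sided paired Student t-test and the Pearson correlation of visit 1
#' against visit 2.
#'
#' @param visit1,visit2 paired numeric vectors, length >= 3.
#' @return list: `t_stat`, `p_value`, `df`, `pearson_r`. With zero-variance
#'   differences the t statistic is undefined and returned as `NA` with a
#'   note.
#' @export
paired_t_and_pearson <- function(visit1, visit2) {
  stopifnot(length(visit1) == length(visit2))
  if (length(visit1) < 3) stop("need at least 3 pairs")
  d <- visit1 - visit2
  r <- stats::cor(visit1, visit2)
  if (stats::sd(d) == 0) {
    return(list(t_stat = NA_real_, p_value = NA_real_,
                df = length(d) - 1L, pearson_r = r,
                note = "zero-variance differences: t undefined"))
  }
  tt <- stats::t.test(visit1, visit2, paired = TRUE)
  list(t_stat = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), pearson_r = r, note = "")
}

#' Run the full repeatability battery on a paired table
#'
#' For every metric in the table: paired t-test, Pearson r, Bland-Altman
#' limits of agreement, ICC(2,1) with 95% CI, and the inter-visit CV.
#'
#' @param pairs a [paired_measurements()] table.
#' @param unit `"kidney"` (each kidney a unit, the default) or `"subject"`
#'   (kidneys averaged within subject before analysis).
#' @return data.frame, one row per metric, with columns n, mean_diff,
#'   loa_low, loa_high, icc, icc_ci_low, icc_ci_high, cv_ws_percent, t_stat,
#'   p_value, pearson_r, icc_form.
#' @export
repeatability_battery <- function(pairs, unit = c("kidney", "subject")) {
  pairs <- paired_measurements(as.data.frame(pairs))
  unit <- match.arg(unit)
  if (unit == "subject") {
    agg <- stats::aggregate(cbind(visit1, visit2) ~ subject + metric,
                            data = pairs, FUN = mean)
    agg$kidney <- "both"
    pairs <- agg
  }
  res <- lapply(split(pairs, pairs$metric), function(g) {
    ba <- bland_altman(g$visit1, g$visit2)
    icc <- icc_two_way_random(g$visit1, g$visit2)
    tp <- paired_t_and_pearson(g$visit1, g$visit2)
    data.frame(metric = g$metric[1], n = nrow(g), unit = unit,
               mean_diff = ba$mean_diff, loa_low = ba$loa_low,
               loa_high = ba$loa_high,
               icc = icc$icc, icc_ci_low = icc$ci_low,
               icc_ci_high = icc$ci_high,
               cv_ws_percent = cv_within_subject(g$visit1, g$visit2),
               t_stat = tp$t_stat, p_value = tp$p_value,
               pearson_r = tp$pearson_r, icc_form = icc$form)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Bland-Altman plot
#'
#' Inter-visit difference against pair mean, with the mean-difference line
#' (solid) and the 95% limits of agreement (dashed).
#'
#' @param visit1,visit2 paired numeric vectors.
#' @param title plot title.
#' @param units axis unit label.
#' @return a ggplot object.
#' @export
bland_altman_plot <- function(visit1, visit2, title = "Bland-Altman",
                              units = "ml/min/100 g") {
  ba <- bland_altman(visit1, visit2)
  df <- data.frame(m = (visit1 + visit2) / 2, d = visit1 - visit2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$d)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$mean_diff, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(title = title,
                  x = sprintf("Mean of visits (%s)", units),
                  y = sprintf("Visit 1 - visit 2 (%s)", units)) +
    ggplot2::theme_minimal()
}
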