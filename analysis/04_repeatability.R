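#!/usr/bin/env Rscript
# Full two-visit cohort study on simulated data: 12 subjects, both kidneys,
# two visits, quantified end to end, then the repeatability battery
# (Bland-Altman, ICC(2,1), within-subject CV, paired t, Pearson r) on
# cortical and whole-kidney perfusion. Writes the report bundle under
# results/cohort/.

library(renalasl)

cfg <- pipeline_config(n_subjects = 12L, seed = 1L, noise_sd = 10,
                       visit_sd = 20)
res <- run_pipeline(cfg, "results/cohort", plots = TRUE)

cat("Repeatability battery (24 kidneys, 2 visits):\n")
print(res$repeatability[, c("metric", "n", "mean_diff", "loa_low",
                            "loa_high", "icc", "icc_ci_low", "icc_ci_high",
                            "cv_ws_percent", "p_value", "pearson_r")],
      digits = 3)

wk <- res$repeatability[res$repeatability$metric == "kidney_perfusion", ]
cat(sprintf(
  "\nWhole-kidney perfusion: ICC %.2f (95%% CI %.2f-%.2f), CV_ws %.1f%%.\n",
  wk$icc, wk$icc_ci_low, wk$icc_ci_high, wk$cv_ws_percent))
cat(sprintf(
  "Paired t-test p = %.2f: no systematic shift between visits, as built\n",
  wk$p_value))
cat("into the generator (visit effects are zero-mean drift).\n")
cat(sprintf("Outputs carry config hash %s.\n", res$config_hash))
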