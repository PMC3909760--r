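# renalasl

Quantification of renal perfusion from FAIR arterial spin labelling (ASL)
MRI, with a ground-truth digital kidney phantom and the inter-study
repeatability statistics needed to establish that two scan visits agree.
Intended for imaging scientists working on non-contrast renal perfusion —
ASL needs no gadolinium and no ionising radiation, which makes it the
technique of choice when renal function is impaired.

## What it computes

Perfusion is quantified pixel-wise from selective/non-selective inversion
pairs via the single-compartment FAIR model

    f = lambda / (2 TI) * (dM / M0) * exp(TI / T1)

with `lambda = 0.8` ml/g, `TI = 900` ms, per-pixel `T1`, and `dM` the
average of the registered, pairwise-subtracted label/control images after
extreme-pixel exclusion (default 2.5/97.5 percentiles within the kidney).
`f` is reported in ml/min/100 g. Around that core:

* **phantom** — `phantom_spec()`, `phantom_truth()`,
  `simulate_asl_series()`, `generate_volume_stack()`: a 2D ellipsoidal
  kidney (cortex 320, medulla 120 ml/min/100 g; T1 1400/1650 ms) whose
  forward signal model is the exact inverse of the pipeline, plus noise,
  rigid motion and vessel-like outliers, all seeded and bit-reproducible.
* **quantification** — `register_series()`, `subtract_pairs()`,
  `average_subtractions()`, `exclude_extreme_pixels()`,
  `compute_perfusion_map()`, and the one-call `quantify()`.
* **morphometry** — `ellipsoid_volume()` (L·W·D·π/6),
  `voxel_count_volume()`, mass at 1.05 g/ml, `absolute_perfusion()`
  (ml/min), `total_participant_perfusion()`.
* **regional summaries** — `roi_mean()`, `roi_summary_table()` for
  cortex/medulla/whole-kidney T1 and perfusion.
* **repeatability** — `bland_altman()`, `icc_two_way_random()` (ICC(2,1),
  absolute agreement, F-based 95% CI), `cv_within_subject()` (sd of
  inter-visit differences over the grand mean), `paired_t_and_pearson()`,
  the `repeatability_battery()` driver and `bland_altman_plot()`.
* **IO / orchestration** — minimal NIfTI-1 read/write, YAML/JSON configs,
  and `run_pipeline()` for the full simulate → quantify → summarise →
  repeatability chain with hashed, byte-reproducible outputs.

## Worked example

```r
library(renalasl)

spec  <- phantom_spec(noise_sd = 10, seed = 1)   # noise = 1% of M0
truth <- phantom_truth(spec)
series <- simulate_asl_series(truth)
pm <- quantify(series, truth$t1_map_truth, truth$label_map > 0)
roi_mean(pm$values, truth$region_map, "cortex", pm$valid_mask)[, 1:5]
#>   region                metric     mean       sd n_pixels
#> 1 cortex perfusion_ml_min_100g 317.4971 12.52286      782
```

The cortical mean recovers the 320 ml/min/100 g ground truth to 0.8%
despite the noise; with `noise_sd = 0` recovery is exact to floating point.
A full simulated two-visit cohort study (12 subjects, 24 kidneys):

```r
res <- run_pipeline(pipeline_config(n_subjects = 12, seed = 1), "results/cohort")
res$repeatability[, c("metric", "icc", "icc_ci_low", "icc_ci_high", "cv_ws_percent")]
#>             metric       icc icc_ci_low icc_ci_high cv_ws_percent
#> 1 cortex_perfusion 0.8590467  0.7016881   0.9364911      8.725662
#> 2 kidney_perfusion 0.7925169  0.5778271   0.9046325      8.902804
```

ICC near 0.8–0.9 with a within-subject CV below 10% is what the generator's
stated world (between-kidney sd 50, visit drift sd 20 ml/min/100 g) implies
— the battery measures it back out of fully simulated images.

The numbered drivers under `analysis/` run the same stages as a narrative
workflow (`01_simulate_phantom.R` … `04_repeatability.R`) and write their
tables under `results/`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the full cohort chain end to end from the given seed (simulation,
quantification, repeatability battery), logs the headline statistics, and
writes the machine-readable result map to `--out`.
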