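---
title: "Quantifying renal perfusion from FAIR ASL MRI: models, phantom and repeatability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying renal perfusion from FAIR ASL MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalasl)
```

## The measurement problem

Arterial spin labelling (ASL) measures tissue perfusion by magnetically
labelling arterial blood water and imaging its arrival, with no exogenous
contrast — attractive for the kidney, where gadolinium is contraindicated in
renal impairment. In the FAIR (flow-sensitive alternating inversion
recovery) scheme, pairs of images are acquired after a slice-selective
inversion (label) and a non-selective inversion (control); their difference
$\Delta M$ isolates the signal of inflowing blood. A separate image without
ASL preparation supplies the equilibrium magnetisation $M_0$, and a T1 map
supplies the tissue relaxation time entering the kinetic model.

`renalasl` implements the complete measurement chain for a single-slice
renal FAIR acquisition, plus the morphometry and the inter-study
repeatability statistics used to establish whether two scan visits agree.
Because raw clinical ASL series are rarely shareable, the package is built
around a digital kidney phantom with known ground truth: every stage is
validated by parameter recovery rather than by comparison to an
irreproducible clinical table.

## The perfusion model

Perfusion is quantified pixel-wise from the averaged subtraction image by
the single-compartment FAIR relation

$$ f \;=\; \frac{\lambda}{2\,TI}\,\frac{\Delta M}{M_0}\,e^{TI/T_1}, $$

with $f$ in ml/g/s when time is in seconds, reported $\times 6000$ as
ml/min/100 g. The parameters, their defaults and their meaning:

| parameter | default | meaning |
|---|---|---|
| $\lambda$ | 0.8 ml/g | tissue–blood water partition coefficient |
| $TI$ | 900 ms | inversion time between labelling and readout |
| $T_1$ | per-pixel map, ms | longitudinal relaxation at 3 T |
| exclusion percentiles | 2.5 / 97.5 | extreme-pixel rejection bounds |

The model ignores transit-time and water-exchange effects; that is a known
limitation of single-TI FAIR quantification, not of this implementation,
and matters most when transit times vary (e.g. renovascular disease).

The processing chain mirrors standard practice for breath-hold renal FAIR:

1. **Registration.** All images are aligned to the first non-selective
   image by rigid in-plane translation maximising a correlation similarity.
   The estimate is the FFT cross-correlation peak; sub-pixel refinement by
   Nelder–Mead on the bilinearly resampled correlation is available
   (`subpixel = TRUE`) but off by default: inter-acquisition breath-hold
   motion is well captured at integer resolution, and integer correction
   resamples nothing, so a motion-free series passes through bit-exactly.
   The contract is only that similarity never decreases; an image whose
   peak correlation falls below 0.3 (no usable structure) is passed through
   unchanged with a warning flag rather than aborting the pipeline.
2. **Subtraction.** $\Delta M_i$ = selective$_i$ − non-selective$_i$. The
   sign convention is fixed once so perfusion comes out positive.
3. **Averaging.** The arithmetic mean over all pairs; with 25 pairs the
   noise sd of the mean falls by a factor 5.
4. **Extreme-pixel exclusion.** Within the kidney mask, pixels of the
   averaged $\Delta M$ outside the 2.5th–97.5th percentile are excluded as
   likely vessels or adventitia. No published threshold exists for this
   step, so the default is deliberately mild, symmetric and scale-free, and
   configurable. Exclusion operates on the *averaged* subtraction (rather
   than per-pair or on raw intensities), which is the variant that directly
   targets structured outliers surviving the average; masks under 20 pixels
   skip exclusion with a warning. Negative-perfusion pixels are *retained*
   — clipping them would bias ROI means upward — and counted in the QC log.
5. **Quantification.** The formula above, applied on valid pixels; pixels
   with non-positive $M_0$ or $T_1$ are invalidated and counted.

T1 enters as a per-pixel map on the ASL grid. Internally all times are
seconds; all interfaces use ms, matching how acquisition parameters are
printed.

## The phantom: a stated world

`phantom_spec()` declares the simulated world; its defaults are fixed
a priori and are not tuned to make tests pass:

* grid 256 × 256 over a 380 mm field of view (1.484 mm/px), slice 10 mm —
  the acquisition geometry of a single-slice renal protocol;
* ellipsoidal kidney, semi-axes 55 × 25 × 20 mm (a 11 × 5 × 4 cm organ,
  typical adult kidney), with an 8 mm cortical shell — normal cortical
  thickness;
* cortical perfusion 320, medullary 120 ml/min/100 g; cortical T1 1400 ms,
  medullary 1650 ms — healthy-kidney magnitudes at 3 T;
* $M_0$ = 1000 signal units; 5 label/control pairs per acquisition,
  5 acquisitions; optional Gaussian noise, per-acquisition rigid
  translation, and vessel-like outlier pixels.

The forward model is the exact algebraic inverse of the quantification
chain, so a noiseless, motion-free, outlier-free phantom must be recovered
to floating-point accuracy — the package's primary oracle. Stochastic
features draw from stream-separated seeds derived from the spec seed, so
identical specs give bit-identical series.

Design choices where the design was genuinely open:

* the control image is modelled as $c \cdot M_0$ with $c = 1$; the chain
  uses only the pair difference and the separate $M_0$ image, so $c$ is
  irrelevant to recovery;
* motion is rigid in-plane translation (integer by default, sub-pixel via
  bilinear interpolation); rotation is omitted for oracle clarity;
* vessel outliers overwrite the selective image at ±2 × the maximum kidney
  intensity — far enough out that any sane "extremes of the range"
  exclusion must catch them, which is exactly what the outlier criterion
  tests;
* the ASL phantom is a single 2D slice (matching a single-slice protocol);
  3D stacks exist only for volumetry, as transverse slabs covering the
  kidney extent exactly;
* slice obliquity of real sagittal-oblique acquisitions is not emulated —
  it changes the geometry of one slice, not the algebra of recovery.

What a green recovery test does **not** establish: fidelity to real renal
ASL data, with its transit-time dispersion, B0/B1 inhomogeneity,
through-plane and non-rigid motion, and partial-volume mixing at the
cortico-medullary boundary. The phantom validates the *processing*, not the
*acquisition physics*.

## Morphometry

Two volume estimators are implemented: the ellipsoid formula
$V = L \times W \times D \times \pi/6$ from three localiser measurements,
and voxel counting (in-mask pixel count × pixel area × slice thickness over
a multi-slice transverse stack). On phantom ellipsoids they agree as
sampling is refined; on coarse clinical sampling they can differ
substantially, which is data-dependent and not asserted. Pixels are counted
by the centre-in-region rule on a 0-based half-open grid — unambiguous and
matched by the independent rasteriser used in tests. Mass is volume × 1.05
g/ml (renal specific gravity); absolute perfusion is perfusion × mass/100
(ml/min), computed **per kidney and then averaged** — averaging before
multiplying changes cohort summaries. Totals per participant are the sum of
the two kidneys, with missingness propagated, never zero-filled.

## Regional summaries

T1 is summarised for cortex, medulla and whole kidney; perfusion for cortex
and whole kidney. Medullary perfusion is computed on request but flagged
unstable: perfusion maps are heterogeneous in the medulla (larger vessels,
renal pelvis), which is why whole-kidney perfusion is the preferred
secondary endpoint. Whole-kidney means are pixel-count-weighted combinations
of the regional means; the reported per-pixel sds describe within-region
spread, while cohort tables additionally carry the across-kidney sd — two
different dispersions that published tables do not always distinguish.

## Repeatability battery

For paired visit-1/visit-2 measurements, `repeatability_battery()` reports:

* **Bland–Altman**: mean difference and 95% limits of agreement
  $\bar d \pm 1.96\,sd(d)$, $n-1$ denominator;
* **ICC(2,1)**: two-way random-effects, single-measure, *absolute
  agreement* intraclass correlation from the ANOVA mean squares, with the
  F-based 95% CI (McGraw–Wong). "Two-way random" alone does not pin down
  the form; single-measure absolute agreement is the strictest common
  choice and is recorded in the output metadata, with consistency and
  average-measure forms available in verbose mode. Negative estimates are
  reported as computed (with a note); truncation to [0, 1] is an option,
  not the default;
* **within-subject CV**, defined here as $100 \cdot sd(d) / \bar x$ — the
  sd of inter-visit differences over the grand mean. This is *not* the
  conventional within-subject-sd CV (which divides $sd(d)/\sqrt 2$ by the
  mean and is $\sqrt 2$ smaller); the package implements the inter-visit
  definition as default for fidelity with how renal ASL repeatability is
  usually reported, and the conventional form behind
  `conventional = TRUE`;
* **paired t-test and Pearson r** between visits.

Each kidney is treated as the observational unit by default (24 kidneys
from 12 subjects); since kidneys within a subject are correlated, a
subject-level aggregation (`unit = "subject"`) is provided for sensitivity
analysis. Degenerate inputs fail loudly: zero total variance makes the ICC
undefined, a zero grand mean makes the CV undefined, zero-variance
differences flag the t statistic as undefined — none are silently replaced.

## The simulated cohort

`run_pipeline()` chains everything: per-kidney cortical/medullary perfusion
truths drawn around the healthy defaults (between-kidney sd 50/25
ml/min/100 g), zero-mean between-visit drift (sd 20 ml/min/100 g), image
noise of 1% of $M_0$, quantification of all 48 kidney-visits, regional and
morphometric tables, and the battery. The cohort grid defaults to 96 × 96
at the ASL pixel spacing — the kidney keeps its physical size; only the
empty field of view shrinks — so the whole study runs in seconds. Phantom
anatomy is identical across kidneys (anatomy does not drive the
repeatability statistics; perfusion truths do). The cohort phantoms are
simulated without inter-acquisition motion and the pipeline correspondingly
skips registration; motion recovery is exercised separately, where the
ground-truth shift is known. All outputs are deterministic given the config
and seed and carry an MD5 config hash.

## Numerical choices and degenerate inputs

* Percentiles use R's default quantile type 7; with near-constant data the
  exclusion bounds collapse onto the data range and nothing is excluded.
* Registration falls back to the identity transform (with a warning flag)
  whenever correction would *decrease* similarity or the correlation peak
  is below 0.3; it never throws.
* The ICC CI collapses to a point when the residual mean square is zero
  (perfect agreement).
* Seeds derived from user seeds stay below $2^{31}$; independent stochastic
  features (noise per image, vessel placement, cohort draws) use separate
  streams so adding one feature never perturbs another.

## Known limitations

Single-slice, single-TI quantification; no transit-time correction, no
background suppression, no MOLLI T1 fitting (T1 maps are inputs), no
automated cortex/medulla segmentation (label maps are inputs). The NIfTI
writer covers the float64 single-file subset the pipeline itself produces;
it is an exchange format here, not a general medical-image IO layer.
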