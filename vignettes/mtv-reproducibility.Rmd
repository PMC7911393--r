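---
title: "Methods: MTV segmentation reproducibility on synthetic PET phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MTV segmentation reproducibility on synthetic PET phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`petmtv` studies a measurement problem, not a biological one: how much of
the variability in the baseline metabolic tumour volume (MTV) of lymphoma
patients is caused by the delineation rule, and how much by the human
reader. The package simulates the whole measurement chain — tracer uptake
image, reader-drawn regions of interest, thresholding rule, per-patient
aggregation — and then applies the standard agreement and survival
statistics to the simulated cohorts.

### The phantom

An SUV phantom is a 3-D array of non-negative standardised uptake values on
a voxel grid. Defaults reproduce a clinical acquisition: 168 × 168
transaxial matrix at 5.3 mm/pixel, 2.0 mm plane spacing, and an isotropic
Gaussian point-spread function (PSF) of 4.4 mm FWHM. Content is built in
this order:

1. uniform soft-tissue background (SUV 1.0 by default);
2. a spherical liver reference region (radius 15 mm, mean SUV 2.2) in a
   fixed corner of the grid, away from the lesion placement region;
3. lesions as uniform spheres; an *infiltrative cluster* is 2–4 overlapping
   spheres sharing a cluster id, one bright (SUV 8–16) and the rest dim
   (SUV 3.5–7), emulating diffusely infiltrated anatomical regions where
   readers disagree about lesion boundaries;
4. convolution with the PSF (separable discrete Gaussian, normalised kernel,
   replicated edges — so blurring can never raise the image maximum);
5. additive Gaussian noise clipped at zero, plus voxel texture inside the
   liver sphere (SD 0.25) so the liver SD that the PERCIST threshold needs
   is non-trivial.

This is a desk-scale stand-in, not a reconstruction simulator: there is no
Poisson counting statistics, no scatter/attenuation, no anatomical texture,
and lesions are spheres. Ground truth records the *analytic* sphere volumes,
which is what volume-recovery tests compare against. Consequences for
interpretation: tests passing here show that the delineation and statistics
machinery behaves as specified under known geometry and contrast; they do
not certify accuracy on real reconstructed PET data, where noise correlation
and heterogeneous uptake matter.

### The observer model

A reader is modelled by two parameters. `box_margin_jitter` (SD in voxels,
default 1 in the cohort studies) jitters every face of the tight
ground-truth bounding box (tight box = sphere extent plus a margin of
PSF FWHM + 4 mm, which contains the suprathreshold spill-out).
`split_merge_probability` is the probability that an infiltrative cluster is
delineated as one merged box rather than one box per component lesion. The
published study this emulates does not quantify how often readers merged
infiltrative regions, so 0.5 is a free simulation parameter chosen to
maximise disagreement opportunity (each patient with a cluster has a 50%
chance per observer, hence 50% chance the two observers decide differently).
Liver statistics are computed automatically from the known liver sphere and
shared by both observers, mirroring software-side automation.

### The eight delineation rules

Thresholds are inclusive (`SUV >= T`) everywhere, and no connected-component
filtering is applied: the mask is all suprathreshold voxels in the box.
Boxes are axis-aligned, 0-based, half-open.

* absolute: `SUV >= 2.5`; `SUV >= liver SUVmax`; `SUV >= PERCIST SUV` with
  PERCIST SUV = 1.5 × liver SUVmean + 2 × liver SD (sample SD over the
  liver-ROI voxels; the operational definition of "2 standard deviations"
  is not fixed by the source literature, so the sample SD was chosen).
* percentage: `SUV >= 0.41 × box maximum`.
* Nestle: `T = β (I₇₀ + B)` with β = 0.15, I₇₀ the mean of box voxels at or
  above 70% of the box maximum, and B a local background from a 2-voxel
  shell around the box (excluding other lesion boxes). β and the core
  fraction are exposed configuration. Note this form keeps β multiplying
  the background as well; with β = 0.15 the resulting threshold sits close
  to the background, so the rule over-segments small blurred spheres more
  than the other rules — visible in the volume-recovery numbers.
* Black: iterative `T ← 0.307 × SUVmean(mask) + 0.588`, started from the
  41% mask, until the mask is a fixed point (cap 100 iterations; reaching
  the cap raises an error with the threshold trace).
* Daisne-type adaptive: iterative fraction `f = m / SBR + c` of the box
  maximum, `SBR = SUVmean(mask) / background`, started from the 41% mask;
  `(m, c)` come from a phantom calibration (below). SBR ≤ 1 at any point is
  an error ("insufficient contrast").
* Fitting: least-squares fit of a closed-form forward model — a uniform
  sphere on a uniform background convolved with the isotropic Gaussian PSF
  (the blurred-sphere radial profile) — to the box voxels; the reported MTV
  is the analytic volume of the fitted sphere. A small width floor
  (0.35 × finest spacing) keeps the model differentiable when FWHM 0 is
  requested. Optimisation is Nelder–Mead followed by BFGS polish from
  moment-based starts; a flat box or a fitted diameter below one voxel is
  an error.

### Adaptive calibration

`calibrate_adaptive()` generates noiseless blurred-sphere phantoms over a
crossed design of diameters {24, 36, 48, 60} mm × contrasts {3, 5, 10, 12}
and, for each, finds the fraction of the box maximum whose threshold best
recovers the analytic sphere volume. Because volume-vs-threshold is a step
function on the finite lattice of voxel values, the optimum is located by
exact scan over that lattice (equivalent to bisection on the step function)
and reported at the midpoint of the optimal plateau. Fractions are then
regressed on 1/SBR. The crossed design matters: on the coarse 5.3 mm
in-plane grid, single-phantom fractions carry voxelisation noise of several
percent, and one phantom per contrast produces unstable constants. A useful
closed-form check: with no PSF the image is two-valued, the optimal plateau
is (background, uptake] and its midpoint fraction is exactly
0.5 + 0.5/SBR — so a zero-blur calibration returns m = 0.5, c = 0.5.

### Aggregation

The patient total is the union of the per-lesion masks (each voxel counted
once, so overlapping boxes are not double-counted; summation instead of
union is available behind `double_count = TRUE`). The fitting method's MTV
is an analytic volume, so it sums over boxes. Bone marrow joins the total
only when focal; the spleen when focal or when its diffuse uptake strictly
exceeds 150% of the liver background, taken as liver SUVmean (the source
rule does not specify mean vs max; mean is the conservative reference an
automated pipeline measures anyway). An included diffuse organ contributes
a dedicated organ box segmented by the active method.

### Agreement statistics

The inter-observer coefficient is the two-way mixed, single-rater
*consistency* ICC — ICC(3,1), computed from closed-form mean squares — which
ignores a constant shift between readers; the absolute-agreement form was
deliberately not used because the study design treats a systematic offset
as a calibration difference, not disagreement. Rank agreement is Kendall's
tau-b (tie-corrected). Confidence intervals are BCa bootstrap (default
10,000 replicates in the pipeline defaults; bias correction from the
proportion of replicates below the estimate, acceleration from the
jackknife). Pairwise method comparison uses a *joint* bootstrap — one
patient resample per replicate drives all methods — preserving the
cross-method correlation; the two-sided p-value is the position of the
Δ-distribution relative to zero with a +1 continuity correction (so p is
never exactly 0), and Hochberg step-up correction is applied across the
method pairs separately per coefficient. How the original analysis formed
its pairwise p-values is not documented; the joint bootstrap is this
package's assumption and its tables are not expected to match printed
cells. Bland–Altman limits are bias ± 1.96 SD with normal-theory CIs
(SE(bias) = SD/√n, SE(limit) = SD·√(3/n)).

### Survival analysis

Outcomes are generated from an exponential proportional-hazards model:
hazard = λ₀ × HRᵥᶻ × HRᵢᵖⁱ × HRᶜᵗ with z the high-vs-low true-volume
indicator (median split unless configured), covariate prevalences 58.2%
(IPI 3–5) and 72% (CHOP-type regimen), uniform administrative censoring on
3–10 years, and analysis-side censoring at 5 years. Default hazard ratios
are 2.31 (volume), 1.8 (IPI), 3.04 (chemotherapy); λ₀ = 0.024/year was
calibrated once so the simulated 5-year progression-free survival is ≈54%,
the value reported for the 239-patient series the defaults emulate.
Analysis uses the Kaplan–Meier estimator, the log-rank test, Cox partial
likelihood with Efron tie handling (Breslow behind a flag; ties are likely
in discretised simulated times), and reverse Kaplan–Meier median follow-up.
ROC cut-offs maximise Youden's J over the empirical curve built on the
per-patient mean of the two observers' MTVs (per-observer curves give the
evaluator-specific cut-offs); ties are broken toward the larger cut-off,
and the AUC is trapezoidal. The 5-year outcome label excludes patients
censored event-free before 5 years (their label is unknown); the exclusion
count is reported.

## Problem sizes

The package's own studies run at deliberately reduced sizes: the agreement
study uses 20 master seeds × 200 patients on a 64³ grid at clinical voxel
spacing (the full 168 × 168 × N grid is supported but unnecessary for
cohorts of single-region phantoms); BCa coverage is assessed with 500
intervals of ~2,000 resamples; Cox recovery with 200 cohorts of 239
records drawn without image rasterisation (`images = FALSE`, which keeps
the true-volume distribution identical while skipping the voxel work).
These sizes are the package's choices for routine verification; all are
configuration, not constants.

## Numerical choices and degenerate inputs

* Ties at thresholds are inclusive everywhere; volumes are reported in cm³
  at full precision internally and rounded only in report tables.
* Iterative methods stop on a mask fixed point, never on a threshold
  tolerance, so convergence is exact; non-convergence within 100 iterations
  is an error carrying the threshold trace.
* An all-zero box under the percentage rule returns an empty mask flagged
  `zero_box` rather than an error; an empty mask after absolute
  thresholding is a valid zero-volume result.
* A degenerate bootstrap distribution collapses the CI to the point
  estimate with a `degenerate` flag; a statistic undefined on more than 1%
  of replicates is an error.
* Zero between-patient variance makes the ICC undefined (error), as does an
  all-tied series for tau-b.
* Every stochastic operation takes a seed; cohort operations derive
  per-patient child seeds from the master seed, so any patient can be
  regenerated in isolation.

## Known limitations

* Spheres and sphere clusters only; no irregular or heterogeneous lesions,
  so the fitting method is never model-misspecified in the way it would be
  clinically.
* The observer model produces box-level variability only; real readers also
  disagree through editing of the segmented contour itself.
* Absolute thresholds are applied inside boxes. For isolated lesions this
  is equivalent to whole-body thresholding followed by lesion assignment
  (the box-invariance property in the test suite makes the distinction
  immaterial); for abutting lesions it is not.
* The Nestle and Black constants are the cited literature values and the
  Daisne constants come from the included calibration; none are tuned to
  reproduce any particular software product's output.
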