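# qpianiso

Scattering anisotropy from quantitative phase images, with the patient-level
statistics needed to evaluate it as a prognostic marker for prostate-cancer
recurrence.

## The problem

After radical prostatectomy, roughly a quarter of patients experience
biochemical recurrence (rising serum PSA). Clinical risk scores such as
CAPRA-S struggle precisely on the pair-matched, intermediate-risk cases where
a better marker is most needed. Quantitative phase imaging (QPI) measures
optical path-length maps \(\phi(r)\) of unstained tissue sections with
nanometer sensitivity; the *scattering-phase theorem* turns spatial moments
of such a phase map into bulk light-scattering parameters. In particular, the
anisotropy factor g — the mean cosine of the scattering angle — of the stroma
immediately adjoining malignant glands is lower (more isotropic scattering,
more fragmented collagen) in patients who go on to recur.

This package implements that analysis end to end for researchers in
quantitative microscopy and biophotonics:

* **`qpi_core`** — phase-image containers, mosaic stitching/cropping, and the
  moment-based anisotropy estimator with its noise/error propagation:

  g = 1 − ⟨|∇φ|²⟩_r / (2 k₀² ⟨Δφ²⟩_r),   k₀ = 2π/λ̄ (λ̄ = 552 nm default),

  where the moments are taken over a stromal region of interest r.
* **`scattering_oracle`** — an independent accuracy oracle: the far-field
  angular scattering distribution is computed from the phase-only
  transmission exp(iφ) by Fourier optics and fitted with the
  Henyey-Greenstein phase function
  p(θ) = (1/4π)(1−g²)/(1+g²−2g cosθ)^{3/2}
  to recover g by a second, physically distinct route.
* **`synthetic_data`** — Gaussian random fields with closed-form gradient
  statistics, oriented fiber textures with tunable fragmentation,
  scattering-consistent stromal textures with prescribed g, synthetic tissue
  cores with gland/stroma geometry, matched recurrent/non-recurrent cohorts
  calibrated to reference group summaries, and post-surgical PSA series.
* **`cohort_analysis`** — per-patient aggregation, fixed-bin histograms,
  Welch tests (raw or from published summaries), rank-based ROC/AUC with
  threshold analysis, CAPRA-S scoring (0–12, editable point table),
  the biochemical-recurrence rule (>0.4 ng/ml once, or >0.2 ng/ml with
  subsequently rising values), and PSA-stratified AUC comparisons.
* **`interface`** — a config-driven CLI (`simulate`, `anisotropy`, `oracle`,
  `cohort-report`) with JSON configs, manifests and reproducible outputs.

## Worked example

Generate an isotropic Gaussian-random-field phase map whose anisotropy is
known in closed form, then measure it:

```r
library(qpianiso)

spec <- texture_spec(shape = c(1024, 1024), pixel_size = 0.05,  # um/px
                     sigma_phi = 0.5,   # phase contrast, rad
                     corr_len  = 0.5,   # correlation length, um
                     seed = 7)
img <- gen_grf_phase(spec)
roi <- roi_mask(matrix(TRUE, 1024, 1024))
anisotropy_from_phase(img, roi)
#> <scattering_result> g = 0.9396 (variant A, 1048576 px)
#>   grad_term = 3.949 rad^2/um^2, var_term = 0.2524 rad^2, sigma_g = NA

1 - 2 / (img$k0^2 * spec$corr_len^2)   # closed form for this covariance
#> [1] 0.9382541
```

The estimator lands within 0.002 of the analytic value: the mean squared
phase gradient of a Gaussian covariance C(r) = σ² exp(−r²/ℓ²) is 4σ²/ℓ², so
g = 1 − 2/(k₀²ℓ²) independent of the phase contrast.

Reproducing the group-level statistics on the default synthetic cohort
(92 recurrent / 89 non-recurrent patients, 12–16 stromal regions each,
calibrated to the reference summaries 0.911 ± 0.039 and 0.935 ± 0.031 with
medians 0.921 / 0.945):

```r
cfg <- run_config(seed = 1)
cli_simulate(cfg, "sim")                       # writes patients.csv, rois.csv
rpt <- cli_cohort_report("sim/patients.csv", "sim/rois.csv", cfg, "report")
rpt$auc_g; rpt$sensitivity; rpt$specificity; rpt$welch$p; rpt$capra_excluded
#> [1] 0.7217880
#> [1] 0.7065217
#> [1] 0.6067416
#> [1] 5.687870e-06
#> [1] 20
```

Lower g scores toward recurrence; at the default decision threshold
g = 0.938 the synthetic cohort gives AUC 0.72 with sensitivity 0.71 and
specificity 0.61, and 20 patients are excluded from CAPRA-S scoring for
missing fields — the report tables (`histogram.csv`, `group_stats.csv`,
`psa_strata_auc.csv`, `summary.json`) mirror the figure-level summaries of a
cohort study.

A Welch test straight from published group summaries:

```r
welch_t_from_summary(0.911, 0.039, 92, 0.935, 0.031, 89)
#> $t [1] -4.590802   $df [1] 172.5653   $p [1] 8.475241e-06
```

## Scope notes

Inputs are assumed to be already-reconstructed phase maps (no phase
unwrapping, no halo correction, no raw interferogram processing) in 32-bit
float TIFF (radians) with pixel size and wavelength carried in the
ImageDescription tag as JSON; masks are 8-bit TIFF. See the methods vignette
(`vignettes/anisotropy-workflow.Rmd`) for the model assumptions, parameter
choices and known limitations.
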