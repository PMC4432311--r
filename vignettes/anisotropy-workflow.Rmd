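---
title: "Measuring stromal scattering anisotropy from quantitative phase images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring stromal scattering anisotropy from quantitative phase images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpianiso)
```

This vignette is the package's own account of the science it implements: the
model and its assumptions, the parameters that matter, what the synthetic
data generator does and does not emulate, the numerical choices, and the
design decisions we made where the underlying methodology is genuinely open.

## 1. The measurement model

A quantitative phase image is a map $\phi(r)$ of optical path-length shift
(radians) through a thin tissue section, with physical pixel size (µm) and a
center illumination wavelength $\bar\lambda$ (552 nm by default, white-light
phase contrast). Under the thin-object approximation the section acts as a
phase-only transmission $t(r) = e^{i\phi(r)}$.

The scattering-phase theorem expresses bulk scattering parameters of the
tissue as spatial moments of $\phi$. For the anisotropy factor $g$ — the
mean cosine of the scattering angle, with $g \to 1$ forward-peaked and
$g \to 0$ isotropic — the estimator implemented by
`anisotropy_from_phase()` (variant `"A"`, the default) is

$$ g = 1 - \frac{\langle|\nabla\phi|^2\rangle_r}
               {2 k_0^2 \langle \Delta\phi^2 \rangle_r}, \qquad
   k_0 = 2\pi/\bar\lambda, $$

with both moments taken strictly over a region of interest $r$ (a stromal
band adjoining a gland), and the phase variance computed about the region's
own mean. The estimator is exact in the forward-scattering regime: writing
the far-field intensity of the scattered field as a distribution over
spatial frequency $q = k_0\sin\theta$, the ratio of moments equals
$E[q^2]$, and $1 - E[q^2]/2k_0^2$ is the small-angle expansion of
$E[\cos\theta]$. Its assumptions are therefore:

* thin object, phase-only transmission (no absorption contrast);
* forward-peaked scattering (valid for stroma, $g \gtrsim 0.85$);
* the phase map resolves the relevant spatial frequencies (the objective
  NA, 0.75 by default, band-limits $q$ at $k_0\,\mathrm{NA}$).

Two algebraic variants of the moment combination circulate in prose
descriptions of this estimator. Variant `"B"`
($\langle|\nabla\phi|\rangle^2$ over $2k_0^2\langle\Delta\phi^2\rangle^2$)
is implemented for comparison but is *not* the default: on the
Gaussian-random-field test bed with known closed-form $g$ (Section 3),
variant A reproduces the analytic value ($g = 0.938$ at
$\ell_c = 0.5$ µm) and tracks the independent Henyey-Greenstein oracle,
while variant B lands more than 0.1 away from the oracle on the same fields
(both facts are asserted by the test suite). The disambiguation is thus made
by physics, not by citation.

Properties worth knowing: $g$ is invariant to adding a constant phase and to
translating the ROI with its texture; it can leave $[0, 1)$ on fields rough
beyond the theorem's regime, in which case the result is *flagged and
warned, never clipped* — silent clipping would hide miscalibration.

### Gradients, and degenerate inputs

`phase_gradient()` uses central differences on interior pixels, one-sided at
borders, in rad/µm. Central differences are exact on linear ramps and have a
known transfer function $\sin(qh)/qh$ per axis; at the default 0.05 µm
pixels the induced bias on the GRF gradient moment is about 2%, well inside
the Monte-Carlo tolerance of the tests that rely on it. A constant-phase ROI
has zero variance, and the estimator then raises a distinct
"undefined anisotropy" condition rather than returning an arbitrary number.

### Noise and error propagation

Phase noise enters both moments. `background_noise()` estimates the noise
standard deviation of each moment from a tissue-free region by subdividing
it into 32 × 32-pixel blocks (all pixels in-mask), computing per-block
moments, and scaling the across-block dispersion to the full region size
(sd/√K). The block estimator was validated against a repeated-realization
Monte-Carlo oracle (independent noise fields, full-region moments) to within
15%.

`g_uncertainty()` propagates those standard deviations to first order,

$$ \sigma_g^2 = \left(\frac{\partial g}{\partial a}\right)^2 \sigma_a^2 +
               \left(\frac{\partial g}{\partial b}\right)^2 \sigma_b^2, $$

with $a$ the gradient term and $b$ the variance term. The quadrature sum
assumes *independent* moment errors; that is a property of this error model,
not of our implementation — noise injected at the image level induces
correlated moment errors (both moments rise with added noise), so the
Monte-Carlo check perturbs the moments, matching the model's own assumption.
Zero noise propagates to exactly zero uncertainty.

### Mosaics

Tiled acquisitions (`tile_grid()`, default geometry 10 × 10 tiles of
1388 × 1040 px) are stitched at nominal grid offsets with averaging in
overlap zones — no cross-correlation registration, since synthetic tiles
have exact offsets and registration is out of scope. `crop_core()` takes a
centered square; when the margin to remove is odd, the extra removed pixel
is taken from the trailing (bottom/right) side. Both operations are lossless
round trips outside blend zones.

## 2. The independent oracle

`farfield_spectrum()` realizes the far field of the ROI by Fourier optics:
out-of-mask pixels are replaced by the mean in-mask transmission, a
*periodic* Hann window suppresses leakage from the box edges (periodic so a
constant input occupies exactly the 3-bin window kernel), and the squared
modulus of the FFT gives intensity over spatial frequency. For fitting, the
coherent (specular, unscattered) component is removed by subtracting the
mean transmission before the transform (`subtract_specular = TRUE`, used by
`anisotropy_from_oracle()`); the raw spectrum keeps the DC beam.

`angular_profile()` maps $q \mapsto \theta = \arcsin(q/k_0)$, excludes
$q = 0$ and evanescent frequencies, respects the NA collection cone
(0.75 → 48.6°), and azimuthally averages into equal-width $\theta$ bins.
Empty bins are reported as missing, never as zero intensity.

`fit_hg()` fits $c\,p_{HG}(\theta; g)$ by unweighted nonlinear least squares
over a configurable window ((2°, 45°] by default; the lower cut keeps
residual specular leakage out). The optimizer works in
$(\operatorname{atanh} g, \log c)$, starts at $g = 0.9$ with restarts at
0.5 and 0.99, and polishes with Nelder-Mead; it is deterministic given the
profile. On noiseless HG-sampled profiles it recovers $g$ to better than
$10^{-4}$ — the exact-recovery oracle of the test suite. Flat profiles
return $g = 0$ with a warning. Whether the original analysis fit the
solid-angle-weighted or raw profile, and over which angular window, is not
documented anywhere we could rely on; both are configuration choices here,
with the defaults above.

### Why cross-method agreement constrains the texture model

The acceptance property "theorem and HG fit agree within 0.02 for
$g \in [0.85, 0.98]$" is a statement about tissue, and it quietly constrains
what a faithful synthetic stroma must look like. If a texture's in-band
angular profile is *exactly* HG-shaped, the fit returns the shape parameter,
but the theorem returns the in-band second moment, which for a truncated HG
distribution exceeds the shape parameter by 0.03–0.11 over that range — the
HG tail beyond the collection cone carries the difference. Conversely,
single-scale Gaussian or exponential-correlation textures disagree by
0.05–0.3 in the other direction. No single-scale texture can satisfy the
property; tissue that satisfies it (as the reference measurements did, 0.932
vs 0.928) must combine a forward lobe with fine-scale structure.

`gen_scattering_texture()` is therefore built as a two-component Gaussian
field: an HG($g$)-shaped forward lobe (coarse fiber bundles) plus a
quasi-periodic fine-fibril component appearing as a diffraction ring at
$q = 7.2$ rad/µm ($\theta \approx 39°$). The ring's energy weight is *not a
free dial*: it is fixed in closed form by requiring the total in-band second
moment — evaluated with the discrete central-difference response
$\sin(qh)/h$, i.e. the operator the estimator actually applies — to equal
$2k_0^2(1-g)$. On these fields both measurement routes define the same $g$,
and the sweep tests fit the forward lobe over (2°, 20°], excluding the
fibril ring, averaging the angular profile over four independent fields the
way a large stitched tissue region averages speckle spatially.

## 3. The synthetic world

The generators provide ground truth for every downstream stage. What they
emulate, and what they do not:

* **`gen_grf_phase()`** — stationary Gaussian fields with exact (circulant,
  spectrally synthesized) Gaussian covariance
  $C(r) = \sigma_\phi^2 e^{-|r|^2/\ell_c^2}$. Because
  $\langle|\nabla\phi|^2\rangle = 4\sigma_\phi^2/\ell_c^2$, the anisotropy
  $g = 1 - 2/(k_0^2\ell_c^2)$ is known analytically (0.938 at
  $\ell_c = 0.5$ µm, 552 nm) — the package's primary oracle. These fields
  are *not* realistic stroma; they are the analytic test bed.
* **`gen_fiber_texture()`** — anisotropic Gaussian fields with correlation
  length `anisotropy_ratio × corr_len` along the fiber axis. Fragmentation
  is modeled as a *continuous shortening of the along-fiber correlation
  length* toward the across-fiber value. We first implemented literal gap
  masking (thresholded gap fields replacing fiber texture); it looks right
  but makes $g$ *non-monotone* in the gap fraction — boundary density peaks
  at intermediate coverage, so $g$ dips and then recovers. The
  correlation-shortening model satisfies the limiting case exactly (full
  fragmentation collapses along-fiber correlation to the across-fiber
  value) and makes $g$(fragmentation) strictly decreasing via the closed
  form — which is the biological claim being modeled: more fractionated
  stroma scatters more isotropically.
* **`gen_core_image()`** — a tissue-core layout: harmonic-perturbed
  elliptical gland lumens (low phase) punched into fiber-textured stroma,
  with per-gland stromal ROIs as morphological bands of configurable width
  (default 10 px; real hand-drawn regions vary with gland size, hence a
  parameter). Bands start 2 px clear of every gland boundary so that
  central-difference gradients never straddle the stroma/lumen step.
* **`gen_cohort()`** — matched patient groups whose *patient-level* g
  distributions are calibrated to the reference summaries (recurrent
  0.911 ± 0.039, median 0.921; non-recurrent 0.935 ± 0.031, median 0.945).
  The required skew offsets, $(\mathrm{median}-\mathrm{mean})/\mathrm{sd} =
  0.256$ and $0.323$, exceed what a skew-normal (max ≈ 0.205) or log-normal
  (max ≈ 0.30) can represent, so the three-parameter family is a *reflected
  gamma*, $g = c - \Gamma(k, \vartheta)$: the shape solves
  $(k - q_{50}(k))/\sqrt{k}$ = offset on its decreasing branch, then scale
  and location follow in closed form, and infeasible targets (offset
  ≳ 0.40) raise a calibration error. Per-ROI values add small
  within-patient noise (sd 0.01) so that patient means still reproduce the
  targets within the 1% Monte-Carlo criterion at $n = 10^4$. Covariates
  (age, race, Gleason patterns, stage) are drawn once per matched pair; PSA
  is log-normal (meanlog log 8, sdlog 0.8 — a realistic post-biopsy
  distribution putting ~10% of patients above 20 ng/ml) and *independent of
  g*, so stratified AUCs are flat across PSA by construction. Exactly
  `n_unscorable` patients (default 20, mirroring the reference cohort's
  exclusions) have one CAPRA-S field blanked.
* **`gen_psa_series()`** — piecewise-exponential post-surgical PSA:
  non-recurrent series are noisy nadirs capped below 0.2 ng/ml (no clause of
  the recurrence rule can fire); recurrent series rise exponentially and are
  guaranteed past 0.4 ng/ml. Only the classification rule's behavior
  matters; the trajectories make no pharmacokinetic claim.

Every generator is a pure function of its spec including the seed (the
caller's RNG stream is never disturbed). A green test on this world
establishes that the estimators and statistics are implemented correctly and
are mutually consistent; it does **not** establish clinical performance —
the cohort-level AUC ≈ 0.72 emerges from the calibrated group summaries, not
from tissue.

## 4. Patient-level statistics

* Aggregation to one g per patient is the arithmetic mean of the 12–16 ROI
  values (median available); the aggregation rule is not documented in the
  source methodology, so it is explicit and recorded in provenance.
* The two-sample test is Welch's (unequal variances), callable from raw
  samples or directly from published (mean, sd, n) summaries — the two paths
  agree exactly by construction. From the printed reference summaries the
  recomputed $p = 8.5\times10^{-6}$; the printed $7.66\times10^{-6}$ lies
  inside the interval induced by the inputs' 3-decimal rounding, which is
  the strongest statement those inputs support.
* ROC AUC uses the rank (Mann-Whitney) estimator with midranks for ties,
  validated against exhaustive pair counting; *lower* g scores toward the
  recurrent class (direction configurable for scores like CAPRA-S that rise
  with risk). The bootstrap CI (percentile, seeded) resamples patients.
* The decision rule is strict: predict recurrence when $g <$ threshold
  (default 0.938); a patient exactly at the threshold is predicted
  non-recurrent. `youden_threshold()` maximizes sensitivity + specificity −
  1 over data-relative candidate cut points (midpoints plus sentinels, so
  the threshold is shift-equivariant), breaking ties toward the higher
  threshold.
* CAPRA-S: PSA ≤ 6 → 0, (6, 10] → 1, (10, 20] → 2, > 20 → 3; Gleason sum
  ≤ 6 → 0, 3+4 → 1, 4+3 → 2 (any Gleason-7 with primary ≥ 4 counts as 4+3),
  sum 8–10 → 3; margins +2, SVI +2, ECE +1, LNI +1; total 0–12. The point
  table ships as an editable CSV (`inst/extdata/capra_s_points.csv`) so it
  can be corrected without code changes. Any missing field raises an
  "unscorable" error naming the field — partial scores are never returned —
  and the report layer counts such exclusions.
* Biochemical recurrence: TRUE if any PSA value exceeds 0.4 ng/ml, or if
  some value $v_i > 0.2$ is followed by two later values forming a strictly
  increasing run above it ($i < j < k$, $v_i < v_j < v_k$, not necessarily
  consecutive — the most permissive faithful reading). Note a limitation of
  *any* such rule: it is not globally monotone in the measurements. Raising
  the middle of `[0.25, 0.30, 0.35]` to 0.36 breaks the increasing run
  without tripping the 0.4 clause, flipping TRUE to FALSE. The property
  tests therefore assert the monotone sub-properties that do hold (raising
  any value past 0.4 forces TRUE; appending larger values never un-recurs a
  series), and this caveat is documented rather than papered over.
* PSA strata follow the CAPRA-S ranges with left-open intervals —
  (0, 6], (6, 10], (10, 20], (20, ∞) — so PSA 6.0 belongs to the first
  stratum and 6.01 to the second. Strata with one class report NA AUCs
  ("undefined"), never a fabricated 0.5.

## 5. Key parameters

| parameter | default | units | why |
|---|---|---|---|
| `wavelength_nm` | 552 | nm | white-light phase-contrast center wavelength |
| `na` | 0.75 | — | 40×/0.75 objective; caps $\theta$ at 48.6° |
| `pixel_size_um` | 0.05 | µm/px | 40× camera sampling |
| `variant` | "A" | — | moment combination validated by both oracles |
| `band_width_px` | 10 | px | stromal band width; anatomically variable |
| `fit_theta_min`, `fit_theta_max` | 2, 45 | deg | specular exclusion; NA cone |
| `fit_n_bins` | 90 | — | 0.5° resolution over the fit window |
| `threshold_g` | 0.938 | — | reference decision threshold |
| `bin_width` | 0.01 | — | histogram bin width |
| `strata` | 6, 10, 20 | ng/ml | CAPRA-S PSA ranges |
| `block_size` (noise) | 32 | px | background subdivision granularity |

## 6. Numerical choices and conventions

* GRF synthesis samples the target covariance on the torus and filters white
  noise with $\sqrt{\widehat C}$ — exact up to wrap-around, negligible when
  the domain spans many correlation lengths; tiny negative FFT leakage in
  $\widehat C$ is clipped at zero.
* TIFF I/O is a minimal uncompressed little-endian baseline codec (32-bit
  float grayscale, 8-bit masks, metadata as JSON in ImageDescription),
  written because the deployment R stack has no TIFF package; it reads what
  it writes plus plain uncompressed grayscale TIFFs, and interoperates with
  `tifffile`.
* Configs serialize as JSON (`jsonlite`), not YAML — no YAML parser is
  guaranteed in the deployment stack, and flat key/value content is
  identical either way.
* All error conditions are classed (`parameter`, `data`, `stat`, `io`,
  `undefined_anisotropy`, `unscorable`) and the CLI maps them to exit codes
  0/2/3/4.
* Seeds: every generator takes one; derived child seeds stay below $2^{31}$.

## 7. Known limitations

* The theorem estimator degrades outside the forward-scattering regime
  ($g \lesssim 0.8$) and on fields whose spectra extend beyond the NA; the
  out-of-range flag is the symptom to watch.
* The synthetic stroma reproduces second-order statistics and the dual-route
  consistency of tissue, not its morphology; no nuclei, no glands-within-
  glands, no H&E appearance, no raw interferograms.
* Stitching uses nominal offsets only; real mosaics with stage drift would
  need registration upstream.
* The cohort generator draws PSA independently of g; the weak negative
  correlation reported on real tissue (r ≈ −0.12) is not emulated, and the
  synthetic cohort's Pearson r is therefore near zero.
* No survival modeling: recurrence is a binary endpoint, as in the source
  analysis.
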