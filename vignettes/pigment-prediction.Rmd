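---
title: "Predicting carrot pigment content from calibrated root colour: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting carrot pigment content from calibrated root colour: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carotlab)
```

## Overview

`carotlab` models the relationship between the flesh colour of carrot root
disks, measured from calibrated digital images, and their pigment content
(total carotenoids, total monomeric anthocyanins, and the individual
carotenoids lutein, α-carotene and β-carotene) measured by wet-lab assays.
The pipeline has four scientific layers, and each is exposed as ordinary R
functions so any stage can be used, tested or replaced on its own:

1. **colour calibration** against a 24-chip checker present in every image;
2. **colour measurement**: polygon regions of interest, mean ± SD RGB,
   conversion to CIELab and the cylindrical LCh coordinates;
3. **pigment chemistry**: spectrophotometric equations converting
   absorbance readings to contents in mg per 100 g fresh weight;
4. **chemometrics**: partial least squares regression of content on the
   five colour parameters, cross-validated in ten random segments.

## The regression model and why PLS

The predictors are the five CIELab/Ch colour parameters
$(L^*, a^*, b^*, C^*, h^\circ)$ with $C^* = \sqrt{a^{*2} + b^{*2}}$ and
$h^\circ = \mathrm{atan2}(b^*, a^*)$ in degrees on $[0, 360)$. Because
$C^*$ and $h^\circ$ are deterministic functions of $a^*$ and $b^*$, the
design is strongly multicollinear; in degenerate data it is exactly
rank-deficient, and `fit_multiple_linear()` deliberately fails there,
naming the collinear columns. PLS handles this by regressing on latent
components that maximise the covariance between the standardized
predictors and the response.

`fit_pls()` implements single-response NIPALS. Both $X$ and $y$ are
z-scored (each variable centred and divided by its standard deviation), so
that high-variance colour parameters do not dominate the leading
components. Components are extracted sequentially: the weight vector is
the normalised covariance $X_d^\top y_d$ of the deflated data, scores are
$t = X_d w$, and $X_d$, $y_d$ are deflated by the loadings after each
step. The final model is back-transformed to original units, intercept
included, so coefficients can be read in mg/100 g per colour unit. Two
structural identities are enforced by tests rather than assumed:

* with as many components as predictors on a full-rank design, the PLS
  solution equals ordinary least squares (closed-form limit);
* predicting through the latent path and through the back-transformed
  coefficient vector must agree to $10^{-9}$.

Five components is the default and the maximum: with five predictors a
larger latent space has no meaning.

The coefficient of determination is reported two ways, since reported
"explained variance" in applied work is ambiguous: `r2_ss` ($1 -
\mathrm{SSE}/\mathrm{SST}$, the default shown in reports) and
`r2_pearson` (squared correlation of fitted and observed). They coincide
for least-squares-like fits at full rank.

### Cross-validation

`cross_validate()` splits the $n$ samples into ten near-equal segments by
a seeded random permutation; each segment is predicted once from a model
calibrated on the other nine. Standardisation parameters are re-estimated
inside every training fold — the alternative (standardising once,
globally) leaks the held-out samples' location into the calibration and
systematically flatters RMSEP, so it is not offered. Held-out predictions
are reverted to original units before the error is formed:
$\mathrm{RMSEP} = \sqrt{\tfrac1n \sum (\hat y_{-i} - y_i)^2}$, and the
relative form divides by the mean observed content (a range-based
denominator is an easy variant but the mean is the default and the one
reported). The segment seed is a required argument everywhere, and the
pipeline logs it.

## Colour calibration

Every scene contains the classic 24-chip colour checker. Chips are read
by `measure_chips()` as the mean of interior pixels after trimming a 20 %
margin per side (border pixels carry edge gradients and overlay strokes).
`fit_calibration()` regresses the known sRGB reference chip values on the
measured values, per output channel, over one of two bases:

* `linear`: $[1, R, G, B]$ (4 terms);
* `quadratic_cross_band` (default): $[1, R, G, B, R^2, G^2, B^2, RG, RB,
  GB]$ (10 terms) — the cross-band products let one channel correct
  another, which is what absorbs white-balance and tone-curve errors.

The fit is ordinary least squares in *encoded* (gamma) sRGB space on
0–255 values. Fitting in encoded space mirrors the image-editor workflow
the method is meant to reproduce; a physically linear-light fit is a
one-line change (decode first) but changes the fitted coefficients, so
the choice is fixed and documented. Calibration quality is summarised as
the mean CIE76 $\Delta E^*_{ab}$ (Euclidean distance in Lab) between
calibrated and reference chips. CIE76 rather than CIEDE2000 because the
quantity is a fit diagnostic, not a perceptual claim, and the simplest
metric is the most reproducible; the conversion illuminant is
configurable.

Calibration is fitted **per light condition** (indeed per image, since
each scene carries its own checker): exposure and polarisation change the
effective transfer function, so one global model would fold condition
differences into colour. Applying a model to an image from another
condition is allowed but flagged in the log.

## Colour spaces

`srgb_to_lab()` is the standard pipeline — piecewise sRGB decoding, the
sRGB primary matrix into CIE XYZ, then Lab against a chosen reference
white — with the exact inverse provided. Defaults follow the imaging
protocol the package targets: D65 with the 1964 10° observer. Two
subtleties are deliberate:

* no chromatic adaptation transform is applied. sRGB's native white is
  D65/2°, so under the default D65/10° white point a pure white pixel
  maps to $|a^*|, |b^*| \approx 1$ rather than exactly 0. This mirrors
  the common applied-colorimetry convention of selecting the 10° observer
  without adapting, and both observers (and D55) are selectable;
* hue is computed with the two-argument arctangent and reported in
  degrees; $a^* = b^* = 0$ has no hue, is reported as 0°, and flagged via
  an attribute rather than silently.

## Pigment chemistry

Total carotenoids (TCC) from absorbances at 662, 645 and 470 nm:

$$C_a = 11.75\,A_{662} - 2.35\,A_{645}, \qquad
  C_b = 18.61\,A_{645} - 3.96\,A_{662},$$
$$C_{x+c} = (1000\,A_{470} - 2.27\,C_a - 81.4\,C_b)/227 \quad
  [\mu g/mL].$$

Total monomeric anthocyanins (TAC) by the pH-differential method:

$$A = (A_{520} - A_{700})_{pH\,1.0} - (A_{520} - A_{700})_{pH\,4.5},
  \qquad \mathrm{TAC} = A \cdot MW \cdot DF \cdot 1000 / EF \quad [mg/L],$$

with cyanidin-3-glucoside constants $MW = 449.2$ g/mol and $EF = 26\,900$
L mol⁻¹ cm⁻¹ as defaults — they are the standard constants for the assay
but remain explicit arguments, never hard-coded, because other reference
anthocyanins are in use. Absorbances are divided by the optical path
length (default 1 cm) before the equations; microplate readers often have
sub-centimetre paths and the equations assume 1 cm. Duplicate extractions
may be passed as matrix columns and are averaged at the absorbance level.

Concentrations convert to fresh-weight contents as
$$\mathrm{mg}/100\,\mathrm{g\,FW} = C \cdot V / (10\, m) \cdot
  (1 - \mathrm{moisture}),$$
with $V$ the extract volume (mL) and $m$ the assayed dry mass (g). Bench
bookkeeping differs between labs, so every factor is an explicit input
and the formula is documented rather than hidden; the identities
"doubling the mass halves the content" and "content is linear in
$(1-\mathrm{moisture})$" are tested. Moisture fractions are per-cultivar
inputs — the synthetic study supplies them; real use must provide them.

Small negative concentrations beyond $-10^{-9}$ raise an error
(inconsistent readings); round-off negatives are clamped to zero.

### Sample filters

`apply_content_filters()` encodes the pre-modelling exclusion rules, each
removal carrying a reason code so sample counts are conserved:

| pigment | rule |
|---|---|
| TCC, TAC | drop below 0.25 mg/100 g (spectrophotometric totals near zero in strongly coloured roots are likely false positives) |
| TAC | additionally drop the red cultivar (single sample, minimal content) |
| lutein, α-, β-carotene | drop fully purple cultivars; keep sub-threshold rows down to the HPLC detection limit 0.025 mg/100 g |
| lycopene | not modelled (present in a single cultivar) |

## The synthetic study

`study_design()` + `generate_study()` produce a complete emulated study:
16 cultivars (one white, two yellow, nine orange, one red, two fully
purple, one purple with yellow core) × 6 replicate disks × 6 light
conditions, one rendered checker-plus-disks scene per cultivar and
condition, a ground-truth table, and a wet-lab absorbance table obtained
by algebraically inverting the pigment equations (so chemistry recovers
truth exactly when assay noise is zero).

Design choices, made once:

* **Cultivar colours** are hand-set to occupy the four clusters seen in
  diverse carrot panels — white highest $L^*$, purple lowest, yellow low
  $a^*$/high $b^*$, orange/red high $a^*$ — with within-cultivar SD of
  (1.5, 1.2, 1.5) Lab units per channel, a realistic disk-to-disk spread
  for replicate roots of one cultivar.
* **The colour→pigment link is linear in the five predictors with
  additive Gaussian noise** (SD 0.5 mg/100 g for TCC, 3 for TAC) — the
  generative inverse of the model the package fits, which is what makes
  parameter recovery a meaningful end-to-end check. Link coefficients are
  solved from cluster-level content targets (orange ≈ 8.5–9.5, red ≈ 13–15,
  purple-yellow ≈ 5–7, others low for TCC; fully purple ≈ 40 for TAC)
  with a ridge penalty on the slopes, heavier on hue. The penalty keeps
  the link gentle enough that it stays positive with comfortable margin
  at every cluster: contents are physical concentrations and draws are
  truncated at zero, so a well-specified design must make truncation
  rare, not structural. Hue receives the extra penalty because its 0/360°
  wrap makes steep hue dependence unphysical.
* **Light conditions** combine the two environments (WF unpolarised, PF
  polarised) with relative exposure steps. Distortion is per-channel gain
  $2^{k\,\mathrm{step}}$ ($k = 0.06$), a small per-condition channel
  offset, and a tone-curve gamma in 0.96–1.06 — the simplest family that
  makes per-condition calibration necessary. Specular glare (moisture
  reflection on fresh-cut disks) is a localized Gaussian highlight per
  disk, present only in the WF environment: polarisation suppresses it.
  Its amplitude strictly increases mean disk $L^*$, and a test asserts
  that monotonicity.
* **Anthocyanin assay availability** mirrors realistic sampling: all six
  replicates for the first purple and the purple-yellow cultivar, three
  for the second purple, one for the red.
* **Scenes** are 140 × 168 px with a 6 × 4 chip grid and up to six disks;
  pixel values are quantised to 8 bits (quantisation alone leaves the
  noiseless colour round trip below 0.5 ΔE). Per-pixel sensor noise
  (SD 1.5) applies after the condition distortion.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: photorealistic texture, peel/core
colour gradients within a disk, camera optics and demosaicing, and above
all the large *genotypic* within-cultivar pigment variability of real
roots. Real studies report within-cultivar content ranges of several
mg/100 g that colour does not explain; the synthetic link's noise is
deliberately small and well-specified, so pipeline R² on synthetic data
(≈ 0.98–0.99) is far higher than is achievable in the field (≈ 0.7–0.8),
and cross-validated RMSEP sits at the generative noise SD rather than at
field-realistic 30–40 % relative error. The synthetic study validates the
*machinery* — calibration inversion, colour recovery, equation algebra,
model and CV correctness — not field-level predictive performance.

## Numerical and interface choices

* **Polygon rasterisation** uses the even-odd rule with pixel centres
  tested at $(x + 0.5, y + 0.5)$ in 0-based coordinates; the same polygon
  therefore yields the identical mask on every image of equal shape,
  which is what lets one hand-drawn region serve all six conditions of a
  sample. Degenerate (zero-area) polygons error.
* **ROI statistics** use the population SD: the pixels are the entire
  population of the region, and at typical disk counts (hundreds of
  pixels) the $n$ vs $n-1$ distinction is immaterial. Descriptive
  per-cultivar tables use the sample SD, matching "mean ± SD" conventions.
* **Calibrated values are clipped** to [0, 255]; the polynomial can
  legitimately leave the gamut.
* **Rank checks**: the calibration design and the multiple-linear design
  are QR-rank-checked and fail with the offending columns named, rather
  than silently pseudo-inverting.
* **Determinism**: a seed fully determines the synthetic study, the CV
  segmentation and hence the whole pipeline; re-running a stage from its
  persisted inputs reproduces outputs byte for byte. The modelling stage
  always re-reads the persisted contents table so that in-memory and
  from-disk runs cannot diverge through CSV round-off.
* **Reference equations** from the published study (two total-pigment
  equations under each of the two best conditions, plus the
  default-condition models for all pigments) ship as a versioned JSON
  file; `compare_to_reference()` reports signed coefficient differences,
  cosine similarity and sign agreement. The two printed versions of the
  default-condition total-carotenoid equation differ from each other;
  both are shipped verbatim and the package does not arbitrate between
  them. Reproducing the published R²/RMSEP values themselves requires the
  deposited field dataset and is outside the offline test surface.

## Problem sizes used in tests

The shipped test suite and acceptance script run the full default study
(96 roots × 6 conditions, 96 rendered scenes) once through the complete
pipeline, repeat the truth-table generation (without rendering) across
30–50 seeds for link recovery, and use 200 random 30 × 5 designs for the
PLS-equals-OLS limit — sizes chosen to make the statistical assertions
sharp while keeping a full run in the order of a minute.

## Known limitations

* Checker chips are located by layout coordinates; there is no automatic
  checker detection.
* Disk segmentation is the user's responsibility via polygon placement
  (peel and background exclusion included).
* The individual-carotenoid models inherit whatever table the HPLC stage
  provides; peak integration is out of scope.
* CIE76 only; no CIEDE2000, CAM16 or spectral rendering.
* The linear link and Gaussian noise of the generator are a deliberate
  idealisation, as discussed above.
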