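---
title: "Validating dentin-reaction imaging: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating dentin-reaction imaging: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentinval)
```

## The problem

Ground sections of carious teeth are scored site by site — each site an
area of roughly 150 µm × 150 µm in the outer dentin — as normal, carious
(demineralised) or sclerotic (hypermineralized) dentin, by six imaging
techniques: wet and dry stereomicroscopy (SW, SD), microradiography under
three contrast conditions (NFNBC, NFBC, FBC) and polarized light
microscopy in quinoline (PLMQ). Microradiographic gray level tracks
mineral content directly, which makes the contrast-corrected FBC image the
natural reference; stereomicroscopic translucency and birefringence are
optical proxies whose fidelity is exactly what is under test. `dentinval`
implements that validation: concordance statistics between techniques,
effect sizes between validation designs, and gray-level photometry of the
translucency/radiopacity relationship.

## Score tables and the canonical class map

A score table holds one row per histological site with raw per-technique
codes (1–3; 1–2 for PLMQ). The cross-vocabulary identification —
stereomicroscopic "translucent", microradiographic "hypermineralized" and
canonical `SCLEROTIC` are one class — is fixed at the type level, because
the validation tabulates them as one column throughout. PLMQ structurally
lacks the class: it scores birefringence sign only, and no sclerosis call
is ever attempted with it. Validation is strict on read (code ranges per
technique, unique site keys, ICDAS 0–6) and missing cells survive a
read/write round trip; a `dialect` map rebinds nonstandard CSV headers at
read time because deposited supplements rarely agree on column names.

## Concordance

The scores are three-class but the reported statistics are 2×2, so a
binarization rule is needed. We use one-vs-rest per reaction: a site is
positive when its canonical class equals the reaction under study. This is
the only reduction whose per-reaction TP/FP/TN/FN reconcile with the
published per-technique detection counts, and it makes accuracy symmetric
in test and gold. Only sites scored by both techniques enter
(pairwise-complete case analysis).

When PLMQ is the test technique, sites the gold calls `SCLEROTIC` have no
expressible correct answer. Two policies are implemented:

* `exclude_unscorable` (default): drop such sites; `n_effective` shrinks.
* `include_as_negative`: keep them as gold-negative for the reaction
  under study (a sensitivity analysis — it penalizes PLMQ for a class it
  never claims to detect).

The published PLMQ accuracies are consistent with slightly different
denominators for the normal and carious rows, which neither policy alone
reproduces; both are therefore exposed and neither is asserted as *the*
rule. Undefined PPV/NPV (zero test-positives or test-negatives) are
reported as missing, never coerced to 0 or 1. Cohen's kappa for examiner
calibration uses the standard marginal-product chance correction and is
defined as 1 in the doubly degenerate all-agree case.

Printed-precision conventions: accuracies are displayed to 4 decimals and
predictive values to 2, matching the precision of the published tables;
objects keep full precision internally. When integer confusion counts are
rebuilt from printed proportions (`reconstruct_confusion()`), rounding is
half-away-from-zero — base R's half-to-even would make the reconstruction
depend on the parity of neighbouring counts.

## Effect sizes

The arcsine transform is implemented as φ(P) = 2·arcsin(√P). The radical
matters: the worked values published alongside the analysis (0.154, 0.043,
0.044 from predictive values 0.26/0.31/0.33 and 0.94/0.95) are reproduced
only with the square root, which is also the standard variance-stabilizing
form of Cohen's h. The implementation computes h = φ(p_test) − φ(p_gold);
the published effect-size table prints signs consistent with the opposite
order, so table-level comparisons are made on magnitude, where the two
conventions coincide. Magnitude labels follow the conventional bands
(negligible < 0.2 ≤ small < 0.5 ≤ moderate < 0.8 ≤ large), consistent with
the 0.5 "acceptable difference" threshold used to interpret the results.

The temporary-gold-standard procedure takes, per reaction, the technique
with the largest detection count as reference; every count becomes a
proportion of that maximum and is compared to 1 by h. Ties are broken by a
fixed technique order (SW, SD, NFNBC, NFBC, FBC, PLMQ) with a warning —
argmax over small counts is otherwise not reproducible.

```{r}
temporary_gold(reference_table("counts"), "SCLEROTIC")
```

## Photometry

* **Site statistic**: the arithmetic mean of the ROI's gray levels. A
  region mean is the least noisy unbiased choice when the underlying site
  is homogeneous at the 150 µm scale, which the site-selection protocol
  aims for.
* **Optical indices**: (I_ext − ΔI)/I_ext with ΔI = |I_site − I_ext|,
  I_ext the histogram maximum for radiopacity (where the formula reduces
  algebraically to I_site/I_max and is invariant to rescaling all gray
  levels) and the minimum for translucency. The translucency form can go
  negative when I_site > 2·I_min; such values are preserved and flagged,
  not clipped — clipping would silently hide a miscalibrated background.
* **Saturation QC**: pass iff the histogram maximum is strictly below 0.8
  of the representable maximum (204 at 8 bits). Failing images still
  yield indices, with a warning, so a QC failure is visible rather than
  fatal.
* **Normalization before correlation**: min–max across the measured
  sites. It is the only order-preserving, affine-invariant rescaling with
  no free parameters.
* **Correlation**: Pearson r with the *adjusted*
  R² = 1 − (1 − r²)(n − 1)/(n − 2). Plain r² cannot be negative; the
  adjusted form is the statistic that produces the small negative values
  a null association yields (at r = 0, n = 80 it is exactly
  1 − 79/78 ≈ −0.0128).

## Illumination fitting

Vignetting is characterized from 1-D profiles: the image is normalized by
its maximum gray level, averaged over rows to give the x profile and over
columns to give the y profile, and each profile is fitted by least squares
to `baseline + height·exp(−(t − μ)²/2σ²)` or `baseline + slope·t`. The
reported height is the mean fitted amplitude over the two axes (for the
linear model, |slope| × span, the total rise across the field); the
goodness of fit is the adjusted R² of the pooled two-axis fit, which is
≤ 0 for a structureless field. The axis-handling convention (which axis is
averaged, how amplitudes are combined) is this module's own; nothing in
the underlying measurement fixes a 1-D versus 2-D choice.

Numerical safeguards, all visible in the returned object:

* a coarse grid over (μ, σ) with baseline/amplitude solved linearly
  initializes the Levenberg–Marquardt polish (`minpack.lm::nlsLM`); if
  the polish fails the grid solution is returned flagged non-converged;
* σ is constrained to at most 0.6 of the axis length. A Gaussian much
  wider than the field of view is not identifiable from it — amplitude
  and baseline trade off along a flat ridge — so wider candidates are
  reported at the constraint rather than with an arbitrary amplitude;
* a numerically flat profile short-circuits to height 0 (nothing to fit);
* regions holding specimen structure (the measured site ROIs) can be
  excluded: every row intersecting an excluded region is dropped from the
  x profile and every column from the y profile, so both profiles average
  identical background pixels at every position and keep their shape.
  `cmd_photometry()` always excludes the measured sites this way.

## The synthetic-data generators

The generators define the conditions under which the pipeline is tested;
their defaults are the study conditions, chosen once.

**Score tables.** A latent gold class is drawn per site from marginals
equal to the FBC detection counts (59/89/20 of 168); each technique's
score is drawn conditionally independently from a per-technique confusion
row given the gold class. FBC's row is the identity, so its column *is*
the latent reference, mirroring the role of the contrast-corrected image
in the validation design. The other rows were chosen once to emulate the
qualitative biases the validation exposed — stereomicroscopy over-calls
translucency, PLMQ reads most demineralised and many sclerotic sites as
negatively birefringent — and are deliberately round numbers, not fitted
values. Conditional independence given one latent class is the simplest
structure that produces tables with the observed shape while keeping
recovery targets analytic.

**Micrographs.** Each scenario yields an SM-like patch (dark background at
0.2 of full scale — its histogram minimum — with brighter dentin sites)
and an MR-like patch (bright field at 0.75 of full scale — its histogram
maximum, below the saturation gate — with radiolucent sites), sharing a
multiplicative separable vignette `(1 − h) + h·exp(−(t − c)²/2σ²)` per
axis (σ = 0.45 × axis length, so the fall-off is identifiable within the
field) and additive Gaussian noise. Site ROI gray levels are set so the
optical-index formulas return the assigned truth exactly in the
noise-free flat-field limit (`I_site = radiopacity·I_max`;
`I_site = (2 − translucency)·I_min`); under a non-flat vignette the
background extremes shift with the field and recovery acquires the same
flat-field error a real acquisition would. True per-site translucency and
radiopacity are joined by a Gaussian copula with correlation ρ over the
range [0.2, 0.9] — one parameter controls the null (ρ = 0) and alternative
of the correlation experiment. `study_fixtures()` bundles the study
geometry: one 168-site table and five patch pairs of 16 sites each
(80 sites), with a nearly flat Gaussian vignette of height 0.028 and
noise of 2 gray levels, all derived from one seed.

What the generators do **not** emulate: dentin microanatomy (tubules,
lesion geometry — patches are statistical, not anatomical), registration
error between the SM and MR images of a site, examiner disagreement
within a technique, or spatially correlated noise. Passing recovery tests
therefore demonstrates the estimators' correctness under the stated
statistical model, not robustness to those real-data effects.

All generators are pure functions of (spec, seed): a single seeded RNG is
used locally and the caller's RNG state is restored afterwards.

## Problem sizes used in the shipped tests

Parameter-recovery checks run at 5000 sites (agreement probabilities,
judged against family-wise 95% normal confidence intervals with a
Bonferroni correction across the 17 technique × gold-class cells), 20-seed
sweeps for vignette-height recovery (±0.02 at heights 0.13 and 0.05 under
noise), 200 random tables of up to 50 sites against a brute-force
confusion-matrix oracle, and 1000 replicates of the 80-site ρ = 0 scenario
(96 × 96 px patches) for the null-correlation frequency bound. These sizes
give the checks stable pass/fail behaviour at desk scale.

## Known limitations

* The published per-site supplement is not redistributable, so
  deposited-data checks run on a synthetic emulation of its structure;
  the ingestion path (`read_score_table()` with a dialect map) is what
  would consume the real file.
* The PLMQ accuracy-denominator ambiguity above is surfaced, not
  resolved.
* Effect sizes carry no inferential machinery (no CIs or tests on h);
  the validation design reports magnitudes only.
* Illumination characterization is 1-D by convention; a strongly
  non-separable or tilted vignette would be summarized, not recovered.
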