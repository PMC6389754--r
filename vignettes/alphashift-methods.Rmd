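---
title: "Methods: quantifying alpha-rhythm slowing and its scalp topography"
author: "alphashift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying alpha-rhythm slowing and its scalp topography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphashift)
```

## The problem

The posterior alpha rhythm (8–13 Hz) of relaxed, eyes-closed wakefulness
slows down and spreads anteriorly in many brain disorders, including the
epilepsies, where this change has been linked to how well seizures are
controlled. `alphashift` implements a complete analysis chain for testing
that association in 19-channel (10–20 system) resting EEG: spectral
quantification of the low/high alpha power balance, covariate-adjusted group
inference on the global statistic, nonparametric inference on its scalp
topography, and subject-level classification — together with a synthetic
cohort generator so the whole chain can be validated end to end without
access to recorded EEG.

## The alpha-power-shift statistic

Each 20-s segment is re-referenced to the common average and cut into 1-s
epochs with 90% overlap (hop of `round(0.1 * 256) = 26` samples at 256 Hz,
i.e. 89.84% effective overlap — the rounding keeps the epoch grid integer
and the epoch count deterministic: 188 epochs per 20-s segment). Each epoch
is demeaned per channel, multiplied by a periodic Hann taper, zero-padded
by a factor of 2 and Fourier transformed; squared moduli are averaged over
epochs and the bins at 2, 3, …, 20 Hz are retained. Power is normalized per
channel by its sum over those 19 bins, so spectra are relative and the
analysis is invariant to per-subject gain.

The outcome statistic is the **alpha-power shift**: the ratio of mean
relative power in the low-alpha band (6–9 Hz, bins 6,7,8,9 inclusive) over
mean relative power in the high-alpha band (10–11 Hz, bins 10,11), analysed
throughout on a binary-log scale,

$$\mathrm{shift} = \log_2 \frac{\mu_{\text{6–9 Hz}}}{\mu_{\text{10–11 Hz}}}.$$

Positive values indicate slowing. The log transform is adopted globally
because it stabilizes the between-group variance of the ratio. The global
(scalp-wide) shift averages the spectra across channels *first* and then
forms the ratio; the mean of per-channel log-ratios is exposed as an
alternative summary (`mean_channel_shift`) but is not the primary outcome.

Numerical choices worth knowing:

* **Zero-padding.** The padded length is twice the epoch (pad factor 2,
  0.5 Hz native resolution); integer-Hz bins remain exact DFT bins. The
  implementation evaluates the padded DFT directly at the requested bins
  with a DFT matrix, which is algebraically identical to FFT-then-subset
  and is pinned against a naive loop-based DFT oracle at `1e-8`.
* **Hann convention.** The periodic form `0.5 - 0.5 cos(2 pi n / N)` is
  used; an exactly on-bin sinusoid therefore spreads deterministically into
  its two 1-Hz neighbours with amplitude weight 1/4 each, so the peak bin
  carries 2/3 of the in-range power. Tests assert this identity rather than
  pretending the taper is transparent.
* **Normalization domain.** "Total power" for normalization is the sum over
  the extracted 2–20 Hz bins only, not the full Nyquist range; this is a
  documented convention.
* **Individual alpha frequency.** The IAF is the argmax of the
  channel-averaged relative spectrum in 6–13 Hz; exact ties resolve to the
  lower frequency.
* **Degenerate inputs.** Zero high-alpha power makes the ratio undefined
  and raises an error; segments shorter than one epoch, aliasing sampling
  rates and unknown channel labels are rejected up front.

## Group-level models

The global shift is analysed with a one-way between-subjects ANCOVA (three
groups: healthy, good and poor seizure control) with age and gender as
covariates, and with a 2×2 factorial ANCOVA on the patients only (syndrome ×
seizure control, covariates age, gender and total antiepileptic-drug load).
Both use Type III sums of squares with sum-to-zero factor coding, matching
the convention of mainstream ANCOVA software on unbalanced designs, and
report classical $\eta^2 = SS_\mathrm{effect}/SS_\mathrm{total}$. With 102
subjects, three groups and two covariates the error df is 97; the full 2×2
patient model on 63 subjects (intercept, two main effects, interaction,
three covariates) has one consistent error df of 56, which is what the
package reports for all three factorial effects.

Planned post hoc contrasts are deliberately plain pooled-variance two-sample
t-tests on the log2 shift (df $n_a + n_b - 2$, e.g. 100 and 61 at the
default group sizes), not covariate-adjusted contrasts, and are
Bonferroni-corrected within each model's family. Effect sizes are Hedges'
$g$ with the small-sample correction $J = 1 - 3/(4N - 9)$ and
percentile-bootstrap confidence intervals resampling subjects within groups
(default 5000 resamples). Assumption checks: Levene's test on absolute
deviations from group *means*, slope-homogeneity F-tests of
group-by-covariate interaction blocks, and Shapiro–Wilk on residuals.

## Scalp maps and permutation inference

Per-channel shifts are interpolated to a regular 32 × 32 node grid spanning
the bounding square of a 100-mm head circle. The "32 × 32" is read as a
node count, not a 32-mm spacing — a 32-mm raster over a ~200-mm head would
carry only ~7 nodes and could not express the smooth topographies the method
is meant to capture. Interpolation is piecewise linear on the Delaunay
triangulation of the electrode positions (idealized 10–20 spherical
coordinates, azimuthal-equidistant projection); it reproduces constants and
linear fields exactly, and nodes outside the electrodes' convex hull are
masked rather than extrapolated, so edge statistics are never driven by
unconstrained extrapolation. Maps are then smoothed with an isotropic
Gaussian kernel, σ = 8 mm (the FWHM reading of the kernel size is available
by passing σ = 8/2.355), renormalized within the mask so constants are
preserved at the boundary. Because interpolation and smoothing are both
linear, the package precomputes a single channels-to-nodes operator and
produces an entire cohort's maps with one matrix product.

Node-wise inference uses the Aspin–Welch unequal-variance t for a GLM
contrast: the model is fitted by least squares at every node, residual
variance is estimated separately per variance group with effective degrees
of freedom $n_b - \sum_{i \in b} h_i$ (leverage-corrected), and the
Welch–Satterthwaite df accompanies the statistic. With two groups and no
covariates this reduces *exactly* to the classical Welch t-test, which is
how it is tested.

Significance comes from Freedman–Lane permutation: the nuisance-only model
(columns with zero contrast weight) is fitted once, its residuals are
permuted and added back to the nuisance fit, and the full-model contrast t
is recomputed at every node; family-wise error is controlled with the
permutation distribution of the maximum statistic over unmasked nodes. The
first of `n_perm` permutations is always the identity, so
$p = \#\{t^* \ge t_\mathrm{obs}\}/n_\mathrm{perm}$, the smallest achievable
p-value is $1/n_\mathrm{perm}$, zero is never reported, and `n_perm = 1`
honestly returns p = 1 everywhere. Tests are one-sided in the contrast
direction by default (each pairwise comparison is stated directionally),
with a two-sided |t| option. When `n_perm` exceeds the number of distinct
permutations the space is enumerated exhaustively (supported to 10
subjects); with no covariates this reduces to exact label permutation, and
the test suite verifies that equivalence by brute enumeration. Node-wise
Hedges' g maps with subject-level (never node-level) bootstrap CIs
accompany each contrast, and Table-style peak summaries report the peak
statistic, its Welch df, the FWE p and the Euclidean-nearest electrode
(ties alphabetical).

## Classification

Seizure-control status is classified from the 19 per-channel log2 shifts
(the global scalar is available as an alternative feature set) with Fisher
LDA on the pooled within-class covariance, ridge-regularized by
$\epsilon \cdot \mathrm{tr}(S_w)/d$ (default $\epsilon = 10^{-6}$) for
stability, threshold at the equal-prior midpoint — the classes are
imbalanced (25 vs 38 by default) and no prior policy is imposed.
Cross-validation is stratified 10-fold, repeated 100 times by default
because single-run CV yields no spread estimate; sensitivity, specificity
(pooled out-of-fold predictions) and rank-based AUC (pooled out-of-fold
decision values, tie-corrected) are summarized as mean ± SD with
normal-approximation 95% CIs across repeats, on a percent scale.
Out-of-fold decision values are pooled *relative to each fold's threshold*;
this gives the pooled scores a common origin and makes every reported
metric exactly invariant to affine transformations of the feature space.

A z-test compares the AUC against 0.5 via the rank-sum normal approximation
with tie correction. Its null model is exchangeable scores, and the
calibration suite verifies nominal 5% rejection on that null. Pooled
cross-validation scores are *not* exchangeable — they are coupled through
shared training folds — and our null simulations show the z-test applied
directly to pooled CV scores rejects well above nominal. The test is
therefore reported as descriptive when attached to CV output; a permutation
of labels is the rigorous alternative when a decision-grade p-value is
needed.

## The synthetic cohort generator

The generator is first-class, tested code, not a fixture. Each subject's
20-s, 19-channel, 256-Hz segment is a shared narrowband alpha waveform —
random-phase spectral synthesis within peak ± bandwidth/2 under a
raised-cosine band profile, rather than a pure sinusoid, so band power has
physiological variance — scaled per channel by a posterior-to-anterior
linear amplitude gradient, plus independent per-channel 1/f-shaped
background noise (exponent 1, SD 10 by default, against a posterior alpha
amplitude of 20). The `anterior_spread` parameter interpolates between a
strictly posterior topography (0) and a spatially uniform one (1); occipital
amplitude is independent of it by construction, which the tests exploit.

Cohort defaults mirror the three-group structure the analysis targets:
39 healthy subjects and 25 good- / 38 poor-control patients; ages
30 ± 9, 33 ± 12 and 38 ± 14 years; female proportions 0.49/0.60/0.50;
gamma-distributed drug load 1.4 ± 0.9 and 1.5 ± 0.8 in the patient groups;
focal-syndrome proportions 0.40/0.71. Poor control is slower and more
anteriorized (peak 8 Hz, spread 0.6) versus 10.5 Hz / 0.2 elsewhere.
Seizure counts are negative binomial per control level — overdispersed, so
the direct shift–seizure-frequency correlation analysis can be exercised —
truncated below four for good control and shifted above four for poor
control, so the dichotomization rule (poor control ⇔ ≥ 4 seizures in 12
months) holds by construction. Between-subject variability uses
literature-typical values: individual peak frequency SD 1.0 Hz and
log-normal amplitude variation (sdlog 0.5). These were chosen for realism —
tighter values make cohorts separate almost perfectly and would make every
downstream check trivially easy, which is evidence of nothing.

What the generator does *not* emulate: interictal discharges, artifacts,
drowsiness, electrode bridging, volume-conduction correlations between the
background noise of neighbouring channels, or any syndrome-specific
topography beyond the control-level contrast. Passing tests therefore show
that the statistical machinery behaves correctly under the stated
generative model — effect directions, error control, df bookkeeping — not
that recorded clinical EEG would reproduce any particular effect size.

## Problem sizes used by the validation suites

The calibration suites run at sizes chosen to give stable estimates while
keeping the full validation runnable on a laptop: 2000 null replicates for
the ANCOVA-F and Levene rejection rates (binomial 95% band 4.0–6.0%), 500
replicates × 500 permutations on a 16-node-per-side grid for family-wise
error (band 3.1–6.9%), 200 replicates for the AUC z-test null, and 100
seeded cohort replicates (25 vs 38 subjects) for parameter recovery, where
the good-vs-poor contrast is required to exceed g = 0.8 in at least 90% of
replicates. Full-size runs (32-node grids, 10 000 permutations, 5000
bootstrap resamples, 100 CV repeats) are the package defaults for real
analyses.

## Known limitations

* The EDF writer/reader covers continuous 16-bit recordings with one
  sampling rate — the subset the pipeline produces and consumes — not the
  full EDF+ annotation model.
* Resampling is deliberately unsupported: non-256-Hz input is an error, not
  a silent conversion.
* Bonferroni correction across planned contrasts is conservative under the
  positive dependence typical of these contrasts.
* The factorial model reports one consistent error df; software that drops
  terms sequentially can print different dfs for different effects of the
  same design.
* Percentile-bootstrap CIs for Hedges' g undercover slightly at small n
  (the coverage suite bounds this rather than hiding it).
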