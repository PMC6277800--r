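---
title: "Coupling resting-state network connectivity and temporal entropy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling resting-state network connectivity and temporal entropy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsnec)
```

## Overview

`rsnec` asks a single question of resting-state fMRI cohorts: how tightly
does the temporal regularity of regional BOLD signals track the
cohort's dominant pattern of functional connectivity, and does that
coupling differ between groups? The pipeline has four stages:

1. **Functional connectivity (FC).** Pearson correlation between all ROI
   time series (motion-flagged frames deleted), reduced to the 11
   intra-network and 55 inter-network averages over 11 resting-state
   networks (RSNs), giving 66 features per subject.
2. **Primary component.** The N x 66 cohort matrix is column-centered
   and decomposed by SVD, `M = U A V'`. The subject scores on the first
   component, `c1 = (UA)[, 1]`, summarize each subject's position along
   the dominant axis of inter-individual FC variation.
3. **Wavelet-scale sample entropy.** Each ROI series is decomposed with
   a stationary wavelet transform (SWT); at the two levels covering the
   0.01-0.10 Hz band, lagged-pattern sample entropy is computed on the
   detail coefficients with a BayesShrink-informed tolerance, then
   averaged within RSNs, giving an 11-vector of network entropies per
   subject.
4. **Coupling model and statistics.** An elastic net (never shown group
   labels) predicts `c1` from the 11 network entropies; the fitted
   scores `c1H` enter rank-sum group comparisons, a group-by-`c1H`
   interaction regression, and Pearson correlations with symptom
   severity.

## The entropy measure

For one coefficient series the tolerance is `r = r0 * sigma + t`, where
`sigma` is the series sd, `r0 = 0.2` by default, and `t` is the
BayesShrink threshold `sigma_noise^2 / sigma_signal` with
`sigma_signal^2 = max(var - sigma_noise^2, 0)` and `sigma_noise`
estimated as `median(|d1|)/0.6745` from the finest subband. When a level
carries no signal beyond the noise floor the threshold saturates at
`max(|coeffs|)`, so noise-only levels report near-zero entropy rather
than the entropy of noise — the tolerance is how the method focuses on
signal structure.

Patterns of length `m = 1` and `m + 1 = 2` are built from lagged points
`(x[i], x[i + delta])`. `Cm` is the fraction of ordered pattern pairs
(p != q) whose Chebyshev distance is strictly below `r` (a distance of
exactly `r` is a non-match); `H = -ln(Cm1 / Cm) >= 0`. Each length uses
its own admissible-pattern count in the denominator. Fewer than 50
admissible patterns, or a zero match count, makes the level's estimate
missing — never zero.

### Numerical conventions

* **SWT normalization.** Orthonormal analysis filters applied without
  the extra `1/sqrt(2)`: white noise keeps unit coefficient variance at
  every level, and energy obeys
  `sum_j 2^-j ||d_j||^2 + 2^-J ||a_J||^2 = ||x||^2` (periodic
  convolution, length a multiple of `2^J`; inputs are padded by
  symmetric reflection and the padding trimmed from outputs).
* **Scale selection.** Level j covers `[f_N/2^j, f_N/2^(j-1)]` with
  `f_N = 1/(2 TR)`. Levels overlapping the analysis band by at least
  half the level-band width qualify; the two with the largest absolute
  overlap are kept. At TR = 2 s and 0.01-0.10 Hz: levels 2
  (0.0625-0.125 Hz) and 3 (0.03125-0.0625 Hz). A pure >=50%-overlap
  rule would also admit levels 4 and 5, whose bands sit inside the
  analysis band but carry little of its energy; capping at the two
  best-covering scales matches the two-scale averaging the analysis is
  built on.
* **Pattern lag.** Default `2^j` at levels 1-2 and `round(0.75 * 2^j)`
  deeper. The dyadic lag is the decorrelation length of the undecimated
  coefficients; at deep levels that is precisely why it fails — once the
  comparison points are decorrelated for every input, the conditional
  match probability no longer responds to the signal's regularity.
  Measured on band-limited AR(1) inputs, level-3 coefficient
  autocorrelation at lag 8 spans only |rho| 0.02-0.28 across
  phi = 0-0.9, versus 0.60-0.69 (monotone in phi) at lag 6. The lag is
  a `delta_fun` argument for anyone wanting the strict dyadic rule.
* **Motion masking.** The default removes a pattern when any of its own
  lagged indices falls on a flagged frame — masking, never imputation;
  the value of H computed from the surviving patterns is unchanged by
  how many other patterns were removed. A conservative alternative
  (`contamination = "swt"`) masks every index the flags reach through
  the filter cascade; with sym8 one flagged frame then contaminates
  `(L-1)(2^j - 1) + 1 = 106` indices at level 3, which empties
  realistic series — measured on a 40-subject cohort at 2% flag rate,
  12 subjects lost entire networks under the conservative rule and none
  under the default.
* **r0 selection.** Over the grid 0.10-0.30 (step 0.05) the value
  maximizing the range of network entropies across all subjects is
  chosen, ties broken toward 0.20. Network-level (not ROI-level) values
  define the range; both interpretations were defensible and the
  network level is what the downstream model consumes.

## The coupling model

`c1 = X_H beta + eps` is fit by elastic net in the coordinate-descent
parameterization `(1/2N) RSS + lambda [(1-alpha)||beta||^2/2 +
alpha||beta||_1]`, with predictors standardized internally and
coefficients reported on the original scale. A 21-point alpha grid and a
per-alpha lambda path are searched by 10-fold cross-validation with a
seeded fold assignment shared across the grid; the (alpha, lambda) pair
minimizing mean CV MSE is refit on all data (minimum-MSE rule, not the
one-standard-error rule). Standardization happens inside each training
fold, the leakage-safe choice.

The statistics: two-sided Wilcoxon rank-sum for group differences in
`c1` and `c1H` (mid-ranks; exact dynamic-programming null for untied
samples with both groups <= 20, tie- and continuity-corrected normal
approximation otherwise; both the rank-sum `W` and Mann-Whitney `U`
conventions reported); OLS for
`c1 = g0 + g1 G + g2 c1H + g3 G c1H + eps`; Pearson correlation with
severity over scored subjects, in-sample `c1H`.

## The synthetic cohort

The generator is a first-class module: every downstream claim is tested
against cohorts whose ground truth is planted.

* **FC structure.** Each subject gets a block correlation target:
  within-network blocks at `intra_corr` (default 0.30), between-network
  at `inter_corr` (0.05), shifted by
  `(group_fc_shift * group + subject_latent) * w` where `w` is a signed
  network contrast (+ for sensory-type networks SM, SM-lat, VIS, AUD,
  DAN, VAN, CO; - for DMN, SAL, FP, SUB) and `subject_latent` is the
  subject's latent FC score (sd 0.04 in correlation units). Cases shift
  negative along the sensory-positive contrast
  (`group_fc_shift = -0.08`). Targets are clipped to [-0.95, 0.95] and
  repaired to PSD by eigenvalue clipping at 1e-8 with diagonal
  renormalization.
* **Signals.** ROIs follow AR(1) with network coefficient `phi_k`
  (default 0.45) minus the network's entropy modulation, innovations
  drawn jointly through the Cholesky factor of the target; series are
  then band-limited to 0.01-0.10 Hz by an ideal FFT filter (the data
  this emulates are band-passed in preprocessing) and standardized.
  Band-limiting matters: without it the finest wavelet subband carries
  the full innovation spectrum, the all-noise threshold branch fires,
  and white-noise ROIs score H ~ 0, inverting every regularity
  ordering. Cross-ROI structure is imposed on innovations, so stationary
  correlations equal the target exactly only for matched phi; tests use
  matched-phi blocks where that holds.
* **Entropy coupling.** Network modulation is
  `coupling_g * z_i * sign_k + noise`, with `z_i` the standardized
  latent score, `coupling_control = 0.25 > coupling_case = 0.08`: the
  entropy-connectivity coupling is planted weaker in cases.
* **Severity.** Cases only:
  `severity = 10.1 - 21 * entropy_score + N(0, 5.1^2)`, truncated at 0.
  The constants are calibrated so severity is distributed ~10.1 +/- 5.4
  with an entropy-severity correlation near -0.31 — the regime reported
  for cohorts of this kind; an earlier ad-hoc choice implied r ~ -0.11,
  which no realistic sample size could detect reliably.
* **Motion.** FD is lognormal below the 0.3 mm threshold with
  exceedances at `flag_rate` (2%); flags are wherever FD exceeds the
  threshold, so the >10%-flagged exclusion rule can be exercised
  directly.
* **Defaults.** 163 controls + 85 cases, 264 ROIs over the 11 networks,
  TR 2 s, 150 frames. Tests scale subjects, ROIs-per-network and frames
  down for runtime and say so; effect-size presets used by recovery
  tests (e.g. coupling 0.5/0.3 with entropy noise 0.10 for sign
  recovery) are frozen choices made for test power, as the generator's
  documentation notes.

## What a green test does and does not establish

The synthetic world is Gaussian, stationary within subject, linearly
coupled, and single-site. Green recovery tests establish that the
implementation measures what it claims on data with known structure at
realistic noise levels. They do not establish hemodynamic realism
(no HRF or physiological noise), scanner or site effects, non-linear or
non-stationary coupling, or the behavior of the entropy measure on
signals whose irregularity is not AR(1)-like. One consequence measured
during development and worth flagging: the *sign* of the
group-by-prediction interaction `g3` at desk scale depends on the noise
regime — when entropy profiles are estimated accurately, the
weakly-coupled group can show the *steeper* regression slope (classic
attenuation asymmetry), and signs flip across seeds. The within-group
association strength (correlation) contrast is robust in every regime,
and that is what the end-to-end test asserts; `g3` power is verified in
the regime where the planted slope difference is identifiable
(slopes 1.0 vs 0.3, n = 90, noise sd 0.5).

## Known limitations

* The SWT uses periodic convolution on reflection-padded series; for
  series far from a multiple of `2^J` the trimmed coefficients near the
  end mix padded content (standard for undecimated transforms, but
  worth knowing for very short series).
* `extract_roi_means` operates on in-memory 4-D arrays with an affine,
  not on NIfTI files (no NIfTI reader among the package's allowed
  dependencies); sphere membership is by voxel-center distance, not
  partial volumes.
* Exact rank-sum enumeration is limited to both groups <= 20 without
  ties; beyond that the tie-corrected normal approximation is used.
* Run configs are JSON, not YAML.
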