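# rsnec — resting-state network entropy–connectivity coupling

`rsnec` is an R package for studying how the **temporal regularity** of
regional resting-state BOLD signals couples to the cohort's dominant
pattern of **functional connectivity (FC)**, and whether that coupling
differs between clinical groups. It is aimed at neuroimaging researchers
working with preprocessed, band-limited (0.01–0.1 Hz) ROI time series
organized into resting-state networks (RSNs).

## The method

For each subject with an R-ROI time series matrix and an ROI→RSN map
over 11 networks (SM, SM-lat, VIS, AUD, DAN, VAN, CO, DMN, SAL, FP,
SUB):

1. **FC features.** Pearson correlations between all ROI series
   (frames with framewise displacement > 0.3 mm scrubbed; subjects with
   > 10 % flagged frames excluded), averaged into 11 intra-network +
   55 inter-network values — 66 features per subject.
2. **Primary component.** The cohort matrix `M` (N × 66) is
   column-centered and decomposed, `M = U A Vᵀ`; subject scores
   `c₁ = (UA)[, 1]` summarize the dominant axis of inter-individual FC
   variation. `V₁` is oriented so sensory intra-network loadings average
   positive.
3. **Wavelet-scale entropy.** Each ROI series is decomposed with a
   stationary wavelet transform (sym8 by default); at the two dyadic
   levels covering 0.01–0.1 Hz (0.031–0.063 and 0.063–0.125 Hz at
   TR = 2 s), sample entropy

   `H = −ln( Cm+1(r) / Cm(r) )`,  `r = r₀·σ + t`

   is computed on lagged coefficient patterns (m = 1, r₀ = 0.2, t the
   BayesShrink threshold from the finest-subband noise estimate;
   motion-hit patterns removed), then averaged within networks → 11
   network entropies per subject.
4. **Coupling model.** An elastic net `c₁ = X_H β + ε` (10-fold CV over
   an (α, λ) grid, group labels never seen) yields predictions
   `c₁H = X_H β̂`. Wilcoxon rank-sum tests compare `c₁` and `c₁H` between
   groups; `c₁ = γ₀ + γ₁G + γ₂c₁H + γ₃G·c₁H + ε` tests whether the
   coupling differs by group; Pearson correlation relates `c₁H` to
   symptom severity.

A synthetic cohort generator plants all of this structure (block FC
targets, AR(1) regularity coupled to a latent FC score, motion, a
severity model) so that every stage can be validated against known
ground truth.

## Worked example

```r
library(rsnec)

sim <- sim_config(n_control = 30, n_case = 20, n_frames = 200,
                  rois_per_network = setNames(rep(2L, 11), canonical_networks()),
                  seed = 1)
res <- run_pipeline(run_config(simulate = sim, seed = 1,
                               alpha_grid = seq(0, 1, 0.25), n_folds = 5))
print(res)
#> rsnec pipeline run
#>   subjects: 50 -> 50 after motion exclusion (50 modeled)
#>   c1 variance explained: 20.1%; r0 = 0.20; alpha = 1.00
#>   rank-sum p (c1) = 4.88e-08, (c1H) = 0.0116; gamma3 = -0.321 (p = 0.468)
#>   severity vs c1H: r = -0.371 (p = 0.107)

round(res$model$beta, 3)
#>     SM SM-lat    VIS    AUD    DAN    VAN     CO    DMN    SAL     FP    SUB
#>  0.000  0.000  0.445  2.099 -1.551  0.000  0.118 -1.175  0.000  0.000 -0.331
```

Reading the output: no subject exceeded the motion-exclusion threshold;
the primary FC component explains 20 % of feature variance and separates
the groups strongly (the generator plants a negative case shift along
the sensory-positive contrast, rank-sum p ≈ 5e-8). The entropy model's
scores also separate the groups (p = 0.012) and trend negatively with
the planted severity (r = −0.37 at only 20 scored subjects). The
interaction γ₃ is negative (controls couple more strongly, as planted)
but not significant at this cohort size — see the methods vignette for
why its sign is only identifiable in the noise-dominated regime.

## Command line

```sh
rsnec simulate --config sim.json --out cohort/     # synthetic cohort
rsnec validate --manifest cohort/manifest.tsv --map cohort/roi_map.tsv
rsnec fc       --cohort cohort/ --out fc/          # features + PCA
rsnec entropy  --cohort cohort/ --out ent/ --r0 auto
rsnec model    --features fc/features.tsv --entropy ent/entropy.tsv --out model/
rsnec run      --config run.json                   # full pipeline
```

(`rsnec` is `inst/exec/rsnec`; equivalently
`Rscript -e 'rsnec::rsnec_main()' <cmd> ...`.) Configs are JSON
mirroring `sim_config()` / `run_config()` fields.

## Layout

```
R/                 io, synthetic generator, fc/PCA, wavelet + entropy,
                   model/statistics, pipeline, CLI
tests/testthat/    unit + property suites, test-acceptance.R
vignettes/         methods vignette (model, conventions, limitations)
scripts/           acceptance.R
```
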