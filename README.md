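# icbmri

Serial-MRI response assessment and radiomic response prediction for
preclinical (mouse) gliomas under immune-checkpoint blockade (ICB), with
the accompanying immunology statistics and a fully synthetic 3D test
cohort generator.

Orthotopic gliomas treated with anti-PD-1 + anti-CTLA-4 split into
responders and non-responders, and responders frequently *pseudoprogress*:
the lesion grows between the baseline scan (MRI1) and the on-therapy scan
(MRI2) before regressing by the post-therapy scan (MRI3). `icbmri`
provides:

* **Volumetric RANO/iRANO translation.** With
  `%V = 100 (V_to − V_from)/V_from`: CR at `%V31 = −100`; PR at
  `%V31 ≤ −65` or `%V32 ≤ −65`; PD at `%V31 ≥ +40` unless
  `%V32 ≤ −30` (pseudoprogression rescue → SD); SD otherwise. CR/PR/SD
  are responders. The ±40/−65 cutoffs are the spherical-assumption image
  of the planimetric +25%/−50% diameter-product cutoffs:
  `(1 + a)^{3/2} − 1`, rounded to the nearest 5%. Growth patterns G1–G4
  are the sign patterns of `(%V21, %V32)`; G2 is pseudoprogression-like.
* **A frozen 423-feature radiomic extractor** (146 first-order, 33 shape,
  200 texture, 44 curvature) for 3D image+mask pairs, with `|MRI2 − MRI1|`
  delta features (846-column design) and reusable z-score normalization.
  Geometry runs on a marching-tetrahedra boundary mesh with physically
  scaled smoothing and quadric-fit curvatures.
* **An in-package gradient-boosting classifier** (stage-wise trees on the
  binomial deviance, deterministic) evaluated by two-times repeated
  stratified 5-fold CV; pooled held-out accuracy is tested against the
  no-information rate (NIR) with an exact one-sided binomial test,
  alongside Clopper–Pearson CI, sensitivity/specificity and AUROC.
* **Immunology statistics**: geometric-mean gene-signature scores,
  immunogram z-scores of log2 fold changes, top-10-clone share and
  productive clonality (`1 − H/ln R`), shared CDR3 motif clusters
  (Hamming ≤ 1 within length strata), and LDH specific-lysis correction.
* **A seeded synthetic cohort generator**: archetype volume trajectories
  (direct response / pseudoprogression / progression / late progression),
  star-convex spherical-harmonic tumor phantoms on a 64³, 0.1 mm grid,
  and an injectable morphological signal carried by the MRI1→MRI2 shift
  in surface irregularity (hence in the volume-to-surface ratio).

## Worked example

```r
library(icbmri)

calls <- classify_response(tibble::tibble(
  animal_id = c("m1", "m2", "m3"), arm = "ICB",
  v1 = c(10, 10, 10), v2 = c(20, 8, 18), v3 = c(13, 2.5, 19)))
calls[, c("animal_id", "category", "responder", "growth_pattern")]
#>   animal_id category responder growth_pattern
#> 1 m1        SD       TRUE      G2        <- pseudoprogression, rescued
#> 2 m2        PR       TRUE      G1
#> 3 m3        PD       FALSE     G3

co <- generate_cohort(cohort_spec(n_animals = 60, seed = 7))
summarize_cohort(co$calls)
#> # A tibble: 1 x 8
#>   arm      CR    PR    SD    PD     n responders response_rate
#> 1 ICB       1    16    10    33    60         27            45

ft  <- cohort_feature_table(co)          # renders + extracts 846 features
res <- train_evaluate(ft, ft, cv = cv_config(seed = 7))
res$report
#> Held-out evaluation (n = 120 pooled predictions)
#>   accuracy    70.8% (95% CI 61.8-78.8%)
#>   sensitivity 66.7%  specificity 74.2%
#>   AUROC       0.788
#>   NIR         55.0%  (one-sided binomial p = 0.000275)
head(res$importance, 3)
#>   feature                importance
#> 1 delta_shape.radial_min      0.251
#> 2 delta_curv.k2_q1            0.184
#> 3 t1_curv.k2_skewness         0.0765
```

The classifier beats the NIR (p = 2.8e-4 at n = 60; the margin grows with
cohort size), and the top-ranked features are longitudinal (`delta_`)
shape/curvature descriptors — exactly where the generator injects the
signal, as the shift in surface irregularity between MRI1 and MRI2.

Plots: `plot_trajectories(calls)`, `autoplot(summarize_cohort(calls))`,
`autoplot(res$report)` (ROC), `autoplot(res$model)` (importances). A thin
command-line wrapper with `classify` / `summarize` / `extract` / `delta` /
`train-eval` / `simulate` subcommands is installed at
`system.file("cli", "icbmri.R", package = "icbmri")`.

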