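---
title: "Volumetric response criteria and radiomic response prediction for preclinical glioma MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric response criteria and radiomic response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icbmri)
```

## The problem

Immune-checkpoint blockade (ICB) produces a characteristic dichotomy in
orthotopic mouse gliomas monitored by serial T2-weighted MRI: some animals
respond (often after a transient lesion enlargement — pseudoprogression)
and some progress. Deciding who responded, and predicting that outcome
from the first two scans, requires (i) response criteria that work on
volumes rather than the planimetric diameter products of the clinical
RANO/iRANO system, and (ii) quantitative image features that see the
morphological signature of incipient response before the volume itself
declares it. `icbmri` implements both, together with the small immunology
statistics that accompany such studies and a synthetic 3D cohort generator
that lets every stage be exercised and tested without any imaging data.

## Volumetric response criteria

Animals are scanned at baseline (MRI1, day 13 after implantation), during
therapy (MRI2, day 19) and after therapy (MRI3, day 26). With
$\%V_{a\text{-}b} = 100\,(V_a - V_b)/V_b$:

* **CR** — $\%V_{31} = -100$ (no residual lesion);
* **PR** — $\%V_{31} \le -65$ or $\%V_{32} \le -65$;
* **PD** — $\%V_{31} \ge +40$, unless the lesion regressed by at least
  30% between MRI2 and MRI3 ($\%V_{32} \le -30$), in which case the
  enlargement is treated as pseudoprogression and the animal is **SD**;
* **SD** — everything else.

CR, PR and SD animals are responders; PD animals are non-responders. The
$+40$ and $-65$ cutoffs are the volumetric translation of the clinical
planimetric cutoffs under a spherical-tumor assumption: a diameter product
scales as $d^2$ and a volume as $d^3$, so a fractional area change $a$
maps to $(1+a)^{3/2}-1$; $+25\% \to +39.75\% \to +40\%$ and
$-50\% \to -64.64\% \to -65\%$ after rounding to the nearest 5%
(`derive_volumetric_thresholds()`). The $-30\%$ rescue cutoff has no
planimetric derivation and is implemented as a literal constant. Rounding
happens only in the derivation utility, never during classification.

Boundary conventions (the published definitions overlap at the cutpoints
and, in one place, disagree by 0.5%): exactly $-65.0$ classifies PR,
exactly $+40.0$ is a PD candidate that may still be rescued, exactly
$-30.0$ rescues. The SD lower bound is taken as $-65.0$ (a lone $-65.5$
variant of this bound is treated as a typographic slip). Growth
patterns are the sign patterns of $(\%V_{21}, \%V_{32})$ —
G1 $(-,-)$, G2 $(+,-)$ (pseudoprogression-like), G3 $(+,+)$,
G4 $(-,+)$ — with a zero change folded into the non-growth branch so that
every trajectory receives a pattern; `strict_growth = TRUE` restores the
strict-inequality reading and labels zero changes `indeterminate`. A
lesion that regrew after complete disappearance at MRI2 has an undefined
$\%V_{32}$; its category is computed from $\%V_{31}$ alone and its growth
pattern is `indeterminate`.

```{r}
calls <- classify_response(tibble::tibble(
  animal_id = c("m1", "m2", "m3"), arm = "ICB",
  v1 = c(10, 10, 10), v2 = c(20, 8, 18), v3 = c(13, 2.5, 19)
))
calls[, c("animal_id", "category", "responder", "growth_pattern",
          "pseudoprogression_rescued")]
```

The `bidimensional_product()` helper reports the planimetric diameter
product on the largest axial slice using axis-aligned caliper extents
(the way preclinical diameters are read off the orthogonal image axes),
and `fisher_exact_2x2()` implements the two-sided exact test with the
point-probability convention (all tables with the observed margins whose
probability does not exceed the observed one, within a relative `1e-7`).

## The radiomic feature roster

`extract_features()` computes exactly 423 features from an intensity
volume plus lesion mask, in four frozen blocks:

* **146 first-order** — 20 base statistics, a 0–100 percentile grid in
  steps of 2.5 (linear interpolation), and 17 histogram statistics at bin
  counts 8/16/32/64/128;
* **33 shape** — voxel and mesh volume, mesh surface area, surface/volume
  ratios (for a sphere $V/S = r/3$), sphericity, compactness, principal
  axes, bounding box, the bidimensional product, radial statistics;
* **200 texture** — 24 gray-level co-occurrence statistics at voxel
  distance 1 and 10 at distance 2, plus 16 run-length statistics, each
  averaged over the 13 unique 3D directions, at fixed bin counts
  8/16/32/64 (fixed-bin-count discretization over the masked range);
* **44 curvature** — 11 summary statistics of each of $\kappa_1$,
  $\kappa_2$, mean curvature $H$ and Gaussian curvature $K$ on the
  triangulated lesion boundary.

The exact feature enumeration of the originating toolkit is not public;
the roster here is a documented, frozen set reproducing the block counts
and the named head feature (the volume-to-surface ratio). Category
cardinalities, name stability and finiteness are enforced contracts.
Longitudinal change enters as `delta_features()`, the element-wise
absolute difference $|f_2 - f_1|$ between the MRI1 and MRI2 vectors, so a
baseline + delta design matrix has 846 columns.

### Numerical choices for the geometry

The boundary surface is the 0.5-level isosurface of the mask by marching
tetrahedra (6-tet cube decomposition; per-element orientation against the
interior), Taubin-smoothed with a pass count that scales with the squared
equivalent radius in voxels — a constant *physical* diffusion scale, which
is what makes surface area, sphericity and curvature converge under grid
refinement instead of chasing the voxel staircase. Curvatures come from
per-vertex quadric fits over 3-ring neighborhoods; the resulting ambient
curvature tensor (linear in the fit noise) is diffused over the mesh graph
before the principal curvatures are read off, which removes the
noise-product bias that otherwise ruins pointwise Gaussian-curvature
estimates; the raw angle-defect total, which satisfies the discrete
Gauss-Bonnet theorem exactly, is retained as an internal oracle. On
digitized spheres of radius 6 mm the implementation reproduces
$V/S = r/3$ and sphericity within 5% and $\bar H = 1/r$ within 10% at
0.5 mm and 0.25 mm voxels, with errors shrinking under refinement (these
are test assertions, not aspirations). Anisotropic spacing is honored
throughout; there is no resampling. Degenerate conventions: a constant
intensity field has entropy 0; a single-gray-level region has GLCM
contrast 0, homogeneity 1, correlation 1.

## Response prediction

The classifier is an in-package gradient-boosting machine: stage-wise
depth-limited regression trees on the binomial deviance, starting from
the prevalence log-odds, each stage fitting the residual $y - p$ by
exhaustive presorted variance-reduction split search and taking a Newton
leaf step $\sum r / \sum p(1-p)$ scaled by the shrinkage. No subsampling
is used, so fits are deterministic. Feature importance is the normalized
total split gain.

Evaluation follows a two-times repeated, stratified five-fold
cross-validation; all held-out predictions are pooled (each animal
predicted twice), and the pooled accuracy at the 0.5 cutoff is compared
against the no-information rate (the largest class share) with a
one-sided exact binomial test, alongside an exact Clopper-Pearson 95% CI,
sensitivity and specificity with responder as the positive class, and a
rank-statistic AUROC with midrank tie handling. Feature normalization is
fit on the training folds only and applied to the held-out fold by
default; `normalize = "global"` reproduces whole-table z-scoring before
splitting (the originally described, slightly leaky protocol) for
comparison. Tuning (`tune_boost()`) maximizes inner-CV accuracy over a
small grid (iterations 50/100/150, depth 1–3, shrinkage 0.1, minimum node
size 5/10) with ties broken toward fewer iterations, then shallower
trees.

## The synthetic cohort generator

`generate_cohort()` draws, per animal, an archetype — direct responder
(G1), pseudoprogressor (G2), progressor (G3), late progressor (G4) — a
three-point volume trajectory from truncated log-normal growth factors,
and per-time-point phantom parameters. Defaults follow the study
conditions the package models: a 47.6% responder rate under treatment
(5.48% in controls), a 78:22 pseudoprogressor:direct mix among
responders, three scans, and star-convex phantoms on a 64^3 grid of
0.1 mm voxels. Baseline volumes are log-normal with median 1.3 mm^3
(early-treatment orthotopic lesions are this small), truncated so the
largest progressing lesion still fits the grid.

Two design decisions matter for what the tests can claim:

* **The null is exact by construction.** The non-responder archetype mix
  mirrors the responders' (78:22), and the MRI1-to-MRI2 growth-factor
  distribution is shared between the two growing archetypes (G2/G3) and
  between the two shrinking ones (G1/G4). Labels are decided by MRI3,
  which the feature table never sees, so at `delta = 0` the baseline and
  on-therapy images carry exactly zero label information — the null
  cohorts test the false-positive behavior of the whole pipeline, not a
  weakened signal.
* **The signal is morphological, not volumetric.** Phantoms are spheres
  perturbed by band-limited spherical-harmonic radial noise (degrees
  2–6); the relative amplitude ("irregularity") sets surface roughness
  and therefore the volume-to-surface ratio at fixed volume (a monotone
  effect, asserted in the tests). From MRI1 to MRI2 responders' lesions
  get smoother by `delta` and non-responders' rougher by `delta`, so the
  shift of V/S and related shape/curvature features carries the label —
  mirroring the head predictive feature of the analysis the package
  implements — while volumes stay label-free. The default
  `delta = 0.08` is a synthetic calibration chosen so the recovery and
  null properties are decisively separated; it encodes no biology.
  Intensity texture (a correlated Gaussian field, 0.3 mm correlation
  length) is label-free by default.

What the phantoms do *not* emulate: MR physics (coil profiles, bias
fields, partial volume), multifocal lesions, inter-scan registration
error, or segmentation noise. A passing recovery test therefore shows
that the pipeline detects a morphological change of plausible size
through the full render-extract-normalize-boost-test chain — not that
real T2 images of this model would yield the same accuracy.

## Problem sizes used by the shipped checks

The package's own end-to-end check runs 20 signal and 20 null replicates
of a 150-animal cohort (two scans extracted per animal, 300 extractions
and a 10-fold fit cycle per replicate) with 50 boosting iterations, and
requires a significant NIR exceedance in at least 90% of signal
replicates and at most 10% of null replicates, plus a demonstration on
three replicates that the baseline block alone stays at the NIR (the
delta block is what carries the injected change). Geometry closed forms
are checked on radius-6 mm spheres at two voxel sizes. These sizes were
chosen to give decisive statistics at desk scale; the observed margins
(recovery p-values around 1e-30 against a 0.05 criterion) are large.

## Immunology statistics

`signature_score()` is the geometric mean of a gene set's expression per
sample (`exp(mean(log(x + pseudocount)))`, pseudocount 1 by default for
count data). `immunogram()` log2-transforms responder/non-responder fold
changes and standardizes across features (sample SD; an all-equal input
yields all-zero scores and a flag). `top_clones_share()` is the percent
of productive templates in the ten most frequent clones (deterministic
count-then-lexicographic tie-break); `productive_clonality()` is
$1 - H/\ln R$ with the single-clone repertoire defined as 1.
`shared_cdr3_motifs()` clusters equal-length CDR3 sequences at Hamming
distance <= 1 (substitutions only, by design: "one amino-acid alteration"
reads as substitution) by single linkage and reports clusters spanning at
least two repertoires. `specific_lysis()` applies the standard LDH kit
correction `(experimental - effector_spont - target_spont + background) /
(target_max - target_spont)`; with raw optical densities the medium
background appears once in the numerator, which is why it is added back.

## Known limitations

* The roster is a reconstruction: block counts, naming scheme and the
  head feature are contractual, individual feature identity beyond that
  is not.
* Axis-aligned caliper diameters understate the planimetric product of
  lesions oriented off the image axes; this matches the stated reading
  convention, and the volumetric criteria do not depend on it.
* Pointwise principal curvatures on voxel meshes remain noisy even after
  tensor diffusion; their means and area-weighted summaries are accurate,
  the extremes (min/max/range) are tessellation-sensitive and should be
  read comparatively, not absolutely.
* The boosting learner intentionally omits stochastic subsampling; for
  very large feature tables a subsampled variant would be faster but
  non-deterministic.
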