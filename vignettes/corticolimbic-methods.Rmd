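---
title: "Dual-modality corticolimbic subtyping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-modality corticolimbic subtyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corticolimbic)
```

## The problem

Alzheimer's disease is heterogeneous: different patients lose grey matter
and glucose metabolism in different spatial patterns. Two recurring axes
organize this heterogeneity — *typicality* (limbic-predominant versus
cortical-predominant neurodegeneration) and *severity* (minimal versus
diffuse burden). `corticolimbic` implements a complete pipeline for
identifying such subtypes from per-subject regional biomarker tables in
two modalities — FDG-PET standard-uptake-value ratios (SUVR) and
structural-MRI regional grey-matter volumes — and for comparing the
resulting subtype assignments across modalities and against a
hypothesis-driven hippocampus-to-cortex-ratio classification.

The pipeline starts from ROI tables (subjects x regions), never images:
segmentation, registration and SUVR extraction are upstream of this
package. Because real multimodal dementia cohorts are access-restricted,
the package ships a synthetic cohort generator with *known planted
subtype structure*, so every downstream stage is testable end to end and
every headline number the package reports is recomputable from code.

## Data model

Three objects flow through the pipeline:

* `roi_atlas` — per-region metadata: `pattern_class`
  (limbic / cortical-association / other), `tissue_class`, a hippocampus
  flag and a reference-region flag (pons). `default_atlas()` supplies 41
  hemisphere-merged grey-matter regions (34 cortical, following the
  Desikan-Killiany naming, plus 7 subcortical structures) and the pons.
  Whether a study's "bilateral" region count merges hemispheres or lists
  them separately varies; the atlas carries a `hemisphere_scope` column so
  either convention loads, and the synthetic default merges hemispheres.
* `subject_meta` — diagnosis, age, sex, education, APOE e4 carriership,
  intracranial volume (ICV), amyloid status. `select_analysis_sample()`
  applies the inclusion rule: AD/MCI enter only if amyloid positive, CN
  only if amyloid negative.
* `roi_matrix` — the values for one modality, tagged with a processing
  state. State tags enforce ordering: clustering consumes
  `"global-normalized"` uptake and `"icv-adjusted"` volumes; w-score
  brain maps consume `"reference-scaled"` uptake.

## Value transformations

**Head-size adjustment (MRI).** Regional volumes are residualized against
ICV with the control-derived model

\[ \mathrm{Volume}_{adj} = \mathrm{Volume}_{raw} - \beta\,(\mathrm{ICV}_{raw} - \mathrm{ICV}_{mean}), \]

where `beta` is the per-region OLS slope of volume on ICV *in controls*
and `ICV_mean` the control mean. The same control-derived model is applied
to every group, so patient volumes are residualized against the normative
head-size relationship. On the fitting sample this makes adjusted volumes
exactly ICV-orthogonal (an OLS identity the tests assert).

**Uptake scaling (FDG).** Two scalings with different purposes:
`normalize_global_mean()` divides each subject's row by that subject's
mean over all non-reference grey-matter regions (output row means are
exactly 1) and feeds clustering; `scale_by_reference()` divides by the
mean pons value and feeds the w-score maps. The global mean is computed
over non-reference regions only — a deliberate choice (the defining
region set of a "global mean" is rarely stated) that keeps the two
scalings independent. Both outputs drop the reference columns: the pons
is scaling machinery, not an analysis feature, and a reference-scaled
reference region is identically 1 (zero variance would poison the
w-score fit).

**QC.** `qc_screen()` regresses total grey-matter volume on ICV and flags
subjects beyond `n_sd` (default 4) residual SDs — an automated stand-in
for the visual volume-versus-ICV outlier check; flags are advisory.

## W-scores

`fit_wscore_model()` fits, per region, an OLS regression of the regional
value on age, sex, education and APOE e4 in the control group and stores
the residual SD; `compute_wscores()` then returns

\[ w = \frac{\text{observed} - \text{covariate-predicted}}{\text{residual SD}}, \]

reversed in sign (default) so that *higher w = greater neurodegeneration*
in both modalities, since lower volume and lower uptake both mean worse.
Covariates enter in natural units (years; 0/1 indicators), so
coefficients are interpretable; a covariate with no variance in controls
is dropped with a warning rather than producing a singular fit. One
control-fitted model per modality is reused for every group in a run.
On a 500-control fitting sample, per-region |mean w| stays below 0.05 and
|SD - 1| below 0.1 (the SD is slightly below 1 by the degrees-of-freedom
correction), which the acceptance tests assert.

## Data-driven subtyping

The clustering chain is `rf_dissimilarity()` →
`classical_mds()` → `average_linkage()` → `k_selection_report()` →
`cut_tree()`, wrapped by `run_subtype_pipeline()`.

**Unsupervised random-forest dissimilarity.** A classification forest is
trained to discriminate the real subjects from a synthetic contrast
sample in which each column is an independent bootstrap resample of the
corresponding real column — marginals preserved, between-region
dependence destroyed (the classical contrast-class construction for
unsupervised forests). The proximity of two real subjects is the fraction
of trees in which they share a terminal node, and the dissimilarity is
`sqrt(1 - proximity)`. Three conventions are explicit toggles because the
literature rarely states them: the contrast-class variant (marginal
bootstrap here), proximity counted over **all** trees for all pairs
(default; `oob_prox = TRUE` restricts to out-of-bag trees, which is
noisier at desk-scale tree counts), and the square-root transform
(metric-friendlier than `1 - proximity`; toggle provided).
Hyperparameters `mtry` and `nodesize` can be tuned by out-of-bag error
over a grid (`tune_rf()`, ties toward the smaller values); the default is
`mtry = floor(sqrt(p))` and `nodesize = 5`, the latter chosen because
mildly smoothed terminal nodes give more stable proximities than fully
grown trees at a few thousand trees. The default `n_trees = 2000` is a
desk-scale setting — reference studies use 20 000 — and
`stability_assessment()` quantifies the consequence: it re-runs the
forest under fresh seeds and reports element-wise dissimilarity
differences and downstream label agreement (adjusted Rand index), the
differences shrinking as trees are added.

**Embedding and clustering.** `classical_mds()` double-centers the
squared dissimilarities, eigendecomposes, and scales eigenvectors by the
square roots of the top-d (default 3) positive eigenvalues; eigenvalues
are returned for scree inspection. Axis signs are canonicalized (first
nonzero coordinate positive) so results are platform-reproducible;
inputs with fewer than d positive eigenvalues return the available
dimensions with a warning. `average_linkage()` runs UPGMA on Euclidean
distances between the embedded coordinates and keeps the full merge
history; `cut_tree()` relabels clusters by decreasing size so label 1 is
always the largest subtype.

**Choosing k.** `k_selection_report()` evaluates Calinski-Harabasz,
Davies-Bouldin, Dunn and mean Silhouette on the *embedding* coordinates
(the space actually clustered) for each candidate k and recommends the
majority vote of the four per-index optima, ties toward smaller k. Dunn
uses the classical single-link-between / complete-diameter variant.
Degenerate geometry yields flagged `Inf` sentinels, never silent drops.
In real studies the final k also weighs prior knowledge — the index
profiles rarely speak with one voice — so `override_k` records a manual
choice while preserving the vote.

## Hypothesis-driven classification and the typicality/severity axes

`classify_hypothesis_driven()` implements a two-step corticolimbic rule
on the hippocampus-to-cortex ratio (mean hippocampal value / mean
cortical-association value; low ratio = limbic-predominant, the same
convention in both modalities). Step 1: ratios below the sample's 25th
percentile are provisionally Limbic Predominant, above the 75th
Cortical Predominant. Step 2 confirms a provisional label only when the
discordance is real against the sample medians — Limbic Predominant
needs a hippocampal composite below the median *and* a cortical composite
above it; Cortical Predominant the reverse; everything else is Typical.
The published two-step procedure this follows is cited rather than
restated in the source literature, so the concrete rule here is this
package's explicit operationalization: all thresholds are returned with
the labels so alternative rules can be compared, and observations exactly
at a threshold fall to the Typical side (logged). Because the rule is
percentile- and median-based it is invariant to any uniform monotone
rescaling of the values.

`compute_axes()` places subjects on the two-axis framework: typicality is
the modality-specific ratio; severity is total grey-matter volume (MRI)
or mean cortical uptake (FDG); both are min-max normalized over the
analysis sample. `axis_correlations()` reports Pearson r, R² and p for
the four within- and cross-modality pairings; `method_agreement()` and
`crossover()`/`overall_agreement()` quantify agreement between methods
and between modalities, the latter through an explicit equivalence map
from subtype names to shared classes.

## Group statistics

`group_compare()` runs chi-squared tests for categorical and
Kruskal-Wallis for continuous variables across subtypes, with family-wise
Holm-Sidak step-down adjustment (`adjusted_i = max_{j<=i}
1 - (1 - p_j)^(m - j + 1)`, capped at 1) implemented directly since the
standard adjustment menu lacks the Sidak step-down variant. Post hoc
pairwise tests (pairwise chi-squared / Wilcoxon rank-sum, its own
Holm-Sidak family per variable) run only where the omnibus adjusted p
clears `alpha`. `alpha` is configuration (default 0.05) and is recorded
in the output, since published conventions differ and sometimes conflict
within one report. Summary tables use the sample SD (n-1).

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not images: control values are a per-region baseline plus
covariate effects plus Gaussian region noise; volumes additionally scale
with ICV (elasticity `icv_slope`, default 0.6, giving volume-ICV
correlations near 0.6 as seen in practice); uptake rows carry a
log-normal per-subject global factor (`global_scale_sd = 0.15`), which is
precisely what global-mean normalization exists to remove. Covariates
are drawn to plausible ranges (age ~ N(74, 7) years, education
~ N(16, 3) years, APOE e4 carriership 0.6 in patients / 0.2 in controls,
ICV ~ N(1.5e6, 1.2e5) mm³ with a sex offset). Patients draw a template
per modality: the MRI template equals the FDG template with probability
`concordance` (default 0.75) and is otherwise re-drawn from the
prevalence distribution, so cross-modality subtype membership is
correlated but imperfect, with the closed-form expected matching
fraction `concordance + (1 - concordance) * sum(prevalence²)`
(`expected_concordant_fraction()`).

**Default templates.** Template effects are mean shifts in control-SD
units; the defaults (prevalences 0.35/0.30/0.20/0.15) are modality
specific:

* MRI (volumes): Limbic Predominant (limbic -3.0, association cortex
  -0.5), Cortical Predominant (-0.5 / -2.5), Diffuse (-3.0 / -2.0, other
  -2.0) and Minimal (-0.1 flat). Volumes retain absolute severity, so a
  minimal/diffuse axis is identifiable.
* FDG (uptake): global-mean normalization removes each subject's uniform
  severity component, so purely severity-differentiated patterns
  (Minimal versus Diffuse) are *not identifiable* in normalized uptake —
  only pattern shape survives. The FDG defaults are therefore four
  shape-distinct patterns: Limbic Predominant, Cortical Predominant, a
  frontal-accented limbic variant and a posterior-accented cortical
  variant. This mirrors the empirical observation that hypometabolism
  subtypes are corticolimbic variants while only atrophy subtypes show a
  minimal/diffuse split, and it is why the package deviates from a
  single shared default template set.

Magnitudes (0.1-3.2 SD) sit in the range severe-disease w-score maps
show, and every template pair differs by at least 1.5 control SDs in the
region classes that distinguish it (for FDG, after removing the uniform
component) — the planted-separation condition under which end-to-end
recovery is asserted. Reference regions are spared by construction.
`planted_effect_check()` verifies realized effects against the plant.

What the generator does **not** emulate: scanner/site effects,
longitudinal change, partial-volume effects, spatially correlated noise
within lobes, or outlier segmentations beyond what `qc_screen()`
exercises. Passing tests therefore demonstrate the pipeline's
correctness and its behavior under known structure, not performance on
any particular clinical cohort.

## Numerical choices and degenerate inputs

* MDS sign indeterminacy: canonicalized per axis; eigenvalue ties break
  by first-axis order.
* Validation-index sentinels: zero within-scatter, coincident centroids
  or zero diameters yield `Inf` with a `sentinel` attribute and a
  warning.
* Silhouette of singletons, and of points with a = b = 0, is 0 by
  convention.
* Classifier ties exactly at a percentile threshold go to Typical and
  are logged; count conservation (every analysis subject gets exactly
  one label) is asserted by tests.
* Raw matrices must be strictly positive and complete; w-score fits
  guard against ~0 residual SD (exactly collinear inputs) and collinear
  covariates.
* `cut_tree` relabeling, tuning tie-breaks (smaller `mtry`, then smaller
  `nodesize`) and fixed seeds everywhere make every stage reproducible
  bit for bit.

## Problem sizes used by the test-suite experiments

Calibration checks run at 500 controls; end-to-end recovery uses the
generator defaults (176 controls, 180 patients, four templates) with
2000-tree forests over 10 seeds per modality; oracle-equivalence checks
use 100 random instances of n <= 12 (UPGMA) and n <= 10 (indices);
family-wise error calibration uses 200 null simulations of a
three-variable battery at n = 60. These sizes were chosen so the whole
suite documents the method's behavior at desk scale while remaining
quick to re-run; `n_trees` and cohort sizes are configuration, and
scaling the forests to 20 000 trees changes stability, not logic
(`stability_assessment()` shows how).

## Known limitations

* The hypothesis-driven rule is one defensible operationalization of a
  two-step corticolimbic scheme; agreement percentages depend on it.
* Index-based k selection is a majority-vote proxy for what is, in
  practice, a judgment call; the override exists for that reason.
* The generator's independence assumptions (region noise independent
  within class) make clustering easier than on real data with
  spatially correlated residuals; recovery rates here are upper bounds.
* Only bilateral-merged atlases are exercised by the defaults, though
  per-hemisphere atlases load through the same `roi_atlas` contract.
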