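---
title: "Methods: from segmented nuclei to a disease-stage classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from segmented nuclei to a disease-stage classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## Scientific setting

Chronic lymphocytic leukemia (CLL) can progress to an accelerated phase
(aCLL) and further to Richter transformation (RT), a large B-cell
lymphoma with poor prognosis. Under the microscope the three stages
differ mainly in cellular composition: indolent CLL tissue is dominated
by small, weakly stained lymphocytes, while aCLL and RT tissue contains
increasing fractions of larger, more proliferative cells. `cellpheno`
operationalizes this: it measures each segmented nucleus, groups nuclei
into three data-driven *phenotypes*, summarizes each region of interest
(ROI) by the composition and spatial arrangement of those phenotypes,
and classifies ROIs into CLL / aCLL / RT.

The unit of data is the **cell table**: one row per segmented nucleus
with pixel area, mean gray-level intensity (0–255), centroid, and
solidity, plus ROI metadata (identifier, resolution in µm/px, physical
dimensions, optional disease label). Tables can be measured from
instance label masks with `cells_from_mask()`, which computes solidity
as pixel area over the pixel count of the region's convex hull.

## Quality control

`filter_cells()` keeps nuclei with solidity ≥ 0.84 and area in the
closed window 8–108 µm². Low solidity flags merged or fragmented
segmentations; the size window (32–432 px at the 0.50 µm/px working
resolution) removes debris below and non-nuclear structures above the
plausible nuclear range. Both boundaries are inclusive, the filter is
idempotent, and a per-ROI report records how many cells each rule
removed (a cell failing both rules is counted under solidity).

## Phenotype discovery

Clustering every nucleus of a cohort is unnecessary and expensive;
5000 quality-passed cells per disease class (`subsample_cells()`) are
ample to estimate three clusters in a two-dimensional feature space,
and drawing equally per class keeps any one stage from dominating the
pooled sample. The two features, nuclear area (µm²) and mean intensity,
are z-standardized on the sample so their scales are comparable.

`cluster_phenotypes()` uses spectral clustering: a symmetrized
k-nearest-neighbor graph (k = 10) over the standardized points, the
top-3 eigenvector embedding of the normalized affinity
`D^(-1/2) A D^(-1/2)`, row normalization, and seeded k-means with 10
restarts. Spectral clustering is preferred over plain k-means here
because the phenotype clusters are unbalanced and non-spherical (size
is lognormal-like, intensity roughly normal); the graph construction
respects local density rather than global variance.

Clusters are given meaning purely by their statistics
(`assign_phenotype_names()`): the cluster with the largest mean size is
**RT-like**; of the remaining two, the dimmer is **CLL-like** and the
brighter **aCLL-like**. Exact ties in a deciding statistic are refused
rather than broken arbitrarily, since they indicate a degenerate
clustering. This makes the labeling invariant to the arbitrary cluster
indexing returned by k-means.

The sample's labels are then generalized to all cells with a
multinomial logistic regression on the same standardized features
(`fit_propagator()` / `propagate_labels()`). A weak fixed ridge penalty
(λ = 1/n) makes the fit strictly convex and deterministic without
materially shrinking the decision boundaries; the propagator is three
columns of coefficients, serializable as JSON, so a phenotype model
fitted once can label any future ROI. Probability ties break to the
earlier phenotype in the fixed order CLL-like < aCLL-like < RT-like.

`stability_analysis()` probes the one worrisome degree of freedom —
the random subsample — by refitting the whole chain at subsample sizes
9000–21,000 and several seeds, then measuring pairwise propagated-label
agreement on a common probe set and the downstream accuracy of each
run.

## Per-ROI features

`featurize_cohort()` computes 20 features per ROI in three families
(canonical order in `feature_names()`):

* **Unsupervised (6)** — per-phenotype cell ratio (count over total)
  and density (count per mm² of ROI area). These need only the
  propagated phenotype labels.
* **Mixed (4)** — mean nuclear area, mean intensity, mean
  nearest-neighbor distance between cell centroids, and overall cell
  density. These ignore phenotypes entirely.
* **Supervised (10)** — cells are split at a size cutoff into small (S)
  and large (L): the large-cell ratio; the Pearson correlation,
  symmetric chi-square statistic, and 1-D Wasserstein distance between
  the S and L intensity distributions (the first two on 32-bin
  histograms over [0, 256), the last on raw values); S and L densities;
  and the four directed mean nearest-neighbor distances S→S, S→L, L→S,
  L→L, which summarize whether large cells grow in sheets or scatter
  among small ones.

Features whose preconditions fail (an empty group, a single point) are
*missing*, never zero — a ROI with no large cells has an undefined L→L
distance, not a zero one. The boosted trees downstream route missing
values natively, so no imputation is needed.

The cutoff is not hand-picked. `optimize_size_cutoff()` evaluates every
integer cutoff from 8 to 108 µm² and maximizes

```
(R_RT − R_aCLL) · (R_aCLL − R_CLL) · (R_RT − R_CLL)
```

where `R_c` is the mean large-cell ratio of training ROIs of class `c`.
The product is positive exactly when the ratios are ordered the way the
disease biology predicts (CLL < aCLL < RT) and grows with all three
pairwise separations; ties break to the smallest cutoff. Because the
objective uses only class labels, never phenotype labels, the cutoff is
stable across phenotype-model refits.

## Diagnosis models and evaluation

`train_classifier()` fits gradient-boosted decision trees (multiclass
softprob, depth 6, learning rate 0.3, 100 rounds, single-threaded and
seeded, hence bit-reproducible). Boosted trees are a good match for 20
mixed-scale, partially missing, collinear features on a few hundred
ROIs. Five feature strategies are compared: each family alone, all 20
fused, and an impurity-selected subset — `select_features()` fits an
extremely-randomized-trees ensemble, normalizes impurity importances to
sum to one, and keeps features at or above 0.02.

Evaluation is strictly **patient-level**: `split_cohort()` halves the
patients 1:1 within joint strata of disease class and the binary
clinical covariates (sex, age group, slide source, biopsy technique,
survival group), pooling odd leftovers within class so per-class counts
differ by at most one. Stratified halving stands in for covariate
matching between the cohorts. Because a single split of a small cohort
is noisy, `repeated_split_eval()` redraws the split (default 100×,
per-repeat seeds derived from a master seed), trains every strategy on
the identical split, and reports per-repeat accuracy and macro
one-vs-rest AUC. Strategies are compared with a one-tailed
unequal-variance t-test on the per-repeat accuracies
(`one_tailed_ttest()`; two degenerate zero-variance vectors with equal
means give p = 0.5 by convention).

## The synthetic generator

Real cohorts of this kind are small and access-restricted, so the
package ships a generator whose defaults emulate the study conditions:
a patient → slide → ROI hierarchy (1–2 slides per patient, 1–8 ROIs
per slide, 200–500 cells per ROI, 768×768 px at 0.50 µm/px), binary
covariates with mixed-cohort marginals, and per-cell attributes drawn
from three phenotype archetypes — truncated-lognormal sizes,
truncated-normal intensities, beta-distributed solidities in
[0.7, 1] — mixed per disease class so that the RT-like fraction rises
monotonically from CLL to aCLL to RT. A configurable contaminant
fraction (default 2%) redraws cells as segmentation artifacts (low
solidity or out-of-window area) to exercise the QC filter. Cells can
also be rendered into instance label masks and grayscale images
(ellipse blobs of exactly the tabulated pixel area) to test the mask
ingestion path. Every ROI's seed is derived by stable hashing of
(master seed, patient, slide, ROI), so single ROIs can be regenerated
without replaying the cohort.

Two parameter sets matter:

* `default_phenotype_params()` — overlapping archetypes (medians 14,
  16, 45 µm²; intensities 110, 160, 130): a realistic difficulty level.
* `separated_phenotype_params()` — a *benchmark* construction for
  recovery tests. The two small phenotypes share one size distribution
  truncated to 8–22 µm² and differ only in intensity (108 vs 162); the
  RT-like size support is 28–108 µm². With identical small-size
  distributions, every pairwise difference of class large-cell ratios
  at cutoff c is proportional to the same factor
  `P_RT(area > c) − P_small(area > c)`, which is maximized exactly on
  the support gap [22, 28]; the grid tie-break then selects 22. The
  cutoff search therefore has a provable target, independent of the
  class mixtures.

What the generator does **not** emulate: staining variation across
slides, spatial correlation of phenotypes within tissue (centroids are
uniform), intensity–size correlation within a phenotype, and
slide-level batch effects. Conclusions about the *spatial* features'
clinical value must come from real data; here they are exercised for
correctness, not realism.

## Null behavior

With identical phenotype mixtures in all three classes the features
carry no class signal, and mean repeated-split accuracy should sit at
the chance level 1/3. Two design points make this a fair check: the
null cohort uses a *balanced* design (equal ROI counts per patient and
class), because with unbalanced ROI counts the chance level of a
majority-leaning classifier exceeds 1/3; and the accuracy band is
measured in units of the per-repeat accuracy SD, because repeated
splits of one finite cohort are positively correlated and the nominal
standard error of their mean understates its true spread.

## Reproducibility

All randomness flows from integer seeds through a 31-bit string-hash
seed derivation (`derive_seed()`), identical across platforms. Model
fits are deterministic (seeded k-means restarts, fixed-λ ridge
regression, single-threaded seeded boosting). `scripts/acceptance.R`
reruns the headline computation from an installed copy of the package
and writes its quantities to JSON; the test suite additionally checks
the cutoff search against a brute-force oracle, clustering/mixture
recovery on the separated benchmark, chance-level behavior on null
cohorts, and the geometric and partition invariants of every feature.
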