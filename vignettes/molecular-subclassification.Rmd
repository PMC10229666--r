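---
title: "Unsupervised molecular subclassification of MDS/sAML: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised molecular subclassification of MDS/sAML: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdsmc)
```

## The problem

Myelodysplastic syndromes (MDS) and secondary acute myeloid leukemia (sAML)
are classically subtyped by morphology, blast counts and cytogenetics. Those
criteria track disease *stage* more than disease *biology*: patients with the
same molecular lesions land in different morphological categories, and
blast-defined categories mix molecularly unrelated diseases. `mdsmc`
implements an unsupervised alternative: patients are clustered purely on
their binary somatic-mutation and karyotype profiles, the resulting
molecular clusters (MCs) are characterized by their genomic signatures, and
survival analysis then asks — rather than assumes — whether the molecular
grouping carries prognostic and treatment-response information.

The pipeline has five stages, each usable on its own:

1. **Encoding** (`encode_features()`): gene-level mutation calls are OR-ed
   across variants into one 0/1 indicator per gene, optional pathway
   indicators (1 if any member gene is mutated), and eight mutually
   exclusive karyotype one-hots.
2. **Embedding** (`fit_autoencoder()`): a 16-dimensional linear autoencoder
   of the binary profiles.
3. **Consensus clustering** (`fit_clusters()`): repeated subsampling +
   Gaussian-mixture clustering in the latent space, accumulation of pairwise
   co-clustering frequencies, and silhouette-based selection of the number
   of clusters.
4. **Validation and characterization** (`cross_fold_stability()`,
   `mean_decrease_accuracy()`, `feature_frequencies()`,
   `pairwise_cooccurrence()`).
5. **Survival** (`kaplan_meier()`, `logrank_pairwise()`, `cox_ph()`,
   `aggregate_risk_groups()`, `harrell_c()`, `response_logistic()`).

## Encoding choices

**Karyotype as a mutually exclusive categorical.** The eight categories
(`NK`, `del5q`, `del7q`, `del20q`, `trisomy8`, `delY`, `complex`,
`other_abnormal`) are encoded as one-hots with exactly one active per
patient. Published cluster tables show abnormal-karyotype clusters that are
100% pure in a single category, which this encoding reflects. Raw strings
carrying several qualifying abnormalities are resolved by a fixed,
documented precedence — three or more distinct abnormalities are `complex`;
otherwise `complex > del7q > del5q > del20q > trisomy8 > delY >
other_abnormal`. How multi-abnormality patients were categorized upstream is
not documented anywhere we could rely on, so the precedence is this
package's decision; it is configurable in `normalize_karyotype()`'s alias
table and flagged in the function documentation.

**No VAF, no variant granularity.** Clustering operates on *binary* profiles,
so all variants in a gene collapse to one bit.

**Rare features.** `min_feature_frequency` defaults to 0 (keep the whole
panel). The intended mitigation for rare mutations is pathway grouping (the
default `RAS_pathway` = NRAS, KRAS, PTPN11, CBL, NF1, RIT1 — membership is a
config default, editable), not a frequency filter. Karyotype one-hots are
never dropped by the filter, so every row always carries exactly one active
category.

## The linear autoencoder

The encoder is a single linear map $Z = XW_1 + b_1$ to $d = 16$ dimensions;
the decoder maps back through a sigmoid, trained under Bernoulli
cross-entropy (squared error with a linear decoder is available). Depth is
deliberately not configurable: the embedding is specified as linear, and a
single linear layer keeps the method reproducible and interpretable.

Training is full-batch gradient descent — no minibatch nondeterminism — from
a seeded scaled-uniform initialization. The step size adapts: it is halved
whenever a step would increase the loss (and the step retried), and grown 5%
after every accepted step. The recorded loss trace is therefore monotone
non-increasing and the whole fit is a deterministic function of the seed.
Defaults (500 epochs, initial step 0.5) were chosen so the loss-decrease
invariant holds comfortably on the simulation presets; neither the loss nor
the optimizer is dictated by anything upstream, so both are package
decisions recorded in the fitted object.

## Gaussian-mixture consensus clustering

For each candidate $K$, `run_consensus()` repeats `n_iterations` times
(default 100; 50 in the package's acceptance-scale runs): draw
$\lceil 0.8 n \rceil$ patients without replacement, fit a $K$-component
Gaussian mixture to their latent coordinates, and for every co-sampled pair
increment a co-sampling counter and, if the two patients share a component,
a co-clustering counter. The consensus matrix is the elementwise ratio;
pairs never co-sampled (vanishingly rare at the default settings for
$n \ge 100$) get consensus 0 with a warning. The final partition cuts an
average-linkage tree on $1 - \text{consensus}$ — the standard
consensus-clustering reduction, chosen for determinism.

### Numerical choices that mattered

Two textbook choices fail on this data, and both failures trace to the same
fact: binary profiles embed to *exactly duplicated* latent points.

- **Variance floor.** An unfloored (or weakly floored) Gaussian likelihood
  rewards components that collapse onto stacks of duplicate points. Worse,
  EM *drifts*: started from a partition that matches the planted clusters
  almost perfectly, weakly floored EM merges clusters and splits noise
  directions within a few dozen iterations, while a strong floor holds the
  initialization essentially unchanged to convergence. The default floor is
  0.5× the mean global per-dimension variance — strong regularization
  toward near-spherical components.
- **Restart selection.** Selecting among random restarts by raw
  log-likelihood inverts quality on this geometry: degenerate spiky fits
  can dominate the likelihood of a correct partition by a wide margin, and
  reference mixture implementations with unconstrained diagonal or full
  covariance fail outright on the same coordinates. Restarts are therefore
  seeded kmeans++ initializations compared by within-cluster sum of
  squares; EM refines the best one, and the log-likelihood is used only to
  monitor convergence.

The fitted mixture (centroids, covariances, empirical weights) is stored in
the cluster model and reused verbatim by `predict()` to assign new patients
by posterior argmax, with posteriors summing to 1.

### Model-order selection

Both a latent-distance and a consensus-dissimilarity mean silhouette are
computed for every $K$, but **selection is driven by the latent-distance
silhouette**. The consensus silhouette cannot rank model orders: whenever a
coarse split is stable across subsamples its dissimilarity is ~0 within and
~1 between groups, so the silhouette saturates near 1 for *any* stable
$K$ — on data with six planted clusters it scores a stable two-way split
above the true six-way partition. The latent silhouette peaks at the
planted $K$ on the same data. Both traces are reported in
`silhouette_by_k` so users can inspect stability separately from geometry.

Ties are resolved by parsimony: all $K$ whose silhouette is within
`silhouette_tolerance` (default 0.01) of the maximum are treated as tied and
the smallest wins. Secondary signature genes at intermediate carrier
frequencies create genuine sub-structure, which makes the silhouette nearly
flat past the true $K$; the tolerance makes the selection robust to that
flatness instead of chasing noise-level differences between candidate
orders.

Final clusters are renamed `MC1..MCK` in decreasing size order. The
numbering is this package's convention and is stated in output metadata.

## Stability validation

`fold_plan()` builds five disjoint 20% test folds; each fold's training set
is the complement (the 80%/20% five-fold scheme; `split_sizes(3588, 0.8)`
is 2870/718). `cross_fold_stability()` refits the entire pipeline per fold
and compares folds two ways:

- **Symmetric ARI**: each pair of folds, on the intersection of their
  training sets, each model's own labels.
- **Asymmetric (model-transfer) ARI**: fold $g$'s training patients are
  encoded with fold $f$'s autoencoder and assigned with fold $f$'s mixture,
  then compared with fold $g$'s own labels. "Asymmetric" is not a standard
  term; we define it as this directional model-transfer agreement because it
  uses exactly the machinery the pipeline already has (encode + assign) and
  measures what a deployed model would do to unseen patients. Both matrices
  are reported.

The adjusted Rand index itself is computed from the pair-counting
contingency formula; the test suite checks it against exhaustive
pair enumeration and against an independent reference implementation.

## The latent-class baseline

The comparison baseline is a finite mixture of independent Bernoulli
features fitted by EM (`latent_class_baseline()`, order selected by BIC in
`latent_class_select()`). This is maximum-likelihood latent class analysis;
full Bayesian posterior sampling is out of scope, and the comparison claim —
the baseline resolves coarser structure than the embedding pipeline — is
testable either way. Parameters are clamped to $[10^{-4}, 1-10^{-4}]$ to
keep the likelihood finite; the log-likelihood trace is non-decreasing
within a run.

## Cluster characterization

"Mean decrease in accuracy" is realized as out-of-bag permutation importance
of a bagged-tree classifier: a ranger forest with `mtry = p` (pure bagging,
500 trees by default), OOB majority-vote accuracy as the baseline, and for
each feature the mean accuracy drop over `n_permutations` (default 10)
seeded column permutations, evaluated with the same OOB masking. Features
with importance ≥ 0.01 are flagged important. A constant column scores
exactly 0 (permutation changes nothing), and the whole computation is
bit-reproducible under a fixed seed. Whether importance should be one
multiclass model or per-cluster one-vs-rest is ambiguous; both are provided
(`mean_decrease_accuracy()` drives the flag,
`mean_decrease_accuracy_by_cluster()` gives per-cluster tables).

Per-cluster feature frequencies are within-cluster column means, and
pairwise co-occurrence is the fraction of cluster members carrying both
features, emitted as a tidy long table (the data behind circos-style
diagrams; no graphical circos rendering is attempted).

## Survival layer

Kaplan-Meier estimation (Greenwood variance, log-log 95% bands), pairwise
two-group log-rank tests (χ² on 1 df, with $-\log_{10} p$ for heatmaps), and
Cox proportional hazards with **Efron tie handling** (follow-up is recorded
in months, so ties are heavy) are all delegated to the survival package
behind this package's tabular interfaces. Harrell's C uses the
censoring-aware usable-pair definition (ties in score count ½);
`bootstrap_c_difference()` compares two risk scores by paired patient
resampling with a percentile interval.

**Risk-group aggregation** makes an otherwise manual step algorithmic. The
landmark $t^\*$ is the largest time at which every cluster's survival still
exceeds `survival_floor` (default 0.25, itself an arbitrary but conventional
choice). Each cluster is represented by its curve on an even grid over
$[0, t^\*]$; pairwise distances are root-mean-square differences
standardized by the pooled Greenwood standard error, so curves that differ
only by sampling noise sit at comparable small distances regardless of how
steep they are. The average-linkage tree is cut either at a requested
`n_groups` or at the fixed height `merge_threshold = 2`: clusters whose
curves differ by less than about two pooled standard errors are judged
statistically indistinguishable and share a risk group. (An earlier design
cut at the largest gap in merge heights; it was discarded because the
landmark window compresses differences between long-surviving clusters, so
the largest gap systematically merged the top tiers.) Groups are numbered
best-to-worst by median overall survival.

HMA-response analysis is a multivariate logistic regression of the binary
response on cluster membership (user-declared reference cluster) and
covariates, reporting odds ratios with Wald intervals and flagging
separation. Response labels (CR/mCR/HI) are consumed as given; no response
adjudication is performed. Covariate coding in the survival models defaults
to continuous (age, blast %) — the exact coding used upstream is unstated,
so the default is documented rather than guessed at.

## The synthetic cohort generator

`simulate_cohort()` draws from an explicit latent-class model: cluster
membership from `mixing_weights`; gene bits as independent within-cluster
Bernoullis; karyotype from a per-cluster categorical over the eight levels;
survival from per-cluster Weibulls (exponential is the shape-1 special
case — Weibull spans proportional and non-proportional hazards regimes);
exponential plus administrative censoring; cluster-dependent treatment
flags and response labels. One master seed expands into named per-stage
substreams, so adding a field never perturbs earlier draws and cohorts are
bit-reproducible.

`preset_mds_like()` plants six clusters over the default 40-gene myeloid
panel, loosely imitating published signatures: NK+SF3B1, NK+TET2+ZRSR2,
del5q, NK+ASXL1+SRSF2+RUNX1, del7q+RAS-pathway, and complex+TP53 with the
shortest survival. Signature genes carry probability ~0.97 against a 0.015
background — mirroring the near-100% carrier purity that published cluster
tables report — and the Weibull scales form three planted risk tiers
(90/90, 40/40, 14/12 months) under exponential censoring at rate
0.008/month with a 180-month administrative horizon, giving a realistic
~30% censored fraction. Clinical covariates (age ~72, Hb ~10 g/dL,
platelets ~110, WBC ~4.5) match typical MDS cohort medians.

What the generator deliberately does **not** emulate: variant allele
fractions and clonal hierarchy, within-cluster mutation correlations beyond
the latent class (real co-mutation patterns are richer), panel or assay
differences between centers, covariate–genotype dependence, and
non-proportional treatment effects. Passing tests on these cohorts
demonstrate that the machinery recovers the structure it assumes — latent
classes with near-pure signatures — not that real MDS data contain exactly
fourteen clusters.

## Problem sizes and determinism

The test suite and the acceptance script exercise the pipeline at
n = 2000 patients, latent dimension 16, 500 training epochs, K grid 2–10,
50 consensus iterations and 5 restarts per mixture fit — sizes chosen so a
full run completes in minutes on a single core while keeping the recovery
margins wide (cluster recovery ARI ≈ 0.95, five-fold minimum symmetric ARI
≈ 0.97 on the preset). Every stochastic stage consumes a named substream of
one master seed; rerunning any entry point with the same inputs and seed
reproduces its numeric output bit for bit.

## Known limitations

- The Gaussian-mixture variance floor (0.5× mean variance) is a strong
  regularizer chosen for the geometry of embedded binary panels; on dense
  continuous data a smaller floor may be preferable.
- Silhouette-based selection inherits silhouette's bias toward balanced,
  convex clusters; the parsimony tolerance mitigates but does not remove
  flat-maximum ambiguity.
- The risk-grouping `merge_threshold` treats grid points as if their
  standardized differences were independent, which they are not; 2 is a
  conservative conventional default, not a calibrated test level.
- `latent_class_baseline()` is maximum-likelihood EM; it does not quantify
  posterior uncertainty over class assignments.
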