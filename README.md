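# mdsmc

Unsupervised molecular subclassification of myelodysplastic syndromes (MDS)
and secondary acute myeloid leukemia (sAML) from binary mutation and
karyotype profiles.

`mdsmc` is for biostatisticians and translational hematology groups who have
per-patient gene-level mutation calls (a targeted myeloid panel),
cytogenetic categories and survival follow-up, and who want to subtype
patients by molecular pattern alone — independently of blast counts,
morphology or clinical scores — and then ask whether the resulting clusters
carry prognostic and treatment-response information.

## Method

Patients are encoded as a binary matrix $X \in \{0,1\}^{n \times p}$: one
indicator per panel gene (all variants OR-ed), optional pathway indicators,
and eight mutually exclusive karyotype one-hots. The pipeline is:

1. **Linear autoencoder.** A 16-dimensional linear embedding
   $Z = XW_1 + b_1$ trained with a sigmoid decoder under Bernoulli
   cross-entropy by deterministic full-batch gradient descent.
2. **Subsample consensus clustering.** For each candidate $K$: repeatedly
   draw 80% of patients, fit a $K$-component Gaussian mixture on their
   latent coordinates, and record for every co-sampled pair whether they
   share a component. The consensus matrix
   $C_{ij} = \frac{\#\text{co-clustered}}{\#\text{co-sampled}}$ is cut by
   average-linkage agglomeration on $1 - C$.
3. **Model order by silhouette.** $K$ maximizes the mean silhouette
   $s_i = (b_i - a_i)/\max(a_i, b_i)$ of the consensus partition in latent
   space (near-ties resolve to the smaller $K$). Clusters are named
   `MC1..MCK` by decreasing size, and new patients are assigned by the
   stored mixture posterior.
4. **Validation.** Five-fold refits compared by symmetric and
   model-transfer adjusted Rand index; a Bernoulli-mixture (latent class)
   EM baseline for comparison.
5. **Characterization.** Per-cluster feature frequencies, pairwise
   co-occurrence, and permutation importance (mean decrease in out-of-bag
   accuracy of a bagged-tree classifier, important at ≥ 0.01).
6. **Survival.** Kaplan-Meier curves, pairwise log-rank tests, Cox
   proportional hazards (Efron ties), Harrell's C with bootstrap
   comparison, HMA-response logistic regression, and aggregation of
   clusters into risk groups: at the landmark $t^*$ — the largest time at
   which every cluster's survival exceeds 0.25 — clusters whose curves are
   statistically indistinguishable (≲ 2 pooled standard errors, RMS over
   the landmark grid) share a risk group.

A synthetic-cohort generator (`simulate_cohort()`, `preset_mds_like()`)
plants latent-class structure — cluster-specific Bernoulli gene profiles,
karyotype categories, Weibull survival tiers, censoring, treatment and
response labels — so the full pipeline is testable without access to any
patient-level data. See the vignette
(`vignettes/molecular-subclassification.Rmd`) for the model, parameter
defaults and design rationale.

## Worked example

```r
library(mdsmc)

# simulate a 500-patient cohort from the documented 6-cluster preset
cohort   <- simulate_cohort(preset_mds_like(), n_patients = 500, seed = 1)
features <- encode_features(cohort)

embedding <- fit_autoencoder(features, embedding_config(seed = 1))
fit <- fit_clusters(embedding,
                    consensus_config(n_iterations = 30, k_grid = 2:10, seed = 1))
fit
#> <mds_cluster_model> 500 patients; K = 6 (silhouette 0.421)
#>   cluster sizes: MC1=137 MC2=106 MC3=75 MC4=65 MC5=60 MC6=57

adjusted_rand_index(fit$labels, cohort$true_cluster)
#> [1] 0.9407658

surv <- dplyr::mutate(cohort, cluster = tidy(fit)$cluster)
aggregate_risk_groups(surv)
#> <mds_risk_grouping> 6 clusters -> 3 risk groups (t* = 15.95 months)
#> # A tibble: 3 x 6
#>   risk_group     n n_events median_os conf_low conf_high
#>        <int> <int>    <int>     <dbl>    <dbl>     <dbl>
#> 1          1   243      136     64.7     56.8       71.2
#> 2          2   140      110     24.1     18.0       29.4
#> 3          3   117      101      8.27     6.36      10.4
```

The silhouette trace selects six clusters — the number planted by the
preset — and the partition agrees with the planted labels at ARI 0.94.
Risk aggregation recovers the preset's three planted survival tiers
(median overall survival 65, 24 and 8 months, best to worst), each with a
95% confidence interval from the pooled Kaplan-Meier fit.

Every result object has `tidy()`/`glance()` methods returning tibbles, and
`autoplot()`/`plot_*()` functions (silhouette trace, consensus heatmap,
KM curves, log-rank heatmap, cluster signatures).

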