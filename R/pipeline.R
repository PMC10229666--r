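# End-to-end orchestration: encode -> embed -> cluster -> validate ->
# characterize -> survive, with deterministic per-stage seed substreams, an
# artifact directory, a reproducibility manifest, and optional resume from
# cached stage results.

flag_column <- function(cohort, flag) {
  if (!"treatment_flags" %in% names(cohort)) return(rep(0L, nrow(cohort)))
  vapply(cohort$treatment_flags, function(f) as.integer(flag %in% f),
         integer(1))
}

config_hash <- function(x) {
  key <- paste(deparse(x), collapse = "")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

pipeline_stage <- function(name, out_dir, resume, compute) {
  cache <- if (!is.null(out_dir)) file.path(out_dir, "cache",
                                            paste0(name, ".rds"))
  if (resume && !is.null(cache) && file.exists(cache)) {
    inform(sprintf("stage `%s`: reusing cached result.", name))
    return(readRDS(cache))
  }
  res <- tryCatch(compute(), error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", name,
                  conditionMessage(e)))
  })
  if (!is.null(cache)) {
    dir.create(dirname(cache), recursive = TRUE, showWarnings = FALSE)
    saveRDS(res, cache)
  }
  res
}

#' Run the full subclassification pipeline
#'
#' Executes encoding, autoencoder embedding, consensus clustering with
#' silhouette model-order selection, optional cross-fold stability
#' validation, cluster characterization (frequencies, permutation
#' importance, co-occurrence), and the survival layer (pairwise log-rank,
#' risk-group aggregation, Kaplan-Meier by risk group, covariate-adjusted
#' Cox). Every stage derives its own seed substream from `seed`, so a rerun
#' with the same inputs reproduces all numeric outputs bit-for-bit. When
#' `out_dir` is given, tabular artifacts (TSV/JSON) plus a manifest are
#' written and stage results are cached; `resume = TRUE` reuses cached
#' stages after an interruption.
#'
#' @param cohort A `mds_cohort` tibble (e.g. [read_cohort()] or
#'   [simulate_cohort()]).
#' @param schema A [cohort_schema()].
#' @param embed_config An [embedding_config()] (its seed is re-derived from
#'   `seed`).
#' @param consensus_cfg A [consensus_config()] (idem).
#' @param importance_cfg An [importance_config()] (idem).
#' @param survival_floor Landmark floor for risk grouping (default 0.25).
#' @param n_risk_groups Optional fixed number of risk groups.
#' @param n_folds Stability-validation folds; `NULL` skips the validation
#'   stage.
#' @param out_dir Optional artifact directory.
#' @param resume Reuse cached stage results from `out_dir` (default FALSE).
#' @param seed Master seed.
#' @return An object of class `mds_pipeline`: `features`, `embedding`,
#'   `clusters`, `stability` (or NULL), `frequencies`, `importance`,
#'   `cooccurrence`, `logrank`, `risk_groups`, `km_risk`, `cox`,
#'   `manifest`.
#' @export
run_pipeline <- function(cohort,
                         schema = cohort_schema(),
                         embed_config = embedding_config(),
                         consensus_cfg = consensus_config(),
                         importance_cfg = importance_config(),
                         survival_floor = 0.25,
                         n_risk_groups = NULL,
                         n_folds = NULL,
                         out_dir = NULL,
                         resume = FALSE,
                         seed = 1L) {
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  embed_config$seed <- substream_seed(seed, "embed")
  consensus_cfg$seed <- substream_seed(seed, "consensus")
  importance_cfg$seed <- substream_seed(seed, "importance")

  features <- pipeline_stage("encode", out_dir, resume, function() {
    encode_features(cohort, schema)
  })
  embedding <- pipeline_stage("embed", out_dir, resume, function() {
    fit_autoencoder(features, embed_config)
  })
  clusters <- pipeline_stage("cluster", out_dir, resume, function() {
    fit_clusters(embedding, consensus_cfg)
  })

  stability <- NULL
  if (!is.null(n_folds)) {
    stability <- pipeline_stage("validate", out_dir, resume, function() {
      plan <- fold_plan(nrow(cohort), n_folds,
                        seed = substream_seed(seed, "folds"))
      cross_fold_stability(features, plan, embed_config, consensus_cfg)
    })
  }

  labels <- tidy(clusters)$cluster
  characterization <- pipeline_stage("characterize", out_dir, resume,
                                     function() {
    list(frequencies = feature_frequencies(features, labels),
         importance = mean_decrease_accuracy(features, labels,
                                             importance_cfg),
         cooccurrence = pairwise_cooccurrence(features, labels))
  })

  survive <- pipeline_stage("survive", out_dir, resume, function() {
    dat <- dplyr::mutate(cohort, cluster = labels,
                         hma = flag_column(cohort, "HMA"),
                         hsct = flag_column(cohort, "HSCT"))
    lr <- logrank_pairwise(dat, group = "cluster")
    rg <- aggregate_risk_groups(dat, cluster = "cluster",
                                survival_floor = survival_floor,
                                n_groups = n_risk_groups)
    dat <- dplyr::left_join(
      dat, dplyr::mutate(rg$mapping, cluster = factor(.data$cluster,
                                                      levels(labels))),
      by = "cluster")
    dat$risk_group <- factor(dat$risk_group)
    km <- kaplan_meier(dat, by = "risk_group")
    cox_covs <- c("risk_group",
                  intersect(c("age", "sex", "blast_pct"), names(dat)),
                  if (any(dat$hma == 1L)) "hma",
                  if (any(dat$hsct == 1L)) "hsct")
    cox <- tryCatch(cox_ph(dat, covariates = cox_covs),
                    error = function(e) NULL)
    list(logrank = lr, risk_groups = rg, km_risk = km, cox = cox,
         data = dat)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("mdsmc")),
    seed = as.integer(seed),
    n_patients = nrow(cohort),
    n_features = ncol(features) - 1L,
    k_selected = clusters$k_selected,
    config_hash = config_hash(list(schema, embed_config, consensus_cfg,
                                   importance_cfg, survival_floor,
                                   n_risk_groups, n_folds, seed)))

  result <- structure(list(
    features = features, embedding = embedding, clusters = clusters,
    stability = stability,
    frequencies = characterization$frequencies,
    importance = characterization$importance,
    cooccurrence = characterization$cooccurrence,
    logrank = survive$logrank, risk_groups = survive$risk_groups,
    km_risk = survive$km_risk, cox = survive$cox, data = survive$data,
    manifest = manifest), class = "mds_pipeline")

  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  readr::write_tsv(tidy(result$clusters), file.path(out_dir, "labels.tsv"))
  readr::write_tsv(result$clusters$silhouette_by_k,
                   file.path(out_dir, "silhouette.tsv"))
  readr::write_tsv(result$frequencies, file.path(out_dir, "signatures.tsv"))
  readr::write_tsv(result$importance, file.path(out_dir, "importance.tsv"))
  readr::write_tsv(result$cooccurrence,
                   file.path(out_dir, "cooccurrence.tsv"))
  readr::write_tsv(result$logrank, file.path(out_dir, "logrank.tsv"))
  jsonlite::write_json(
    list(mapping = result$risk_groups$mapping,
         summary = result$risk_groups$group_summary,
         t_star = result$risk_groups$t_star),
    file.path(out_dir, "risk_groups.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(result$stability)) {
    jsonlite::write_json(
      list(k_by_fold = result$stability$k_by_fold,
           modal_k = result$stability$modal_k,
           min_ari_symmetric = result$stability$min_ari_symmetric,
           min_ari_asymmetric = result$stability$min_ari_asymmetric),
      file.path(out_dir, "stability.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.mds_pipeline <- function(x, ...) {
  cat("<mds_pipeline>\n")
  print(x$clusters)
  print(x$risk_groups)
  invisible(x)
}

#' A small packaged synthetic cohort
#'
#' Convenience fixture: ~200 patients simulated from [preset_mds_like()],
#' used throughout the unit tests and examples.
#'
#' @param seed Seed (default 42).
#' @param n_patients Cohort size (default 200).
#' @return A `mds_cohort` tibble with `true_cluster` labels.
#' @export
make_fixture <- function(seed = 42L, n_patients = 200L) {
  simulate_cohort(preset_mds_like(), n_patients = n_patients, seed = seed)
}
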