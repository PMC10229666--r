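# Cluster signatures: per-cluster feature frequencies, permutation
# importance (mean decrease in out-of-bag accuracy of a bagged-tree
# classifier), and within-cluster pairwise co-occurrence.

check_labels_align <- function(X, labels) {
  if (length(labels) != nrow(X)) {
    abort("`labels` must have one entry per row of the feature matrix.")
  }
}

#' Per-cluster feature frequencies
#'
#' Column means of the binary feature matrix within each cluster: the
#' fraction of cluster members carrying each feature.
#'
#' @param features A `mds_features` tibble or 0/1 matrix.
#' @param labels Cluster labels aligned with rows (any atomic vector or
#'   factor).
#' @return A tibble `cluster`, `feature`, `frequency` (long format).
#' @export
feature_frequencies <- function(features, labels) {
  X <- if (is.matrix(features)) features else as_feature_matrix(features)
  check_labels_align(X, labels)
  labs <- as.factor(labels)
  if (any(table(labs) == 0L)) abort("empty cluster in `labels`.")
  purrr::map_dfr(levels(labs), function(cl) {
    tibble::tibble(cluster = cl, feature = colnames(X),
                   frequency = unname(colMeans(X[labs == cl, , drop = FALSE])))
  }) |>
    dplyr::mutate(cluster = factor(.data$cluster, levels = levels(labs)),
                  feature = factor(.data$feature, levels = colnames(X)))
}

#' Within-cluster pairwise feature co-occurrence
#'
#' For each cluster and ordered feature pair, the fraction of cluster
#' members carrying both features (the data behind circos-style
#' co-occurrence diagrams). The diagonal pair `(f, f)` equals the feature's
#' frequency.
#'
#' @inheritParams feature_frequencies
#' @return A tibble `cluster`, `feature_a`, `feature_b`, `co_occurrence`
#'   (long format, both orientations plus the diagonal).
#' @export
pairwise_cooccurrence <- function(features, labels) {
  X <- if (is.matrix(features)) features else as_feature_matrix(features)
  check_labels_align(X, labels)
  labs <- as.factor(labels)
  purrr::map_dfr(levels(labs), function(cl) {
    sub <- X[labs == cl, , drop = FALSE]
    co <- crossprod(sub) / nrow(sub)
    grid <- tidyr::expand_grid(feature_a = colnames(X),
                               feature_b = colnames(X))
    grid$co_occurrence <- co[cbind(match(grid$feature_a, colnames(X)),
                                   match(grid$feature_b, colnames(X)))]
    grid$cluster <- cl
    grid[, c("cluster", "feature_a", "feature_b", "co_occurrence")]
  }) |>
    dplyr::mutate(cluster = factor(.data$cluster, levels = levels(labs)))
}

#' Configure permutation importance
#'
#' @param n_trees Trees in the bagged forest (default 500).
#' @param n_permutations Independent permutations per feature whose accuracy
#'   drops are averaged (default 10).
#' @param importance_cutoff Features with mean decrease in accuracy at or
#'   above this are flagged important (default 0.01).
#' @param seed Seed.
#' @return A list of class `mds_importance_config`.
#' @export
importance_config <- function(n_trees = 500L, n_permutations = 10L,
                              importance_cutoff = 0.01, seed = 1L) {
  check_scalar_number(n_trees, "n_trees", 1)
  check_scalar_number(n_permutations, "n_permutations", 1)
  check_scalar_number(importance_cutoff, "importance_cutoff", 0)
  structure(list(n_trees = as.integer(n_trees),
                 n_permutations = as.integer(n_permutations),
                 importance_cutoff = importance_cutoff,
                 seed = as.integer(seed)),
            class = "mds_importance_config")
}

# Out-of-bag majority-vote accuracy for a ranger forest given a (possibly
# column-permuted) feature matrix. `inbag` is n x trees counts.
oob_vote_accuracy <- function(forest, X, y_int, inbag, n_class) {
  preds <- predict(forest, data = as.data.frame(X),
                   predict.all = TRUE)$predictions  # n x trees class indices
  oob <- inbag == 0L
  votes <- vapply(seq_len(nrow(X)), function(i) {
    p <- preds[i, oob[i, ]]
    if (length(p) == 0L) return(NA_integer_)
    which.max(tabulate(p, nbins = n_class))  # ties -> lowest class index
  }, integer(1))
  mean(votes == y_int, na.rm = TRUE)
}

#' Permutation importance as mean decrease in accuracy
#'
#' Trains a bagged-tree classifier (ranger with `mtry = p`) predicting
#' cluster labels from the binary features, then measures each feature's
#' importance as the mean, over `n_permutations` seeded permutations, of the
#' drop in out-of-bag majority-vote accuracy when that feature's column is
#' permuted. Features at or above `importance_cutoff` are flagged
#' important. Fully reproducible under a fixed seed; a constant column has
#' importance exactly 0.
#'
#' @inheritParams feature_frequencies
#' @param config An [importance_config()].
#' @return A tibble `feature`, `importance`, `important` (logical), sorted
#'   by decreasing importance; attribute `oob_accuracy` holds the baseline.
#' @export
mean_decrease_accuracy <- function(features, labels,
                                   config = importance_config()) {
  X <- if (is.matrix(features)) features else as_feature_matrix(features)
  check_labels_align(X, labels)
  y <- as.factor(labels)
  if (nlevels(droplevels(y)) < 2L) {
    abort("importance needs at least 2 clusters.")
  }
  y <- droplevels(y)
  y_int <- as.integer(y)
  df <- as.data.frame(X)

  forest <- ranger::ranger(
    x = df, y = y, num.trees = config$n_trees, mtry = ncol(X),
    min.node.size = 1, keep.inbag = TRUE, seed = config$seed,
    num.threads = 1)
  inbag <- do.call(cbind, forest$inbag.counts)
  n_class <- nlevels(y)

  base_acc <- oob_vote_accuracy(forest, X, y_int, inbag, n_class)

  n <- nrow(X)
  perms <- with_seed(substream_seed(config$seed, "perm"), {
    lapply(seq_len(config$n_permutations), function(r) sample.int(n))
  })
  imp <- vapply(seq_len(ncol(X)), function(j) {
    if (length(unique(X[, j])) == 1L) return(0)  # permuting changes nothing
    drops <- vapply(perms, function(pr) {
      Xp <- X
      Xp[, j] <- X[pr, j]
      base_acc - oob_vote_accuracy(forest, Xp, y_int, inbag, n_class)
    }, numeric(1))
    mean(drops)
  }, numeric(1))

  out <- tibble::tibble(feature = colnames(X), importance = imp,
                        important = imp >= config$importance_cutoff)
  out <- dplyr::arrange(out, dplyr::desc(.data$importance))
  attr(out, "oob_accuracy") <- base_acc
  out
}

#' One-vs-rest permutation importance per cluster
#'
#' Runs [mean_decrease_accuracy()] separately for each cluster against the
#' rest, giving per-cluster signatures; the global multiclass run drives the
#' overall "important" flag.
#'
#' @inheritParams mean_decrease_accuracy
#' @return A tibble `cluster`, `feature`, `importance`, `important`.
#' @export
mean_decrease_accuracy_by_cluster <- function(features, labels,
                                              config = importance_config()) {
  labs <- as.factor(labels)
  purrr::map_dfr(levels(labs), function(cl) {
    cfg <- config
    cfg$seed <- substream_seed(config$seed, "ovr", cl)
    res <- mean_decrease_accuracy(features,
                                  factor(ifelse(labs == cl, cl, "rest")),
                                  cfg)
    dplyr::mutate(res, cluster = cl, .before = 1L)
  })
}

#' Plot cluster mutation signatures
#'
#' Bar panels of per-cluster feature frequencies, optionally starring
#' features flagged important.
#'
#' @param frequencies Output of [feature_frequencies()].
#' @param importance Optional output of [mean_decrease_accuracy()].
#' @param min_frequency Hide features below this frequency in every cluster
#'   (default 0.05) to keep panels readable.
#' @return A ggplot object.
#' @export
plot_cluster_signatures <- function(frequencies, importance = NULL,
                                    min_frequency = 0.05) {
  keep <- frequencies |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(mx = max(.data$frequency)) |>
    dplyr::filter(.data$mx >= min_frequency)
  df <- dplyr::semi_join(frequencies, keep, by = "feature")
  if (!is.null(importance)) {
    df <- dplyr::left_join(df,
                           importance[, c("feature", "important")],
                           by = "feature")
  } else {
    df$important <- FALSE
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$frequency,
                                   fill = .data$important)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$cluster)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "carrier frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
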