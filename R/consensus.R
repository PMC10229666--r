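# Subsample consensus clustering in latent space: repeatedly subsample
# patients, cluster each subsample with a Gaussian mixture, accumulate
# pairwise co-clustering frequencies, derive the final partition by
# agglomeration on consensus dissimilarity, and select the number of
# clusters by mean silhouette.

#' Configure consensus clustering
#'
#' @param n_iterations Subsampling iterations per candidate K (default 100).
#' @param subsample_fraction Fraction of patients drawn (without
#'   replacement) per iteration, in (0, 1] (default 0.8).
#' @param k_grid Ordered candidate cluster counts (default 2:20).
#' @param gmm_covariance `"diagonal"` (default) or `"full"` component
#'   covariance.
#' @param gmm_restarts Random restarts per mixture fit; the fit with the
#'   best log-likelihood wins (default 5).
#' @param final_linkage Agglomeration linkage on consensus dissimilarity:
#'   `"average"` (default) or `"complete"`.
#' @param silhouette_tolerance Parsimony band for model-order selection:
#'   candidate K whose mean silhouette is within this of the maximum are
#'   treated as tied, and the smallest tied K is selected (default 0.01).
#' @param seed Master seed; each (K, iteration) pair derives its own
#'   substream, so results do not depend on the order of `k_grid`.
#' @return A list of class `mds_consensus_config`.
#' @export
consensus_config <- function(n_iterations = 100L, subsample_fraction = 0.8,
                             k_grid = 2:20,
                             gmm_covariance = c("diagonal", "full"),
                             gmm_restarts = 5L,
                             final_linkage = c("average", "complete"),
                             silhouette_tolerance = 0.01,
                             seed = 1L) {
  gmm_covariance <- match.arg(gmm_covariance)
  final_linkage <- match.arg(final_linkage)
  check_scalar_number(n_iterations, "n_iterations", 1)
  check_scalar_number(subsample_fraction, "subsample_fraction", 1e-9, 1)
  check_scalar_number(silhouette_tolerance, "silhouette_tolerance", 0, 1)
  if (length(k_grid) == 0L || any(k_grid < 2L)) {
    abort("`k_grid` must be non-empty with all values >= 2.")
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 subsample_fraction = subsample_fraction,
                 k_grid = sort(unique(as.integer(k_grid))),
                 gmm_covariance = gmm_covariance,
                 gmm_restarts = as.integer(gmm_restarts),
                 final_linkage = final_linkage,
                 silhouette_tolerance = silhouette_tolerance,
                 seed = as.integer(seed)),
            class = "mds_consensus_config")
}

embedding_coords <- function(x) {
  if (inherits(x, "mds_embedding")) x$coordinates
  else if (is.matrix(x)) x
  else abort("expected a `mds_embedding` or a coordinate matrix.")
}

#' Build the consensus matrix for a fixed number of clusters
#'
#' For each iteration, draws `ceiling(subsample_fraction * n)` patients
#' without replacement, fits a K-component Gaussian mixture on their latent
#' coordinates (best of `gmm_restarts` by log-likelihood), and increments,
#' for every co-sampled pair, a co-sampling count and — when the two
#' patients land in the same component — a co-clustering count. The
#' consensus entry is their ratio; pairs never co-sampled get consensus 0
#' with a warning. The diagonal is 1 by convention.
#'
#' @param embedding A `mds_embedding` (or bare coordinate matrix).
#' @param k Number of mixture components (>= 2).
#' @param config A [consensus_config()].
#' @return An object of class `mds_consensus` with `consensus`,
#'   `co_cluster`, `co_sample` (n x n matrices) and `patient_ids`.
#' @export
run_consensus <- function(embedding, k, config = consensus_config()) {
  Z <- embedding_coords(embedding)
  n <- nrow(Z)
  k <- as.integer(k)
  if (k < 2L) abort("`k` must be >= 2.")
  if (k >= n) abort("`k` must be smaller than the number of patients.")
  m <- as.integer(ceiling(config$subsample_fraction * n))

  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  for (it in seq_len(config$n_iterations)) {
    it_seed <- substream_seed(config$seed, "consensus", k, it)
    idx <- with_seed(substream_seed(it_seed, "subsample"),
                     sort(sample.int(n, m)))
    fit <- fit_gmm(Z[idx, , drop = FALSE], k,
                   restarts = config$gmm_restarts,
                   seed = substream_seed(it_seed, "gmm"),
                   cov_type = config$gmm_covariance)
    s <- numeric(n); s[idx] <- 1
    co_sample <- co_sample + tcrossprod(s)
    memb <- matrix(0, n, k)
    memb[cbind(idx, fit$labels)] <- 1
    co_cluster <- co_cluster + tcrossprod(memb)
  }

  consensus <- matrix(0, n, n)
  pos <- co_sample > 0
  consensus[pos] <- co_cluster[pos] / co_sample[pos]
  never <- sum(!pos[upper.tri(pos)])
  if (never > 0L) {
    warn(sprintf(
      "%d patient pair(s) were never co-sampled; their consensus is set to 0.",
      never))
  }
  diag(consensus) <- 1
  ids <- rownames(Z) %||% as.character(seq_len(n))
  structure(list(consensus = consensus, co_cluster = co_cluster,
                 co_sample = co_sample, patient_ids = ids, k = k,
                 config = config),
            class = "mds_consensus")
}

#' @export
print.mds_consensus <- function(x, ...) {
  cat("<mds_consensus> ", length(x$patient_ids), " patients, K = ", x$k,
      ", ", x$config$n_iterations, " iterations\n", sep = "")
  invisible(x)
}

#' Cut a consensus matrix into a final partition
#'
#' Hierarchical agglomeration (average or complete linkage) on the
#' dissimilarity `1 - consensus`, cut into `k` groups. Deterministic.
#'
#' @param consensus A `mds_consensus` object or a bare consensus matrix.
#' @param k Number of groups (>= 1).
#' @param linkage `"average"` (default) or `"complete"`.
#' @return Integer label vector in `1..k`.
#' @export
consensus_partition <- function(consensus, k,
                                linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  C <- if (inherits(consensus, "mds_consensus")) consensus$consensus
       else consensus
  n <- nrow(C)
  if (k > n) abort("`k` exceeds the number of patients.")
  if (k > nrow(unique(C))) {
    abort("`k` exceeds the number of distinct consensus profiles.")
  }
  if (k == 1L) return(rep(1L, n))
  hc <- hclust(as.dist(1 - C), method = linkage)
  unname(cutree(hc, k = k))
}

# Mean silhouette width of `labels` under a dissimilarity matrix.
mean_silhouette <- function(labels, D) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  sil <- cluster::silhouette(as.integer(labels), dmatrix = D)
  mean(sil[, "sil_width"])
}

relabel_by_size <- function(labels) {
  sizes <- table(labels)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  map <- integer(length(sizes))
  map[as.integer(names(sizes))[ord]] <- seq_along(ord)
  map[labels]
}

#' Fit the consensus cluster model with silhouette model-order selection
#'
#' For every K in `config$k_grid`: builds the consensus matrix
#' ([run_consensus()]), cuts it into K groups ([consensus_partition()]), and
#' scores the partition by mean silhouette. Two silhouette traces are
#' recorded — on latent Euclidean distance and on the consensus
#' dissimilarity `1 - consensus` — and the selected K maximizes the latent
#' silhouette (ties go to the smaller K). The consensus silhouette is
#' reported for stability inspection but does not drive selection, because
#' it saturates near 1 at any K whose coarse split is stable across
#' subsamples, so it cannot rank model orders. Final clusters are renamed `MC1..MCK` in decreasing size
#' order, and per-cluster latent centroids, covariances and weights are
#' stored so new patients can be assigned by Gaussian-mixture posterior.
#'
#' @param embedding A `mds_embedding` from [fit_autoencoder()].
#' @param config A [consensus_config()].
#' @return An object of class `mds_cluster_model`: `k_selected`, `labels`
#'   (integer, size-ordered), `cluster_names`, `silhouette_by_k` (tibble),
#'   `consensus` (the selected K's `mds_consensus`), `centroids`,
#'   `covariances`, `weights`, `patient_ids`, `config`.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(preset_mds_like(), n_patients = 150, seed = 1)
#' emb <- fit_autoencoder(encode_features(coh),
#'                        embedding_config(latent_dim = 8, epochs = 150))
#' fit <- fit_clusters(emb, consensus_config(n_iterations = 20, k_grid = 4:8,
#'                                           gmm_restarts = 2))
#' glance(fit)
#' }
#' @export
fit_clusters <- function(embedding, config = consensus_config()) {
  Z <- embedding_coords(embedding)
  n <- nrow(Z)
  k_grid <- config$k_grid[config$k_grid < n]
  if (length(k_grid) == 0L) abort("no admissible K in `k_grid` (need K < n).")
  D_latent <- as.matrix(dist(Z))

  sil_cons <- sil_lat <- rep(NA_real_, length(k_grid))
  labels_by_k <- vector("list", length(k_grid))
  for (i in seq_along(k_grid)) {
    k <- k_grid[i]
    cons <- run_consensus(Z, k, config)
    labels <- consensus_partition(cons, k, linkage = config$final_linkage)
    labels_by_k[[i]] <- labels
    D_cons <- 1 - cons$consensus
    sil_cons[i] <- mean_silhouette(labels, D_cons)
    sil_lat[i] <- mean_silhouette(labels, D_latent)
  }

  # Selection is driven by the latent-distance silhouette: the consensus
  # dissimilarity saturates at small K whenever a coarse split is stable
  # (within 0, between 1 -> silhouette ~1 regardless of K), so it cannot
  # rank model orders; both traces are reported. Candidates within
  # `silhouette_tolerance` of the maximum count as tied and the smallest
  # tied K wins (parsimony).
  if (all(!is.finite(sil_lat))) abort("silhouette undefined for every K.")
  tied <- which(sil_lat >= max(sil_lat, na.rm = TRUE) -
                  config$silhouette_tolerance)
  i_sel <- tied[1L]
  k_sel <- k_grid[i_sel]
  labels <- relabel_by_size(labels_by_k[[i_sel]])
  # rebuild the selected K's consensus matrix (substreams make it identical
  # to the in-loop run) rather than keeping all K matrices in memory
  best_cons <- run_consensus(Z, k_sel, config)
  d <- ncol(Z)
  centroids <- matrix(0, k_sel, d, dimnames = list(NULL, colnames(Z)))
  covariances <- if (config$gmm_covariance == "full") {
    vector("list", k_sel)
  } else {
    matrix(0, k_sel, d, dimnames = list(NULL, colnames(Z)))
  }
  weights <- numeric(k_sel)
  gvar <- pmax(apply(Z, 2L, var), 1e-4)
  for (k in seq_len(k_sel)) {
    members <- Z[labels == k, , drop = FALSE]
    weights[k] <- nrow(members) / n
    centroids[k, ] <- colMeans(members)
    if (config$gmm_covariance == "full") {
      covariances[[k]] <- if (nrow(members) > d) {
        stats::cov(members) + diag(1e-4, d)
      } else diag(gvar, d)
    } else {
      v <- if (nrow(members) > 1L) apply(members, 2L, var) else gvar
      covariances[k, ] <- pmax(v, 1e-4)
    }
  }

  ids <- rownames(Z) %||% as.character(seq_len(n))
  structure(list(
    k_selected = k_sel,
    labels = labels,
    cluster_names = paste0("MC", seq_len(k_sel)),
    silhouette_by_k = tibble::tibble(
      k = k_grid, silhouette_consensus = sil_cons,
      silhouette_latent = sil_lat),
    labels_by_k = setNames(labels_by_k, k_grid),
    consensus = best_cons,
    centroids = centroids, covariances = covariances, weights = weights,
    patient_ids = ids, config = config),
    class = "mds_cluster_model")
}

#' @export
print.mds_cluster_model <- function(x, ...) {
  cat("<mds_cluster_model> ", length(x$patient_ids), " patients; K = ",
      x$k_selected, " (silhouette ",
      signif(max(x$silhouette_by_k$silhouette_latent, na.rm = TRUE), 3),
      ")\n", sep = "")
  cat("  cluster sizes:",
      paste(sprintf("%s=%d", x$cluster_names, tabulate(x$labels, x$k_selected)),
            collapse = " "), "\n")
  invisible(x)
}

#' @method tidy mds_cluster_model
#' @export
tidy.mds_cluster_model <- function(x, ...) {
  tibble::tibble(patient_id = x$patient_ids,
                 cluster = factor(x$cluster_names[x$labels],
                                  levels = x$cluster_names))
}

#' @method glance mds_cluster_model
#' @export
glance.mds_cluster_model <- function(x, ...) {
  tibble::tibble(
    n = length(x$patient_ids), k_selected = x$k_selected,
    mean_silhouette = x$silhouette_by_k$silhouette_latent[
      match(x$k_selected, x$silhouette_by_k$k)],
    n_iterations = x$config$n_iterations,
    subsample_fraction = x$config$subsample_fraction)
}

#' Assign new patients to fitted molecular clusters
#'
#' Computes Gaussian-mixture posteriors for new latent coordinates from the
#' stored per-cluster centroids, covariances and empirical weights; the
#' assignment is the posterior argmax. Posteriors sum to 1 per patient.
#'
#' @param object A `mds_cluster_model`.
#' @param newdata Coordinate matrix produced by the same encoder
#'   ([predict.mds_embedding()]).
#' @param ... Unused.
#' @return A tibble with `patient_id`, `cluster` (factor `MC*`) and one
#'   `posterior_MC*` column per cluster.
#' @export
predict.mds_cluster_model <- function(object, newdata, ...) {
  Z <- embedding_coords(newdata)
  if (ncol(Z) != ncol(object$centroids)) {
    abort("latent dimension of `newdata` does not match the fitted model.")
  }
  post <- gmm_posterior(Z, object$weights, object$centroids,
                        object$covariances)
  resp <- post$resp
  colnames(resp) <- paste0("posterior_", object$cluster_names)
  cl <- max.col(resp, ties.method = "first")
  ids <- rownames(Z) %||% as.character(seq_len(nrow(Z)))
  dplyr::bind_cols(
    tibble::tibble(patient_id = ids,
                   cluster = factor(object$cluster_names[cl],
                                    levels = object$cluster_names)),
    tibble::as_tibble(as.data.frame(resp)))
}

#' Plot the silhouette trace over candidate K
#'
#' @param object A `mds_cluster_model`.
#' @param ... Unused.
#' @return A ggplot object: mean silhouette (consensus and latent distance)
#'   against K, with the selected K marked.
#' @method autoplot mds_cluster_model
#' @export
autoplot.mds_cluster_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$silhouette_by_k,
                            dplyr::starts_with("silhouette_"),
                            names_to = "distance", values_to = "silhouette",
                            names_prefix = "silhouette_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$silhouette,
                                   colour = .data$distance)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_selected, linetype = 2) +
    ggplot2::labs(x = "number of clusters K", y = "mean silhouette",
                  title = "Model-order selection") +
    ggplot2::theme_minimal()
}

#' Plot a consensus matrix heatmap
#'
#' @param object A `mds_consensus`.
#' @param order_by Optional label vector used to order patients into blocks.
#' @param ... Unused.
#' @return A ggplot tile heatmap of co-clustering frequencies.
#' @method autoplot mds_consensus
#' @export
autoplot.mds_consensus <- function(object, order_by = NULL, ...) {
  C <- object$consensus
  ord <- if (is.null(order_by)) hclust(as.dist(1 - C), "average")$order
         else order(order_by)
  C <- C[ord, ord]
  df <- tidyr::expand_grid(i = seq_len(nrow(C)), j = seq_len(ncol(C)))
  df$consensus <- C[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$consensus)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "navy",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Consensus matrix (K = %d)", object$k)) +
    ggplot2::theme_minimal()
}
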