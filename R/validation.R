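# Stability validation: adjusted Rand index, train/test fold plans,
# cross-fold stability (symmetric and model-transfer ARI), and the
# Bernoulli-mixture (latent class) baseline.

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions up
#' to relabeling, ~0 for independent ones. Computed from the contingency
#' table via the permutation-model expected index.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return A single number <= 1.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))  # 1
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) < 2L) abort("need at least 2 observations.")
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  index <- sum_comb(tab)
  exp_index <- sum_comb(rowSums(tab)) * sum_comb(colSums(tab)) / choose(n, 2)
  max_index <- (sum_comb(rowSums(tab)) + sum_comb(colSums(tab))) / 2
  if (max_index == exp_index) return(1)  # both partitions trivial
  (index - exp_index) / (max_index - exp_index)
}

#' Train/test split sizes
#'
#' `n_train = floor(fraction * n)`, `n_test = n - n_train`.
#'
#' @param n Cohort size.
#' @param train_fraction Fraction in (0, 1).
#' @return Named integer vector `c(n_train, n_test)`.
#' @examples
#' split_sizes(3588, 0.8)  # 2870 / 718
#' @export
split_sizes <- function(n, train_fraction = 0.8) {
  check_scalar_number(train_fraction, "train_fraction", 1e-12, 1 - 1e-12)
  n_train <- as.integer(floor(train_fraction * n))
  c(n_train = n_train, n_test = as.integer(n) - n_train)
}

#' Build a cross-validation fold plan
#'
#' Partitions the cohort into `n_folds` disjoint test folds (~`1 -
#' train_fraction` each); each fold's training set is the complement, giving
#' the 80%/20% five-fold scheme by default.
#'
#' @param n Number of patients.
#' @param n_folds Number of folds (default 5).
#' @param seed Seed for the random permutation.
#' @return An object of class `mds_fold_plan` with `fold_assignments`
#'   (length-n integers 1..n_folds marking each patient's *test* fold).
#' @export
fold_plan <- function(n, n_folds = 5L, seed = 1L) {
  n <- as.integer(n); n_folds <- as.integer(n_folds)
  if (n_folds < 2L || n_folds > n) abort("`n_folds` must be in [2, n].")
  perm <- with_seed(substream_seed(seed, "folds"), sample.int(n))
  assignment <- integer(n)
  assignment[perm] <- rep_len(seq_len(n_folds), n)
  structure(list(n = n, n_folds = n_folds, seed = as.integer(seed),
                 fold_assignments = assignment),
            class = "mds_fold_plan")
}

#' Cross-fold stability of the clustering pipeline
#'
#' Fits the full pipeline (autoencoder + consensus clustering with
#' silhouette model-order selection) independently on each fold's training
#' set, then compares folds two ways. Symmetric ARI between folds f and g is
#' computed on patients in the intersection of their training sets, using
#' each model's own labels. Asymmetric (model-transfer) ARI assigns fold g's
#' training patients with fold f's model — fold f's encoder followed by
#' [predict.mds_cluster_model()] — and compares to fold g's own labels; it
#' is directional.
#'
#' @param features A `mds_features` tibble for the full cohort.
#' @param plan A [fold_plan()].
#' @param embed_config An [embedding_config()].
#' @param consensus_cfg A [consensus_config()]; each fold derives its own
#'   seed substream from `consensus_cfg$seed`.
#' @return An object of class `mds_stability` with `k_by_fold`,
#'   `ari_symmetric` and `ari_asymmetric` matrices, `min_ari_symmetric`,
#'   `min_ari_asymmetric`, `modal_k`.
#' @export
cross_fold_stability <- function(features, plan,
                                 embed_config = embedding_config(),
                                 consensus_cfg = consensus_config()) {
  X <- as_feature_matrix(features)
  n <- nrow(X)
  if (plan$n != n) abort("`plan` does not cover this cohort.")
  nf <- plan$n_folds
  train_idx <- lapply(seq_len(nf), function(f) which(plan$fold_assignments != f))

  models <- vector("list", nf)
  for (f in seq_len(nf)) {
    ec <- embed_config; ec$seed <- substream_seed(embed_config$seed, "fold", f)
    cc <- consensus_cfg; cc$seed <- substream_seed(consensus_cfg$seed, "fold", f)
    emb <- fit_autoencoder(X[train_idx[[f]], , drop = FALSE], ec)
    fit <- fit_clusters(emb, cc)
    models[[f]] <- list(embedding = emb, clusters = fit, idx = train_idx[[f]])
  }

  sym <- matrix(NA_real_, nf, nf); diag(sym) <- 1
  asym <- matrix(NA_real_, nf, nf); diag(asym) <- 1
  for (f in seq_len(nf)) {
    for (g in seq_len(nf)) {
      if (f == g) next
      common <- intersect(models[[f]]$idx, models[[g]]$idx)
      if (length(common) >= 2L && f < g) {
        lab_f <- models[[f]]$clusters$labels[match(common, models[[f]]$idx)]
        lab_g <- models[[g]]$clusters$labels[match(common, models[[g]]$idx)]
        sym[f, g] <- sym[g, f] <- adjusted_rand_index(lab_f, lab_g)
      }
      Zg <- predict(models[[f]]$embedding,
                    X[models[[g]]$idx, , drop = FALSE])
      transfer <- predict(models[[f]]$clusters, Zg)
      asym[f, g] <- adjusted_rand_index(as.integer(transfer$cluster),
                                        models[[g]]$clusters$labels)
    }
  }

  k_by_fold <- vapply(models, function(m) m$clusters$k_selected, integer(1))
  ks <- table(k_by_fold)
  structure(list(
    k_by_fold = k_by_fold,
    modal_k = as.integer(names(ks)[which.max(ks)]),
    ari_symmetric = sym, ari_asymmetric = asym,
    min_ari_symmetric = min(sym[upper.tri(sym)], na.rm = TRUE),
    min_ari_asymmetric = min(asym[row(asym) != col(asym)], na.rm = TRUE),
    models = models, plan = plan),
    class = "mds_stability")
}

#' @export
print.mds_stability <- function(x, ...) {
  cat("<mds_stability> ", length(x$k_by_fold), " folds; K per fold: ",
      paste(x$k_by_fold, collapse = ", "), "; modal K = ", x$modal_k, "\n",
      "  min symmetric ARI = ", signif(x$min_ari_symmetric, 3),
      "; min asymmetric ARI = ", signif(x$min_ari_asymmetric, 3), "\n",
      sep = "")
  invisible(x)
}

#' @method glance mds_stability
#' @export
glance.mds_stability <- function(x, ...) {
  tibble::tibble(n_folds = length(x$k_by_fold), modal_k = x$modal_k,
                 min_ari_symmetric = x$min_ari_symmetric,
                 min_ari_asymmetric = x$min_ari_asymmetric)
}

#' @method tidy mds_stability
#' @export
tidy.mds_stability <- function(x, ...) {
  nf <- length(x$k_by_fold)
  grid <- tidyr::expand_grid(fold_a = seq_len(nf), fold_b = seq_len(nf))
  grid$ari_symmetric <- x$ari_symmetric[cbind(grid$fold_a, grid$fold_b)]
  grid$ari_asymmetric <- x$ari_asymmetric[cbind(grid$fold_a, grid$fold_b)]
  grid[grid$fold_a != grid$fold_b, ]
}

#' Bernoulli-mixture (latent class) baseline
#'
#' Finite mixture of independent Bernoulli features fitted by EM (best of
#' `restarts` seeded runs). This is the maximum-likelihood latent-class
#' model used as a coarser baseline against the autoencoder + consensus
#' pipeline. Parameters are clamped to `[eps, 1 - eps]` to keep the
#' likelihood finite; the log-likelihood trace is non-decreasing within a
#' run.
#'
#' @param features A `mds_features` tibble or 0/1 matrix.
#' @param k Number of latent classes (>= 1).
#' @param restarts Random restarts (default 3).
#' @param max_iter EM iteration cap (default 200).
#' @param eps Probability clamp (default 1e-4).
#' @param seed Seed.
#' @return An object of class `mds_latent_class`: `labels`, `class_probs`
#'   (k x p Bernoulli parameters), `weights`, `loglik_trace`, `loglik`,
#'   `bic`, `converged`.
#' @export
latent_class_baseline <- function(features, k, restarts = 3L,
                                  max_iter = 200L, eps = 1e-4, seed = 1L) {
  X <- if (is.matrix(features)) features else as_feature_matrix(features)
  n <- nrow(X); p <- ncol(X); k <- as.integer(k)
  if (k < 1L) abort("`k` must be >= 1.")

  em_once <- function(run_seed) {
    probs <- with_seed(run_seed,
                       matrix(runif(k * p, 0.2, 0.8), k, p))
    if (k == 1L) probs <- matrix(colMeans(X), 1L, p)
    probs <- pmin(pmax(probs, eps), 1 - eps)
    weights <- rep(1 / k, k)
    trace <- numeric(0)
    prev <- -Inf; converged <- FALSE
    for (iter in seq_len(max_iter)) {
      ll <- matrix(log(weights), n, k, byrow = TRUE) +
        X %*% t(log(probs)) + (1 - X) %*% t(log(1 - probs))
      lse <- logsumexp_rows(ll)
      resp <- exp(ll - lse)
      loglik <- sum(lse)
      trace <- c(trace, loglik)
      if (is.finite(prev) && loglik - prev < 1e-8 * abs(prev)) {
        converged <- TRUE
        break
      }
      prev <- loglik
      nk <- colSums(resp)
      weights <- nk / n
      probs <- pmin(pmax(crossprod(resp, X) / nk, eps), 1 - eps)
    }
    list(probs = probs, weights = weights, resp = resp,
         loglik = trace[length(trace)], trace = trace, converged = converged)
  }

  best <- NULL
  for (r in seq_len(if (k == 1L) 1L else restarts)) {
    fit <- em_once(substream_seed(seed, "lca", k, r))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged) {
    warn("latent-class EM did not converge within `max_iter` iterations.")
  }
  n_par <- (k - 1) + k * p
  structure(list(labels = max.col(best$resp, ties.method = "first"),
                 class_probs = best$probs, weights = best$weights,
                 loglik_trace = best$trace, loglik = best$loglik,
                 bic = -2 * best$loglik + n_par * log(n),
                 converged = best$converged, k = k),
            class = "mds_latent_class")
}

#' Select the latent-class baseline order by BIC
#'
#' Fits [latent_class_baseline()] over a grid of class counts and returns
#' the fit minimizing BIC.
#'
#' @param features A `mds_features` tibble or 0/1 matrix.
#' @param k_grid Candidate class counts.
#' @param ... Passed to [latent_class_baseline()].
#' @return The best `mds_latent_class` fit (with `bic_by_k` attached).
#' @export
latent_class_select <- function(features, k_grid = 1:10, ...) {
  fits <- lapply(k_grid, function(k) latent_class_baseline(features, k, ...))
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.min(bics)]]
  best$bic_by_k <- tibble::tibble(k = as.integer(k_grid), bic = bics)
  best
}

#' @method glance mds_latent_class
#' @export
glance.mds_latent_class <- function(x, ...) {
  tibble::tibble(k = x$k, loglik = x$loglik, bic = x$bic,
                 converged = x$converged, n_iter = length(x$loglik_trace))
}
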