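# Brute-force pair-counting ARI used as the independent oracle.
ari_bruteforce <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    if (same_a && same_b) s11 <- s11 + 1
    else if (!same_a && !same_b) s00 <- s00 + 1
    else if (same_a) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- choose(n, 2)
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

test_that("adjusted Rand index matches exhaustive pair counting", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  a <- c(1, 1, 2, 2); b <- c(1, 2, 1, 2)
  expect_equal(adjusted_rand_index(a, b), ari_bruteforce(a, b))
  set.seed(31)
  for (r in 1:20) {
    x <- sample(1:3, 12, replace = TRUE)
    y <- sample(1:4, 12, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), ari_bruteforce(x, y))
  }
  # label names are irrelevant
  expect_equal(adjusted_rand_index(a, c("x", "z", "x", "z")),
               adjusted_rand_index(a, b))
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})

test_that("ARI agrees with the mclust reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(13)
  for (r in 1:10) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y))
  }
})

test_that("train/test split arithmetic is exact", {
  expect_equal(unname(split_sizes(3588, 0.8)), c(2870L, 718L))
  expect_equal(unname(split_sizes(10, 0.5)), c(5L, 5L))
  set.seed(17)
  for (r in 1:200) {
    n <- sample(2:5000, 1)
    f <- runif(1, 0.05, 0.95)
    s <- split_sizes(n, f)
    expect_identical(sum(s), as.integer(n))
    expect_identical(s[["n_train"]], as.integer(floor(f * n)))
  }
})

test_that("fold plans partition the cohort into complementary folds", {
  plan <- fold_plan(103, 5, seed = 3)
  expect_equal(sort(unique(plan$fold_assignments)), 1:5)
  expect_equal(length(plan$fold_assignments), 103L)
  sizes <- table(plan$fold_assignments)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_identical(fold_plan(103, 5, seed = 3)$fold_assignments,
                   plan$fold_assignments)
})

test_that("cross-fold stability reports coherent fold agreement", {
  sim <- small_sim()
  plan <- fold_plan(nrow(sim$cohort), 2, seed = 5)
  st <- suppressWarnings(cross_fold_stability(
    sim$features, plan,
    embedding_config(latent_dim = 8, epochs = 150, seed = 5),
    consensus_config(n_iterations = 15, k_grid = 5:7, gmm_restarts = 3,
                     seed = 5)))
  expect_equal(st$modal_k, 6L)
  expect_true(all(st$ari_symmetric <= 1, na.rm = TRUE))
  expect_equal(unname(diag(st$ari_symmetric)), rep(1, 2))
  expect_gte(st$min_ari_symmetric, 0.7)
  expect_gte(st$min_ari_asymmetric, 0.7)
  td <- tidy(st)
  expect_equal(nrow(td), 2L)  # off-diagonal pairs only
})

test_that("Bernoulli-mixture baseline satisfies its EM guarantees", {
  X <- as_feature_matrix(small_sim()$features)
  # single class: parameters are the clamped column means
  one <- latent_class_baseline(X, 1)
  expect_equal(as.numeric(one$class_probs),
               unname(pmin(pmax(colMeans(X), 1e-4), 1 - 1e-4)))
  # log-likelihood trace is monotone non-decreasing
  two <- latent_class_baseline(X, 3, seed = 7)
  expect_true(all(diff(two$loglik_trace) >= -1e-6))
  expect_equal(length(two$labels), nrow(X))
})

test_that("Bernoulli mixture recovers planted class parameters", {
  set.seed(5)
  p1 <- c(rep(0.9, 5), rep(0.1, 5))
  p2 <- c(rep(0.1, 5), rep(0.9, 5))
  z <- rep(1:2, each = 1000)
  X <- t(vapply(z, function(k) {
    rbinom(10, 1, if (k == 1) p1 else p2)
  }, integer(10)))
  colnames(X) <- paste0("g", 1:10)
  fit <- latent_class_baseline(X, 2, restarts = 5, seed = 11)
  # align classes to the planted ones by first-feature probability
  ord <- order(-fit$class_probs[, 1])
  expect_lt(max(abs(fit$class_probs[ord[1], ] - p1)), 0.05)
  expect_lt(max(abs(fit$class_probs[ord[2], ] - p2)), 0.05)
  expect_gte(adjusted_rand_index(fit$labels, z), 0.95)
})

test_that("baseline never resolves more structure than the pipeline on
           survival-only cluster differences", {
  # two planted clusters share an identical genotype but different survival
  genes <- paste0("G", 1:12)
  gp <- rbind(c(rep(0.9, 4), rep(0.02, 8)),
              c(rep(0.9, 4), rep(0.02, 8)),   # same genotype as cluster 1
              c(rep(0.02, 8), rep(0.9, 4)))
  kp <- matrix(0, 3, 8); kp[, 1] <- 1
  spec <- simulation_spec(300, genes, rep(1 / 3, 3), gp, kp,
                          weibull_shape = c(1, 1, 1),
                          weibull_scale = c(80, 10, 40), seed = 23)
  coh <- simulate_cohort(spec)
  feats <- encode_features(coh, cohort_schema(genes = genes,
                                              pathways = list()))
  base <- suppressWarnings(
    latent_class_select(feats, k_grid = 1:5, restarts = 3, seed = 2))
  emb <- fit_autoencoder(feats, embedding_config(latent_dim = 6,
                                                 epochs = 150, seed = 2))
  fit <- suppressWarnings(fit_clusters(
    emb, consensus_config(n_iterations = 12, k_grid = 2:5,
                          gmm_restarts = 2, seed = 2)))
  expect_lte(base$k, fit$k_selected)
  expect_equal(base$k, 2L)  # genotype classes, not survival tiers
})
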