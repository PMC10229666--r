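test_that("consensus matrix satisfies its structural invariants", {
  blobs <- latent_blobs(n_per = 30, k = 3, sep = 6, seed = 2)
  cfg <- consensus_config(n_iterations = 15, gmm_restarts = 2, seed = 7)
  for (k in c(2L, 3L)) {
    cons <- suppressWarnings(run_consensus(blobs$Z, k, cfg))
    C <- cons$consensus
    expect_equal(C, t(C))
    expect_equal(unname(diag(C)), rep(1, nrow(C)))
    expect_true(all(C >= 0 & C <= 1))
    expect_true(all(cons$co_cluster <= cons$co_sample))
  }
})

test_that("well-separated blobs give a near-binary consensus", {
  blobs <- latent_blobs(n_per = 100, k = 2, sep = 10, seed = 3)
  cfg <- consensus_config(n_iterations = 50, gmm_restarts = 3, seed = 1)
  cons <- run_consensus(blobs$Z, 2L, cfg)
  same <- outer(blobs$truth, blobs$truth, "==")
  ut <- upper.tri(same)
  expect_gte(min(cons$consensus[same & ut]), 0.95)
  expect_lte(max(cons$consensus[!same & ut]), 0.05)
})

test_that("full-sample iterations reduce to the direct mixture partition", {
  blobs <- latent_blobs(n_per = 40, k = 2, sep = 10, seed = 5)
  cfg <- consensus_config(n_iterations = 1, subsample_fraction = 1,
                          gmm_restarts = 3, seed = 2)
  cons <- run_consensus(blobs$Z, 2L, cfg)
  # one full-sample iteration: consensus entries are exactly 0 or 1
  expect_true(all(cons$consensus %in% c(0, 1)))
  # and the consensus partition equals the direct GMM labels
  direct <- mdsmc:::fit_gmm(
    blobs$Z, 2L, restarts = 3,
    seed = mdsmc:::substream_seed(
      mdsmc:::substream_seed(2, "consensus", 2, 1), "gmm"))
  labs <- consensus_partition(cons, 2L)
  expect_equal(adjusted_rand_index(labs, direct$labels), 1)
})

test_that("consensus partition recovers constructed block structure", {
  # two perfect blocks
  C2 <- rbind(cbind(matrix(1, 5, 5), matrix(0, 5, 5)),
              cbind(matrix(0, 5, 5), matrix(1, 5, 5)))
  expect_equal(adjusted_rand_index(consensus_partition(C2, 2),
                                   rep(1:2, each = 5)), 1)
  # all-ones consensus collapses to a single cluster
  expect_equal(consensus_partition(matrix(1, 6, 6), 1), rep(1L, 6))
  # 3 noisy blocks (0.9 within, 0.1 between)
  blk <- function(i, j) if (i == j) 0.9 else 0.1
  C3 <- matrix(0, 30, 30)
  g <- rep(1:3, each = 10)
  for (i in 1:30) for (j in 1:30) C3[i, j] <- blk(g[i], g[j])
  diag(C3) <- 1
  expect_equal(adjusted_rand_index(consensus_partition(C3, 3), g), 1)
  expect_error(consensus_partition(C3, 40), "patients")
})

test_that("silhouette model-order selection recovers the planted K", {
  fit <- small_fit()$clusters
  sim <- small_sim()
  expect_equal(fit$k_selected, 6L)
  expect_gte(adjusted_rand_index(fit$labels, sim$cohort$true_cluster), 0.9)
  sil <- fit$silhouette_by_k
  expect_true(all(sil$silhouette_consensus >= -1 &
                    sil$silhouette_consensus <= 1, na.rm = TRUE))
  expect_true(all(sil$silhouette_latent >= -1 &
                    sil$silhouette_latent <= 1, na.rm = TRUE))
  # clusters are named MC1.. in decreasing size order
  expect_equal(fit$cluster_names, paste0("MC", 1:6))
  sizes <- tabulate(fit$labels, 6)
  expect_true(all(diff(sizes) <= 0))
})

test_that("new patients are assigned by a proper posterior", {
  fitted <- small_fit()
  sim <- small_sim()
  pred <- predict(fitted$clusters, fitted$embedding$coordinates)
  post <- as.matrix(pred[, grep("^posterior_", names(pred))])
  expect_equal(unname(rowSums(post)), rep(1, nrow(post)), tolerance = 1e-9)
  # self-assignment agrees with the fitted partition
  expect_gte(adjusted_rand_index(as.integer(pred$cluster),
                                 fitted$clusters$labels), 0.9)
  expect_error(predict(fitted$clusters, fitted$embedding$coordinates[, 1:3]),
               "dimension")
})

test_that("held-out patients from planted clusters are assigned accurately", {
  coh <- simulate_cohort(preset_mds_like(), n_patients = 400, seed = 77)
  X <- as_feature_matrix(encode_features(coh))
  train <- seq_len(200); test <- 201:400
  emb <- fit_autoencoder(X[train, ],
                         embedding_config(latent_dim = 8, epochs = 200,
                                          seed = 7))
  fit <- suppressWarnings(fit_clusters(
    emb, consensus_config(n_iterations = 20, k_grid = 5:7,
                          gmm_restarts = 3, seed = 7)))
  pred <- predict(fit, predict(emb, X[test, ]))
  expect_gte(adjusted_rand_index(as.integer(pred$cluster),
                                 coh$true_cluster[test]), 0.9)
})

test_that("reordering patients reorders the consensus partition with them", {
  blobs <- latent_blobs(n_per = 25, k = 3, sep = 8, seed = 9)
  cfg <- consensus_config(n_iterations = 20, gmm_restarts = 2, seed = 4)
  cons <- run_consensus(blobs$Z, 3L, cfg)
  labs <- consensus_partition(cons, 3L)
  perm <- sample(nrow(blobs$Z))
  labs_perm <- consensus_partition(cons$consensus[perm, perm], 3L)
  expect_equal(adjusted_rand_index(labs_perm, labs[perm]), 1)
})

test_that("increasing planted separation never degrades median recovery", {
  ari_at_sep <- vapply(c(2, 4, 8), function(sep) {
    aris <- vapply(1:3, function(r) {
      blobs <- latent_blobs(n_per = 30, k = 2, sep = sep, seed = 10 + r)
      cfg <- consensus_config(n_iterations = 10, gmm_restarts = 2,
                              seed = 20 + r)
      cons <- suppressWarnings(run_consensus(blobs$Z, 2L, cfg))
      adjusted_rand_index(consensus_partition(cons, 2L), blobs$truth)
    }, numeric(1))
    median(aris)
  }, numeric(1))
  expect_true(all(diff(ari_at_sep) >= 0))
})
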