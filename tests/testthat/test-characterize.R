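# Tiny hand-built feature matrix: 8 patients, 2 clusters.
hand_features <- function() {
  m <- rbind(
    c(1, 1, 0, 0),  # cluster 1
    c(1, 0, 0, 0),
    c(1, 1, 0, 0),
    c(1, 0, 0, 0),
    c(0, 0, 1, 0),  # cluster 2
    c(0, 0, 1, 0),
    c(0, 0, 1, 0),
    c(0, 0, 1, 0))
  colnames(m) <- c("NK", "SF3B1", "complex", "NEVER")
  rownames(m) <- paste0("p", 1:8)
  list(X = m, labels = rep(c("A", "B"), each = 4))
}

test_that("feature frequencies are within-cluster column means", {
  h <- hand_features()
  fr <- feature_frequencies(h$X, h$labels)
  get <- function(cl, f) fr$frequency[fr$cluster == cl & fr$feature == f]
  expect_equal(get("A", "NK"), 1)       # universal carriage
  expect_equal(get("A", "SF3B1"), 0.5)  # 2 of 4 carriers, hand count
  expect_equal(get("A", "NEVER"), 0)    # absent feature is 0 everywhere
  expect_equal(get("B", "NEVER"), 0)
  expect_equal(get("B", "complex"), 1)
  expect_error(feature_frequencies(h$X, h$labels[-1]), "one entry per row")
})

test_that("a universal NK+SF3B1 cluster reports both frequencies at 1", {
  m <- matrix(c(1, 1, 1, 1, 1, 1), 3, 2,
              dimnames = list(paste0("p", 1:3), c("NK", "SF3B1")))
  fr <- feature_frequencies(m, rep("MC4", 3))
  expect_equal(fr$frequency, c(1, 1))
})

test_that("pairwise co-occurrence equals explicit AND counts", {
  h <- hand_features()
  co <- pairwise_cooccurrence(h$X, h$labels)
  get <- function(cl, a, b) {
    co$co_occurrence[co$cluster == cl & co$feature_a == a &
                       co$feature_b == b]
  }
  expect_equal(get("A", "NK", "SF3B1"), 0.5)     # 2 of 4 carry both
  expect_equal(get("A", "NK", "complex"), 0)     # disjoint carriers
  expect_equal(get("B", "complex", "complex"), 1)
  # diagonal equals the frequency; symmetry
  fr <- feature_frequencies(h$X, h$labels)
  for (f in colnames(h$X)) {
    expect_equal(get("A", f, f),
                 fr$frequency[fr$cluster == "A" & fr$feature == f])
  }
  expect_equal(get("A", "SF3B1", "NK"), get("A", "NK", "SF3B1"))
  # co-occurrence never exceeds either marginal frequency
  joined <- merge(co, fr, by.x = c("cluster", "feature_a"),
                  by.y = c("cluster", "feature"))
  expect_true(all(joined$co_occurrence <= joined$frequency + 1e-12))
})

make_importance_data <- function(n = 120, seed = 3) {
  set.seed(seed)
  labels <- rep(1:2, each = n / 2)
  X <- cbind(
    signal = as.integer(labels == 1),          # encodes the split exactly
    matrix(rbinom(n * 6, 1, 0.4), n, 6,
           dimnames = list(NULL, paste0("noise", 1:6))),
    constant = rep(1L, n))
  list(X = X, labels = labels)
}

test_that("permutation importance ranks the label-encoding feature first", {
  d <- make_importance_data()
  imp <- mean_decrease_accuracy(d$X, d$labels,
                                importance_config(n_trees = 100,
                                                  n_permutations = 3,
                                                  seed = 5))
  expect_equal(imp$feature[1], "signal")
  expect_true(imp$important[imp$feature == "signal"])
  # a constant column has importance exactly zero
  expect_equal(imp$importance[imp$feature == "constant"], 0)
  # the flagged set is exactly the cutoff rule
  expect_equal(imp$important, imp$importance >= 0.01)
})

test_that("importance is reproducible bit-for-bit under a fixed seed", {
  d <- make_importance_data()
  cfg <- importance_config(n_trees = 60, n_permutations = 2, seed = 8)
  a <- mean_decrease_accuracy(d$X, d$labels, cfg)
  b <- mean_decrease_accuracy(d$X, d$labels, cfg)
  expect_identical(a, b)
  expect_error(mean_decrease_accuracy(d$X, rep(1, nrow(d$X)),
                                      cfg), "2 clusters")
})

test_that("duplicated features share, not double, the credit", {
  d <- make_importance_data(n = 100, seed = 9)
  cfg <- importance_config(n_trees = 150, n_permutations = 3, seed = 2)
  solo <- mean_decrease_accuracy(d$X, d$labels, cfg)
  dup <- cbind(d$X, signal_copy = d$X[, "signal"])
  both <- mean_decrease_accuracy(dup, d$labels, cfg)
  imp_solo <- solo$importance[solo$feature == "signal"]
  imp_pair <- sum(both$importance[both$feature %in%
                                    c("signal", "signal_copy")])
  expect_lte(imp_pair, imp_solo + 0.1)
})

test_that("importance ranking agrees with ranger's own permutation measure", {
  d <- make_importance_data(n = 150, seed = 13)
  imp <- mean_decrease_accuracy(d$X, d$labels,
                                importance_config(n_trees = 150,
                                                  n_permutations = 3,
                                                  seed = 4))
  rf <- ranger::ranger(x = as.data.frame(d$X), y = factor(d$labels),
                       num.trees = 150, mtry = ncol(d$X),
                       importance = "permutation", seed = 4,
                       num.threads = 1)
  expect_equal(names(which.max(rf$variable.importance)), "signal")
  expect_equal(imp$feature[1], "signal")
})

test_that("one-vs-rest importance emits a per-cluster table", {
  d <- make_importance_data(n = 80)
  res <- mean_decrease_accuracy_by_cluster(
    d$X, d$labels, importance_config(n_trees = 50, n_permutations = 2,
                                     seed = 3))
  expect_setequal(unique(res$cluster), c("1", "2"))
  expect_equal(nrow(res), 2L * ncol(d$X))
})
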