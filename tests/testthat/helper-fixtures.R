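# Shared fixtures, built in code. Heavy objects are computed once per test
# run and memoized in `.fixture_cache`.

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, compute) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, compute(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Five hand-written patients covering aliases, empty mutation sets and the
# karyotype precedence rule.
write_tiny_cohort_tsv <- function(path) {
  writeLines(c(
    paste("patient_id", "mutated_genes", "karyotype", "age", "sex",
          "blast_pct", "survival_months", "event", "treatment_flags",
          sep = "\t"),
    paste("p1", "SF3B1,DNMT3A", "46,XX", "70", "F", "2", "48", "0", "HMA",
          sep = "\t"),
    paste("p2", "", "del(5q)", "65", "M", "4", "30", "1", "", sep = "\t"),
    paste("p3", "TP53", "complex", "80", "M", "18", "6", "1", "HMA,HSCT",
          sep = "\t"),
    paste("p4", "TET2,ZRSR2,ASXL1", "-y", "74", "M", "3", "60", "0", "",
          sep = "\t"),
    paste("p5", "NRAS", "del(5q);del(7q)", "69", "F", "9", "22", "1", "HMA",
          sep = "\t")), path)
  path
}

tiny_schema <- function() {
  cohort_schema(genes = c("SF3B1", "DNMT3A", "TP53", "TET2", "ZRSR2",
                          "ASXL1", "NRAS", "KRAS"),
                pathways = list(RAS_pathway = c("NRAS", "KRAS")))
}

tiny_cohort <- function() {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_tiny_cohort_tsv(path)
  read_cohort(path, tiny_schema())
}

# Two well-separated latent blobs (for consensus-machinery tests).
latent_blobs <- function(n_per = 50, d = 4, sep = 10, k = 2, seed = 1) {
  set.seed(seed)
  Z <- do.call(rbind, lapply(seq_len(k), function(j) {
    matrix(rnorm(n_per * d, mean = sep * j), n_per, d)
  }))
  rownames(Z) <- sprintf("b%03d", seq_len(nrow(Z)))
  list(Z = Z, truth = rep(seq_len(k), each = n_per))
}

# A small simulated cohort + encoded features, reused across files.
small_sim <- function() {
  memoize("small_sim", function() {
    coh <- simulate_cohort(preset_mds_like(), n_patients = 250, seed = 42)
    list(cohort = coh, features = encode_features(coh))
  })
}

# A small fitted pipeline (embedding + clusters) on the simulated cohort.
small_fit <- function() {
  memoize("small_fit", function() {
    sim <- small_sim()
    emb <- fit_autoencoder(sim$features,
                           embedding_config(latent_dim = 8, epochs = 200,
                                            seed = 9))
    fit <- suppressWarnings(fit_clusters(
      emb, consensus_config(n_iterations = 20, k_grid = 4:8,
                            gmm_restarts = 3, seed = 9)))
    list(embedding = emb, clusters = fit)
  })
}

# Exhaustive usable-pair concordance oracle (higher score = higher risk).
c_bruteforce <- function(times, events, scores) {
  num <- den <- 0
  n <- length(times)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    first <- if (times[i] < times[j]) i else j
    other <- if (first == i) j else i
    if (times[i] == times[j]) {
      # tied times: usable only if exactly one is an event
      if (events[i] + events[j] != 1) next
      first <- if (events[i] == 1) i else j
      other <- if (first == i) j else i
    }
    if (events[first] == 0) next   # earlier time censored: unusable
    den <- den + 1
    if (scores[first] > scores[other]) num <- num + 1
    else if (scores[first] == scores[other]) num <- num + 0.5
  }
  num / den
}
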