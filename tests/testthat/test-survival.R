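test_that("Kaplan-Meier matches hand-computed product-limit tables", {
  # all censored: the curve never drops
  km0 <- kaplan_meier(data.frame(survival_months = c(3, 7, 9),
                                 event = c(0, 0, 0)))
  expect_true(all(km0$estimate == 1))

  # three events, no censoring: S = 2/3, 1/3, 0
  km1 <- kaplan_meier(data.frame(survival_months = c(1, 2, 3),
                                 event = c(1, 1, 1)))
  expect_equal(km1$estimate, c(1, 2 / 3, 1 / 3, 0))

  # mixed censoring, hand-computed:
  # t=5 (d=1,n=6) S=5/6; t=8 (d=1,n=5) S=2/3; censor at 8;
  # t=12 (d=1,n=3) S=4/9; censor at 15; t=20 (d=1,n=1) S=0
  km2 <- kaplan_meier(data.frame(
    survival_months = c(5, 8, 8, 12, 15, 20),
    event = c(1, 1, 0, 1, 0, 1)))
  ev <- km2[km2$n_event > 0, ]
  expect_equal(ev$estimate, c(5 / 6, 2 / 3, 4 / 9, 0))
  expect_true(all(diff(km2$estimate) <= 0))
  expect_equal(km2$estimate[km2$time == 0], 1)
  expect_error(kaplan_meier(data.frame(survival_months = numeric(0),
                                       event = numeric(0))), "no obs")
})

test_that("log-rank statistic matches the hand-computed O-E/V", {
  df <- data.frame(survival_months = c(2, 4, 3, 5),
                   event = c(1, 1, 1, 1),
                   cluster = c("a", "a", "b", "b"))
  lr <- logrank_pairwise(df)
  # hand computation: O1=2, E1=4/3, V=13/18 -> chisq = (2/3)^2 / (13/18)
  expect_equal(lr$statistic, (2 / 3)^2 / (13 / 18), tolerance = 1e-10)
  expect_equal(lr$p_value, pchisq(lr$statistic, 1, lower.tail = FALSE))

  # identical time/event multisets give statistic 0
  df2 <- data.frame(survival_months = rep(c(1, 3, 6), 2),
                    event = rep(c(1, 0, 1), 2),
                    cluster = rep(c("a", "b"), each = 3))
  expect_equal(logrank_pairwise(df2)$statistic, 0, tolerance = 1e-12)

  # label swap leaves the test invariant
  df3 <- df; df3$cluster <- ifelse(df$cluster == "a", "b", "a")
  expect_equal(logrank_pairwise(df3)$statistic, lr$statistic)
})

test_that("Cox regression recovers planted hazard ratios", {
  set.seed(61)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  noise <- rnorm(n)
  tt <- rexp(n, rate = 0.05 * exp(log(2) * x))
  cens <- rexp(n, rate = 0.02)
  df <- data.frame(survival_months = pmin(tt, cens),
                   event = as.integer(tt <= cens),
                   x = x, noise = noise)
  fit <- cox_ph(df, covariates = c("x", "noise"))
  td <- tidy(fit)
  expect_lt(abs(td$estimate[td$term == "x"] - log(2)), 0.1)
  # a covariate independent of the hazard stays near zero
  expect_lt(abs(td$estimate[td$term == "noise"]), 0.1)
  gl <- glance(fit)
  expect_gt(gl$concordance, 0.5)

  # rescaling a covariate rescales its coefficient reciprocally
  df$x10 <- 10 * df$x
  fit10 <- cox_ph(df, covariates = c("x10", "noise"))
  expect_equal(tidy(fit10)$estimate[1], td$estimate[td$term == "x"] / 10,
               tolerance = 1e-6)
  expect_error(cox_ph(df, covariates = character(0)), "non-empty")
  df$const <- 1
  expect_error(cox_ph(df, covariates = "const"), "constant")
})

test_that("risk aggregation recovers planted hazard tiers", {
  set.seed(33)
  scales <- c(80, 80, 30, 30, 8, 8)   # 3 planted tiers across 6 clusters
  df <- do.call(rbind, lapply(1:6, function(k) {
    tt <- rweibull(500, shape = 1.1, scale = scales[k])
    cens <- rexp(500, 0.005)
    data.frame(survival_months = pmin(tt, cens),
               event = as.integer(tt <= cens),
               cluster = paste0("MC", k))
  }))
  rg <- aggregate_risk_groups(df)
  expect_equal(nrow(rg$group_summary), 3L)
  mapping <- rg$mapping
  grp_of <- setNames(mapping$risk_group, mapping$cluster)
  expect_equal(unname(grp_of[c("MC1", "MC2")]), c(1, 1))
  expect_equal(unname(grp_of[c("MC3", "MC4")]), c(2, 2))
  expect_equal(unname(grp_of[c("MC5", "MC6")]), c(3, 3))
  # group 1 is the best prognosis: medians decrease with group id
  expect_true(all(diff(rg$group_summary$median_os) < 0))

  # a fixed target group count is honored
  rg2 <- aggregate_risk_groups(df, n_groups = 2)
  expect_equal(nrow(rg2$group_summary), 2L)

  # identical curves collapse to one group
  df_same <- df[df$cluster == "MC1", ]
  df_same2 <- df_same; df_same2$cluster <- "MC2"
  rg3 <- aggregate_risk_groups(rbind(df_same, df_same2))
  expect_equal(nrow(rg3$group_summary), 1L)
})

test_that("raising the survival floor never creates more risk groups", {
  set.seed(34)
  scales <- c(70, 40, 10)
  df <- do.call(rbind, lapply(1:3, function(k) {
    tt <- rweibull(400, shape = 1, scale = scales[k])
    data.frame(survival_months = pmin(tt, 150), event = 1L,
               cluster = paste0("MC", k))
  }))
  counts <- vapply(c(0.1, 0.25, 0.45), function(fl) {
    nrow(aggregate_risk_groups(df, survival_floor = fl)$group_summary)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})


test_that("Harrell's C equals brute-force usable-pair counting", {
  # perfect concordance: risk score reverses the event order
  tt <- c(2, 5, 8, 11, 14)
  expect_equal(harrell_c(tt, rep(1, 5), -tt), 1)

  # censored fixture against the exhaustive oracle
  times <- c(6, 3, 9, 4, 2, 7, 7)
  events <- c(1, 0, 1, 1, 1, 0, 1)
  scores <- c(2, 1, 4, 3, 5, 2, 2)
  expect_equal(harrell_c(times, events, scores),
               c_bruteforce(times, events, scores))

  # random scores sit near 1/2
  set.seed(71)
  tt <- rexp(1000); sc <- rnorm(1000)
  expect_lt(abs(harrell_c(tt, rep(1, 1000), sc) - 0.5), 0.05)
})

test_that("bootstrap C-difference is seeded and brackets the point value", {
  set.seed(81)
  n <- 300
  x <- rnorm(n)
  tt <- rexp(n, exp(0.8 * x))
  ev <- rbinom(n, 1, 0.8)
  good <- x; bad <- x + rnorm(n, sd = 2)
  bc <- bootstrap_c_difference(tt, ev, good, bad, n_boot = 100, seed = 4)
  expect_identical(bc, bootstrap_c_difference(tt, ev, good, bad,
                                              n_boot = 100, seed = 4))
  expect_gt(bc$delta, 0)
  expect_lte(bc$conf_low, bc$delta)
  expect_gte(bc$conf_high, bc$delta)
})

test_that("response logistic regression recovers planted odds ratios", {
  set.seed(91)
  n <- 2000
  cl <- sample(c("MC1", "MC2", "MC3"), n, replace = TRUE)
  # planted OR 2 for MC2 vs reference MC1
  eta <- -0.5 + log(2) * (cl == "MC2")
  y <- rbinom(n, 1, plogis(eta))
  df <- data.frame(response = y, cluster = cl)
  fit <- response_logistic(df, "response", reference = "MC1")
  mc2 <- fit[fit$term == "cluster:MC2", ]
  expect_gt(mc2$conf_high, 2); expect_lt(mc2$conf_low, 2)
  mc3 <- fit[fit$term == "cluster:MC3", ]
  expect_true(mc3$conf_low < 1 && mc3$conf_high > 1)  # null covered
  expect_false(attr(fit, "separation_flagged"))

  df0 <- df; df0$response <- 0
  expect_error(response_logistic(df0, "response"), "separation")
})

test_that("merging identical groups leaves the KM curve unchanged", {
  df <- data.frame(survival_months = c(1, 4, 6, 9, 1, 4, 6, 9),
                   event = c(1, 0, 1, 1, 1, 0, 1, 1),
                   g = rep(c("a", "b"), each = 4))
  merged <- kaplan_meier(df)
  per <- kaplan_meier(df, by = "g")
  expect_equal(merged$estimate,
               per$estimate[per$group == "a"])
})
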