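# Survival layer: Kaplan-Meier curves, pairwise log-rank, Cox proportional
# hazards, aggregation of molecular clusters into risk groups by a
# landmark-window curve distance, Harrell's C with bootstrap comparison,
# and treatment-response logistic regression.

surv_check <- function(data, time, event) {
  for (col in c(time, event)) {
    if (!col %in% names(data)) abort(sprintf("column `%s` not found.", col))
  }
  if (nrow(data) == 0L) abort("no observations.")
  if (any(data[[time]] < 0, na.rm = TRUE)) abort("times must be >= 0.")
  if (any(!data[[event]] %in% c(0, 1), na.rm = TRUE)) {
    abort("event indicator must be 0/1.")
  }
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimate with Greenwood variance and log-log 95%
#' confidence bands, optionally stratified by a grouping column. The
#' returned table includes the `S(0) = 1` anchor per group.
#'
#' @param data Data frame of per-patient records.
#' @param time,event Column names of the follow-up time (months) and 0/1
#'   event indicator.
#' @param by Optional grouping column name.
#' @return A tibble of class `mds_km`: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `estimate`, `std_error`, `conf_low`,
#'   `conf_high`.
#' @export
kaplan_meier <- function(data, time = "survival_months", event = "event",
                         by = NULL) {
  surv_check(data, time, event)
  grp <- if (is.null(by)) factor(rep("all", nrow(data)))
         else as.factor(data[[by]])
  purrr::map_dfr(levels(grp), function(g) {
    sub <- data[grp == g, , drop = FALSE]
    fit <- survival::survfit(
      survival::Surv(sub[[time]], sub[[event]]) ~ 1, conf.type = "log-log")
    tibble::tibble(group = g,
                   time = c(0, fit$time),
                   n_risk = c(fit$n, fit$n.risk),
                   n_event = c(0, fit$n.event),
                   n_censor = c(0, fit$n.censor),
                   estimate = c(1, fit$surv),
                   std_error = c(0, fit$std.err * fit$surv),
                   conf_low = c(1, fit$lower),
                   conf_high = c(1, fit$upper))
  }) |>
    dplyr::mutate(group = factor(.data$group, levels = levels(grp))) |>
    structure(class = c("mds_km", class(tibble::tibble())))
}

#' @method autoplot mds_km
#' @export
autoplot.mds_km <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$estimate,
                                       colour = .data$group,
                                       fill = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         alpha = 0.15, colour = NA, stat = "identity") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "overall survival S(t)") +
    ggplot2::theme_minimal()
}

#' Pairwise log-rank tests between groups
#'
#' Standard two-group log-rank test (chi-square on 1 df) for every pair of
#' groups, with `-log10(p)` for heatmap display. Groups with no subjects
#' are excluded with a warning.
#'
#' @inheritParams kaplan_meier
#' @param group Grouping column name.
#' @return A tibble `group_a`, `group_b`, `statistic`, `p_value`,
#'   `neg_log10_p`.
#' @export
logrank_pairwise <- function(data, time = "survival_months",
                             event = "event", group = "cluster") {
  surv_check(data, time, event)
  grp <- droplevels(as.factor(data[[group]]))
  levs <- levels(grp)
  empty <- setdiff(unique(as.character(data[[group]])), levs)
  if (length(levs) < 2L) abort("need at least 2 non-empty groups.")
  pairs <- utils::combn(levs, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    keep <- grp %in% c(a, b)
    sd <- survival::survdiff(
      survival::Surv(data[[time]][keep], data[[event]][keep]) ~
        droplevels(grp[keep]))
    p <- pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
    tibble::tibble(group_a = a, group_b = b, statistic = sd$chisq,
                   p_value = p, neg_log10_p = -log10(p))
  })
}

#' Plot the pairwise log-rank heatmap
#'
#' @param pairwise Output of [logrank_pairwise()].
#' @param thresholds Significance stars at these p-values (default
#'   0.05/0.01/0.001).
#' @return A ggplot tile heatmap of `-log10(p)` with significance stars.
#' @export
plot_logrank_heatmap <- function(pairwise,
                                 thresholds = c(0.05, 0.01, 0.001)) {
  df <- dplyr::mutate(
    pairwise,
    stars = vapply(.data$p_value,
                   function(p) paste(rep("*", sum(p <= thresholds)),
                                     collapse = ""),
                   character(1)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group_a, y = .data$group_b,
                                   fill = .data$neg_log10_p)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "-log10(p)") +
    ggplot2::theme_minimal()
}

#' Cox proportional-hazards model
#'
#' Partial-likelihood Cox regression with Efron tie handling (monthly
#' follow-up times tie heavily) over the given covariate columns.
#' Non-convergence or infinite coefficients are flagged.
#'
#' @inheritParams kaplan_meier
#' @param covariates Character vector of covariate column names (factors
#'   allowed).
#' @return An object of class `mds_cox` wrapping the `survival::coxph` fit;
#'   see [tidy.mds_cox()] and [glance.mds_cox()].
#' @export
cox_ph <- function(data, time = "survival_months", event = "event",
                   covariates) {
  surv_check(data, time, event)
  if (length(covariates) == 0L) abort("`covariates` must be non-empty.")
  for (cv in covariates) {
    if (!cv %in% names(data)) abort(sprintf("column `%s` not found.", cv))
    if (length(unique(data[[cv]][!is.na(data[[cv]])])) < 2L) {
      abort(sprintf("covariate `%s` is constant.", cv))
    }
  }
  if (sum(data[[event]], na.rm = TRUE) < 1L) abort("no events observed.")
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite", conditionMessage(w))) {
        warn(paste0("Cox fit flagged: ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    })
  flagged <- any(!is.finite(coef(fit))) || !is.null(fit$info)
  structure(list(fit = fit, covariates = covariates, flagged = flagged),
            class = "mds_cox")
}

#' @export
print.mds_cox <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x A `mds_cox` object.
#' @param conf_level Wald confidence level (default 0.95).
#' @param ... Unused.
#' @return A tibble `term`, `estimate` (log hazard ratio), `std_error`,
#'   `hazard_ratio`, `conf_low`, `conf_high`, `p_value`.
#' @method tidy mds_cox
#' @export
tidy.mds_cox <- function(x, conf_level = 0.95, ...) {
  co <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(term = names(co), estimate = unname(co),
                 std_error = unname(se),
                 hazard_ratio = exp(unname(co)),
                 conf_low = exp(unname(co - z * se)),
                 conf_high = exp(unname(co + z * se)),
                 p_value = 2 * stats::pnorm(-abs(unname(co) / unname(se))))
}

#' Glance at a Cox fit
#'
#' @param x A `mds_cox` object.
#' @param ... Unused.
#' @return One-row tibble: `n`, `n_events`, `concordance`, `loglik`,
#'   `flagged`.
#' @method glance mds_cox
#' @export
glance.mds_cox <- function(x, ...) {
  tibble::tibble(n = x$fit$n, n_events = x$fit$nevent,
                 concordance = unname(x$fit$concordance["concordance"]),
                 loglik = x$fit$loglik[2], flagged = x$flagged)
}

# Step-function evaluation of a KM curve tibble at arbitrary times.
km_eval <- function(curve, at) {
  idx <- findInterval(at, curve$time)
  idx[idx == 0L] <- 1L
  curve$estimate[idx]
}

#' Aggregate molecular clusters into survival risk groups
#'
#' Implements the landmark-window grouping rule: the landmark `t*` is the
#' largest time at which every cluster's Kaplan-Meier survival still
#' exceeds `survival_floor` (default 0.25). Each cluster is represented by
#' its survival curve evaluated on an even grid over `[0, t*]`; pairwise
#' curve distances are the root-mean-square of the pointwise survival
#' difference standardized by its pooled Greenwood standard error, and
#' clusters are agglomerated on this distance. The tree is cut at
#' `n_groups` if given, otherwise at the fixed height `merge_threshold`
#' (default 2): clusters whose curves differ by less than ~2 pooled
#' standard errors share a risk group. Groups are numbered 1..G by
#' decreasing median overall survival (group 1 = best prognosis).
#'
#' @inheritParams kaplan_meier
#' @param cluster Cluster column name.
#' @param survival_floor Landmark survival floor in (0, 1) (default 0.25).
#' @param n_groups Optional fixed number of risk groups.
#' @param linkage `"average"` (default) or `"complete"`.
#' @param grid_size Number of evaluation points on `[0, t*]` (default 64).
#' @param merge_threshold Height (in pooled standard errors) below which
#'   curves are grouped when `n_groups` is not given (default 2).
#' @return An object of class `mds_risk_grouping`: `mapping` (tibble
#'   `cluster`, `risk_group`), `group_summary` (tibble `risk_group`, `n`,
#'   `n_events`, `median_os`, `conf_low`, `conf_high`), `t_star`,
#'   `heights`.
#' @export
aggregate_risk_groups <- function(data, time = "survival_months",
                                  event = "event", cluster = "cluster",
                                  survival_floor = 0.25, n_groups = NULL,
                                  linkage = c("average", "complete"),
                                  grid_size = 64L, merge_threshold = 2) {
  linkage <- match.arg(linkage)
  check_scalar_number(survival_floor, "survival_floor", 1e-9, 1 - 1e-9)
  surv_check(data, time, event)
  grp <- droplevels(as.factor(data[[cluster]]))
  levs <- levels(grp)
  m <- length(levs)
  if (m < 1L) abort("no clusters.")

  curves <- kaplan_meier(data, time, event, by = cluster)
  curves_list <- split(curves, curves$group)

  tau <- vapply(levs, function(g) {
    cv <- curves_list[[g]]
    above <- cv$time[cv$estimate > survival_floor]
    if (length(above)) max(above) else 0
  }, numeric(1))
  t_star <- min(tau)
  if (t_star <= 0) {
    warn("landmark t* collapsed to 0; falling back to the largest per-cluster landmark.")
    t_star <- max(tau)
  }

  grid <- seq(0, t_star, length.out = grid_size)
  profile <- t(vapply(levs, function(g) km_eval(curves_list[[g]], grid),
                      numeric(grid_size)))
  se_prof <- t(vapply(levs, function(g) {
    cv <- curves_list[[g]]
    idx <- findInterval(grid, cv$time)
    idx[idx == 0L] <- 1L
    cv$std_error[idx]
  }, numeric(grid_size)))
  # standardized curve distance: root-mean-square of the pointwise
  # difference divided by its pooled Greenwood standard error, so
  # statistically indistinguishable curves sit at comparable (small)
  # heights whatever their tier's variance
  Dm <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i < j) {
      pse <- sqrt(se_prof[i, ]^2 + se_prof[j, ]^2)
      pse <- pmax(pse, 1e-6)
      Dm[i, j] <- Dm[j, i] <-
        sqrt(mean(((profile[i, ] - profile[j, ]) / pse)^2))
    }
  }
  D <- as.dist(Dm)

  if (m == 1L) {
    groups_raw <- 1L
    heights <- numeric(0)
  } else {
    hc <- hclust(D, method = linkage)
    heights <- hc$height
    groups_raw <- if (!is.null(n_groups)) {
      unname(cutree(hc, k = as.integer(min(n_groups, m))))
    } else {
      # distances are SE-standardized, so a fixed height threshold has a
      # statistical reading: clusters whose curves differ by less than
      # `merge_threshold` pooled standard errors (RMS over the landmark
      # grid) are statistically indistinguishable and share a risk group
      unname(cutree(hc, h = merge_threshold))
    }
  }

  med <- vapply(sort(unique(groups_raw)), function(g) {
    members <- levs[groups_raw == g]
    sub <- data[grp %in% members, , drop = FALSE]
    fit <- survival::survfit(survival::Surv(sub[[time]], sub[[event]]) ~ 1,
                             conf.type = "log-log")
    tb <- summary(fit)$table
    c(n = unname(tb["records"]), events = unname(tb["events"]),
      median = unname(tb["median"]),
      lcl = unname(tb["0.95LCL"]), ucl = unname(tb["0.95UCL"]))
  }, numeric(5))

  # order groups by median OS descending; unreached medians sort best
  med_for_order <- ifelse(is.na(med["median", ]), Inf, med["median", ])
  ord <- order(-med_for_order)
  relabel <- integer(ncol(med)); relabel[ord] <- seq_along(ord)
  mapping <- tibble::tibble(cluster = levs,
                            risk_group = relabel[groups_raw])
  group_summary <- tibble::tibble(
    risk_group = relabel, n = as.integer(med["n", ]),
    n_events = as.integer(med["events", ]),
    median_os = med["median", ],
    conf_low = med["lcl", ], conf_high = med["ucl", ]) |>
    dplyr::arrange(.data$risk_group)

  structure(list(mapping = mapping, group_summary = group_summary,
                 t_star = t_star, heights = heights,
                 survival_floor = survival_floor, linkage = linkage),
            class = "mds_risk_grouping")
}

#' @export
print.mds_risk_grouping <- function(x, ...) {
  cat("<mds_risk_grouping> ", nrow(x$mapping), " clusters -> ",
      nrow(x$group_summary), " risk groups (t* = ",
      signif(x$t_star, 4), " months)\n", sep = "")
  print(x$group_summary)
  invisible(x)
}

#' @method tidy mds_risk_grouping
#' @export
tidy.mds_risk_grouping <- function(x, ...) x$mapping

#' @method glance mds_risk_grouping
#' @export
glance.mds_risk_grouping <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$mapping),
                 n_groups = nrow(x$group_summary),
                 t_star = x$t_star, survival_floor = x$survival_floor)
}

#' Harrell's concordance index
#'
#' Censoring-aware concordance between a risk score (higher = higher risk)
#' and observed survival, over usable pairs; ties in the score count 0.5.
#'
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param risk_scores Numeric risk scores (higher means expected earlier
#'   event).
#' @return Concordance in [0, 1].
#' @export
harrell_c <- function(times, events, risk_scores) {
  if (length(unique(c(length(times), length(events),
                      length(risk_scores)))) != 1L) {
    abort("inputs must have equal length.")
  }
  fit <- survival::concordance(
    survival::Surv(times, events) ~ risk_scores, reverse = TRUE)
  n_usable <- sum(fit$count[c("concordant", "discordant", "tied.x")])
  if (n_usable == 0) abort("no usable pairs (all comparisons censored).")
  unname(fit$concordance)
}

#' Paired bootstrap of a C-index difference
#'
#' Resamples patients with replacement and recomputes `C_A - C_B` for two
#' competing risk scores on the same cohort; percentile confidence
#' interval.
#'
#' @inheritParams harrell_c
#' @param scores_a,scores_b The two risk scores to compare.
#' @param n_boot Bootstrap replicates (default 200).
#' @param conf_level CI level (default 0.95).
#' @param seed Seed.
#' @return A one-row tibble `delta`, `conf_low`, `conf_high`, `n_boot`.
#' @export
bootstrap_c_difference <- function(times, events, scores_a, scores_b,
                                   n_boot = 200L, conf_level = 0.95,
                                   seed = 1L) {
  check_scalar_number(n_boot, "n_boot", 1)
  delta <- harrell_c(times, events, scores_a) -
    harrell_c(times, events, scores_b)
  n <- length(times)
  boots <- with_seed(substream_seed(seed, "cboot"), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, replace = TRUE)
      harrell_c(times[idx], events[idx], scores_a[idx]) -
        harrell_c(times[idx], events[idx], scores_b[idx])
    }, numeric(1))
  })
  alpha <- (1 - conf_level) / 2
  tibble::tibble(delta = delta,
                 conf_low = unname(quantile(boots, alpha)),
                 conf_high = unname(quantile(boots, 1 - alpha)),
                 n_boot = as.integer(n_boot))
}

#' Treatment-response logistic regression
#'
#' Maximum-likelihood logistic regression of a binary response on cluster
#' membership (relative to a reference cluster) and optional covariates,
#' reporting odds ratios with Wald confidence intervals. Perfect or
#' quasi-perfect separation is flagged.
#'
#' @param data Data frame.
#' @param response Column name of the 0/1 response.
#' @param cluster Cluster column name.
#' @param covariates Optional additional covariate column names.
#' @param reference Reference cluster level (default: first level).
#' @param conf_level CI level (default 0.95).
#' @return A tibble `term`, `estimate` (log odds ratio), `std_error`,
#'   `odds_ratio`, `conf_low`, `conf_high`, `p_value`; attribute
#'   `separation_flagged`.
#' @export
response_logistic <- function(data, response, cluster = "cluster",
                              covariates = character(0),
                              reference = NULL, conf_level = 0.95) {
  y <- data[[response]]
  if (any(!y %in% c(0, 1), na.rm = TRUE)) abort("`response` must be 0/1.")
  if (length(unique(y[!is.na(y)])) < 2L) {
    abort("`response` is degenerate (all 0 or all 1): perfect separation.")
  }
  cl <- as.factor(data[[cluster]])
  if (!is.null(reference)) cl <- stats::relevel(cl, ref = reference)
  df <- data.frame(.y = y, .cluster = cl,
                   data[covariates], check.names = FALSE)
  fml <- stats::as.formula(paste(
    ".y ~ .cluster",
    if (length(covariates))
      paste("+", paste(sprintf("`%s`", covariates), collapse = " + "))
    else ""))
  fit <- suppressWarnings(glm(fml, data = df, family = binomial()))
  co <- coef(fit)[-1L]
  se <- sqrt(diag(vcov(fit)))[-1L]
  flagged <- !fit$converged || any(abs(co) > 10) || any(se > 100)
  if (flagged) warn("possible separation or non-convergence in logistic fit.")
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    term = sub("^\\.cluster", paste0(cluster, ":"), names(co)),
    estimate = unname(co), std_error = unname(se),
    odds_ratio = exp(unname(co)),
    conf_low = exp(unname(co - z * se)),
    conf_high = exp(unname(co + z * se)),
    p_value = 2 * stats::pnorm(-abs(unname(co) / unname(se))))
  attr(out, "separation_flagged") <- flagged
  out
}
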