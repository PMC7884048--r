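#' Kaplan-Meier curve for one group
#'
#' Product-limit estimator with the usual tie convention that deaths precede
#' censorings recorded at the same time (censored animals at time t are still
#' at risk for the deaths at t).
#'
#' @param table Survival tibble (`animal_id`, `group`, `time_weeks`, `event`).
#' @param group Group label to estimate.
#' @return Tibble with one row per distinct time: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`.
#' @export
kaplan_meier <- function(table, group) {
  assert_survival_table(table)
  d <- table[table$group == group, ]
  if (nrow(d) == 0) abort(sprintf("group '%s' has no records.", group))
  fit <- survival::survfit(survival::Surv(time_weeks, event) ~ 1, data = d)
  tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, survival = fit$surv
  )
}

# KM survival probability for one group at a single time point.
km_survival_at <- function(table, group, time) {
  km <- kaplan_meier(table, group)
  steps <- km[km$n_event > 0 & km$time <= time, ]
  if (nrow(steps) == 0) 1 else steps$survival[nrow(steps)]
}

#' Log-rank test between two groups, optionally stratified
#'
#' At each distinct event time the observed group-A deaths are compared with
#' their hypergeometric expectation given the risk sets; `O - E` and the
#' variance `V` are summed over event times (and over strata when stratified)
#' and `chi2 = (O - E)^2 / V` is referred to chi-square with 1 df. Strata that
#' do not contain both groups are dropped with a warning.
#'
#' @param table Survival tibble.
#' @param group_a,group_b Group labels.
#' @param strata Optional column name to stratify (block) on, e.g. `"sex"`.
#' @return A `txs_logrank` object: `chisq`, `df`, `p_value`, and per-group
#'   `observed`, `expected` plus the variance `var`.
#' @export
logrank_test <- function(table, group_a, group_b, strata = NULL) {
  assert_survival_table(table)
  d <- table[table$group %in% c(group_a, group_b), ]
  d$group <- factor(d$group, levels = c(group_a, group_b))
  if (any(table(d$group) == 0)) abort("both groups must be non-empty.")
  if (!is.null(strata)) {
    if (!strata %in% names(d)) abort(sprintf("no column '%s' to stratify on.", strata))
    keep <- names(which(tapply(d$group, d[[strata]],
                               function(g) length(unique(g)) == 2)))
    dropped <- setdiff(unique(d[[strata]]), keep)
    if (length(dropped)) {
      warn(sprintf("stratum(s) without both groups dropped: %s",
                   paste(dropped, collapse = ", ")))
      d <- d[d[[strata]] %in% keep, ]
    }
  }
  out <- list(group_a = group_a, group_b = group_b, strata = strata)
  if (sum(d$event) == 0) {
    warn("no events in either group; log-rank p set to 1.")
    out <- c(out, list(chisq = 0, df = 1L, p_value = 1,
                       observed = c(0, 0), expected = c(0, 0), var = 0))
  } else {
    fml <- if (is.null(strata)) {
      survival::Surv(time_weeks, event) ~ group
    } else {
      d$.stratum <- d[[strata]]
      survival::Surv(time_weeks, event) ~ group + survival::strata(.stratum)
    }
    sd <- survival::survdiff(fml, data = d)
    out <- c(out, list(
      chisq = unname(sd$chisq), df = 1L,
      p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
      observed = unname(sd$obs), expected = unname(sd$exp),
      var = unname(sd$var[1, 1])
    ))
  }
  names(out$observed) <- names(out$expected) <- c(group_a, group_b)
  class(out) <- "txs_logrank"
  out
}

#' @export
print.txs_logrank <- function(x, ...) {
  cat(sprintf("Log-rank %s vs %s%s: chi2 = %.4g (df = 1), p = %.4g\n",
              x$group_a, x$group_b,
              if (is.null(x$strata)) "" else paste0(" (stratified on ", x$strata, ")"),
              x$chisq, x$p_value))
  cat(sprintf("  O = (%.0f, %.0f), E = (%.4g, %.4g), V = %.4g\n",
              x$observed[1], x$observed[2], x$expected[1], x$expected[2], x$var))
  invisible(x)
}

#' @method tidy txs_logrank
#' @export
tidy.txs_logrank <- function(x, ...) {
  tibble(group = names(x$observed), observed = x$observed,
         expected = x$expected)
}

#' @method glance txs_logrank
#' @export
glance.txs_logrank <- function(x, ...) {
  tibble(chisq = x$chisq, df = x$df, p_value = x$p_value, var = x$var)
}

#' Log hazard ratio between two groups with 95% confidence interval
#'
#' Both classical log-rank-based estimators are available. Mantel-Haenszel:
#' `log HR = ln((O_A / E_A) / (O_B / E_B))` with `se = sqrt(1/E_A + 1/E_B)`.
#' Score (Peto): `log HR = (O_A - E_A) / V` with `se = 1 / sqrt(V)`. A group
#' that lives longer than its comparator has `O < E`, so a protective
#' first-listed group yields a negative log HR.
#'
#' @param table Survival tibble.
#' @param group_a,group_b Group labels (A first).
#' @param estimator `"mantel-haenszel"` (default) or `"score"`.
#' @return A `txs_hr` object: `log_hr`, `se`, `ci95` (low, high), `estimator`.
#' @export
log_hazard_ratio <- function(table, group_a, group_b,
                             estimator = c("mantel-haenszel", "score")) {
  estimator <- match.arg(estimator)
  lr <- logrank_test(table, group_a, group_b)
  o <- lr$observed; e <- lr$expected
  if (any(o == 0)) abort("log hazard ratio undefined: a group has zero events.")
  if (estimator == "mantel-haenszel") {
    log_hr <- log((o[1] / e[1]) / (o[2] / e[2]))
    se <- sqrt(1 / e[1] + 1 / e[2])
  } else {
    log_hr <- (o[1] - e[1]) / lr$var
    se <- 1 / sqrt(lr$var)
  }
  res <- list(
    group_a = group_a, group_b = group_b,
    log_hr = unname(log_hr), se = unname(se),
    ci95 = unname(c(log_hr - 1.96 * se, log_hr + 1.96 * se)),
    estimator = estimator
  )
  class(res) <- "txs_hr"
  res
}

#' @export
print.txs_hr <- function(x, ...) {
  cat(sprintf("log(HR) %s vs %s = %.4f (95%% CI %.4f to %.4f; %s)\n",
              x$group_a, x$group_b, x$log_hr, x$ci95[1], x$ci95[2], x$estimator))
  invisible(x)
}

#' @method tidy txs_hr
#' @export
tidy.txs_hr <- function(x, ...) {
  tibble(
    group_a = x$group_a, group_b = x$group_b, log_hr = x$log_hr, se = x$se,
    ci_low = x$ci95[1], ci_high = x$ci95[2], estimator = x$estimator
  )
}

#' Phenotype-onset analysis
#'
#' Onset tables (age at first tremor, imbalance, kyphosis, ...) share the
#' survival-table semantics: onset is the event, death before onset is
#' censoring. Returns the KM curves of both groups and their log-rank test.
#'
#' @param table Onset tibble with survival-table columns.
#' @param group_a,group_b Group labels.
#' @param strata Optional stratification column for the log-rank test.
#' @return List with `km` (named list of two KM tibbles) and `logrank`.
#' @export
onset_analysis <- function(table, group_a, group_b, strata = NULL) {
  list(
    km = setNames(
      list(kaplan_meier(table, group_a), kaplan_meier(table, group_b)),
      c(group_a, group_b)
    ),
    logrank = logrank_test(table, group_a, group_b, strata = strata)
  )
}

#' Assemble hazard-ratio results into a forest-plot table
#'
#' Stacks labelled [log_hazard_ratio()] results in the given (stable) order
#' with no numeric transformation, ready for plotting or CSV export.
#'
#' @param results List of `txs_hr` objects.
#' @param labels Character labels, one per result (default "A vs B").
#' @return Tibble: `label`, `log_hr`, `se`, `ci_low`, `ci_high`, `estimator`.
#' @export
forest_assemble <- function(results, labels = NULL) {
  if (length(results) == 0) abort("need >= 1 hazard-ratio result.")
  stopifnot(all(vapply(results, inherits, logical(1), "txs_hr")))
  if (is.null(labels)) {
    labels <- vapply(results, function(r) paste(r$group_a, "vs", r$group_b),
                     character(1))
  }
  stopifnot(length(labels) == length(results))
  purrr::map2(results, labels, function(r, lab) {
    tibble(label = lab, log_hr = r$log_hr, se = r$se,
           ci_low = r$ci95[1], ci_high = r$ci95[2], estimator = r$estimator)
  }) |> bind_rows()
}

#' Forest plot of log hazard ratios
#'
#' @param forest Tibble from [forest_assemble()].
#' @return A ggplot: point estimates with 95% CI error bars, reference line at 0.
#' @export
plot_forest <- function(forest) {
  ggplot2::ggplot(
    forest,
    ggplot2::aes(x = .data$log_hr, y = factor(.data$label, rev(.data$label)))
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "log hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Step plot of Kaplan-Meier curves for several groups
#'
#' @param table Survival tibble.
#' @param groups Group labels to draw (default: all in the table).
#' @return A ggplot of the survival step functions.
#' @export
plot_km <- function(table, groups = NULL) {
  groups <- groups %||% unique(table$group)
  curves <- purrr::map(groups, function(g) {
    km <- kaplan_meier(table, g)
    bind_rows(tibble(time = 0, survival = 1), km[, c("time", "survival")]) |>
      mutate(group = g)
  }) |> bind_rows()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (weeks)", y = "survival") +
    ggplot2::theme_minimal()
}
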