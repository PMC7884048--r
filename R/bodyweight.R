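#' Last week at which every group retains at least 80% survival
#'
#' The body-weight AUC is computed over the interval from the intervention
#' start through the largest week at which all groups still have Kaplan-Meier
#' survival of at least `min_survival` (inclusive at the boundary).
#'
#' @param weights Long weight tibble (`animal_id`, `group`, `week`, `weight_g`).
#' @param survival Survival tibble covering every group in `weights`.
#' @param start_week First week of the intervention interval.
#' @param min_survival Survival floor (default 0.80).
#' @return The end week (integer).
#' @export
auc_interval <- function(weights, survival, start_week, min_survival = 0.80) {
  assert_survival_table(survival)
  groups <- unique(weights$group)
  if (!all(groups %in% survival$group)) {
    abort("every weight group must appear in the survival table.")
  }
  weeks <- start_week:max(weights$week)
  # small tolerance so a survival of exactly the floor (e.g. 8/10 reached via
  # successive products) is included despite floating-point rounding
  ok <- vapply(weeks, function(w) {
    all(vapply(groups, function(g) {
      km_survival_at(survival, g, w) >= min_survival - 1e-9
    }, logical(1)))
  }, logical(1))
  if (!ok[1]) {
    abort(sprintf("some group is already below %.0f%% survival at week %d.",
                  100 * min_survival, start_week))
  }
  if (all(ok)) return(max(weeks))
  weeks[which(!ok)[1] - 1]
}

#' Normalise weekly weights to the log10 scale with a global baseline shift
#'
#' Weights are log10-transformed, each animal's log10 weight at `start_week`
#' is subtracted, and the lowest log10 baseline weight of the whole dataset is
#' then added back as a common shift, which collapses to
#' `log10(weight) - min(log10(baseline))`. The shift is purely cosmetic: it is
#' additive and identical for every animal, so no between-group comparison is
#' affected. Animals without a `start_week` weight are excluded with a warning.
#'
#' @param weights Long weight tibble.
#' @param start_week Baseline week.
#' @return Tibble `animal_id`, `group`, `week`, `norm_weight`.
#' @export
normalize_weights <- function(weights, start_week) {
  stopifnot(all(c("animal_id", "group", "week", "weight_g") %in% names(weights)))
  if (any(weights$weight_g <= 0)) abort("weights must be > 0 g.")
  base <- weights[weights$week == start_week, c("animal_id", "weight_g")]
  missing <- setdiff(unique(weights$animal_id), base$animal_id)
  if (length(missing)) {
    warn(sprintf("excluding %d animal(s) without a week-%d baseline weight: %s",
                 length(missing), start_week,
                 paste(utils::head(missing, 5), collapse = ", ")))
    weights <- weights[!weights$animal_id %in% missing, ]
  }
  global_min <- min(log10(base$weight_g))
  weights |>
    mutate(norm_weight = log10(.data$weight_g) - global_min) |>
    select("animal_id", "group", "week", "norm_weight")
}

#' Trapezoid area under per-animal weight curves
#'
#' Integrates each animal's normalised series over `[start_week, end_week]`
#' with the trapezoid rule on the observed weeks; interior missing weeks are
#' bridged by the trapezoid between the flanking observations (equivalent to
#' linear interpolation). Animals with fewer than two observations in the
#' interval raise an error.
#'
#' @param normalized Tibble from [normalize_weights()].
#' @param start_week,end_week Integration interval (inclusive).
#' @return Tibble `animal_id`, `group`, `auc`, `n_obs`.
#' @export
trapezoid_auc <- function(normalized, start_week, end_week) {
  d <- normalized[normalized$week >= start_week & normalized$week <= end_week, ]
  d |>
    group_by(.data$animal_id, .data$group) |>
    summarise(
      auc = {
        if (n() < 2) {
          abort(sprintf("animal '%s' has < 2 observations in [%d, %d].",
                        .data$animal_id[1], start_week, end_week))
        }
        o <- order(.data$week)
        pracma::trapz(.data$week[o], .data$norm_weight[o])
      },
      n_obs = n(), .groups = "drop"
    )
}

#' Grubbs critical value for a two-sided single-outlier test
#'
#' `G_crit = ((N-1)/sqrt(N)) * sqrt(t^2 / (N - 2 + t^2))` with `t` the upper
#' `alpha / (2N)` quantile of Student t on `N - 2` df.
#'
#' @param n Sample size (>= 3).
#' @param alpha Significance level (default 0.01).
#' @return The critical value of `G = max|x - mean| / sd`.
#' @export
grubbs_critical <- function(n, alpha = 0.01) {
  if (n < 3) abort("Grubbs test needs n >= 3.")
  tcrit <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  ((n - 1) / sqrt(n)) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
}

#' One-pass two-sided Grubbs outlier screen
#'
#' Applied exactly once to the pooled values (no iteration), flagging at most
#' the single most extreme point if its `G` statistic exceeds the critical
#' value. Zero-variance input yields no flag, with a warning.
#'
#' @param x Numeric values (e.g. per-animal AUCs), length >= 3.
#' @param alpha Significance level (default 0.01).
#' @param ids Optional identifiers aligned with `x`.
#' @return Tibble of flagged points (0 or 1 rows): `id`, `value`, `G`,
#'   `critical`.
#' @export
grubbs_screen <- function(x, alpha = 0.01, ids = NULL) {
  if (length(x) < 3) abort("Grubbs test needs n >= 3 values.")
  ids <- ids %||% as.character(seq_along(x))
  s <- sd(x)
  empty <- tibble(id = character(), value = numeric(), G = numeric(),
                  critical = numeric())
  if (s == 0) {
    warn("zero variance: Grubbs screen flags nothing.")
    return(empty)
  }
  g <- abs(x - mean(x)) / s
  crit <- grubbs_critical(length(x), alpha)
  i <- which.max(g)
  if (g[i] > crit) {
    tibble(id = ids[i], value = x[i], G = g[i], critical = crit)
  } else {
    empty
  }
}

#' Welch unequal-variances t test
#'
#' @param a,b Numeric samples (>= 2 each).
#' @return One-row tibble: `t`, `df` (Satterthwaite), `p_value`, group means.
#' @export
welch_compare <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("need >= 2 values per group.")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(t = 0, df = length(a) + length(b) - 2, p_value = 1,
                    mean_a = mean(a), mean_b = mean(b)))
    }
    abort("both groups have zero variance but unequal means; t undefined.")
  }
  wt <- t.test(a, b, var.equal = FALSE)
  tibble(
    t = unname(wt$statistic), df = unname(wt$parameter),
    p_value = wt$p.value, mean_a = mean(a), mean_b = mean(b)
  )
}

#' Full body-weight AUC ledger for one experiment
#'
#' Chains the whole procedure: pick the interval end ([auc_interval()]),
#' exclude animals that died within the interval, normalise
#' ([normalize_weights()]), integrate ([trapezoid_auc()]), screen the pooled
#' AUCs once with Grubbs ([grubbs_screen()]), and compare each requested group
#' pair with Welch's t test.
#'
#' @param weights Long weight tibble.
#' @param survival Survival tibble.
#' @param start_week Intervention start week.
#' @param alpha Grubbs alpha (default 0.01).
#' @param comparisons List of `c(group_a, group_b)` pairs; default: every group
#'   against the first.
#' @return A `txs_auc` object: `auc` (per-animal tibble), `interval`,
#'   `excluded_died`, `outliers`, `comparisons` tibble.
#' @export
bodyweight_auc <- function(weights, survival, start_week, alpha = 0.01,
                           comparisons = NULL) {
  end_week <- auc_interval(weights, survival, start_week)
  died <- survival$animal_id[survival$event == 1 &
                             survival$time_weeks <= end_week &
                             survival$time_weeks >= start_week]
  kept <- weights[!weights$animal_id %in% died, ]
  normalized <- normalize_weights(kept, start_week)
  aucs <- trapezoid_auc(normalized, start_week, end_week)
  out <- grubbs_screen(aucs$auc, alpha = alpha, ids = aucs$animal_id)
  analyzed <- aucs[!aucs$animal_id %in% out$id, ]
  groups <- unique(analyzed$group)
  comparisons <- comparisons %||%
    purrr::map(groups[-1], function(g) c(groups[1], g))
  cmp <- purrr::map(comparisons, function(pr) {
    welch_compare(analyzed$auc[analyzed$group == pr[1]],
                  analyzed$auc[analyzed$group == pr[2]]) |>
      mutate(group_a = pr[1], group_b = pr[2], .before = 1)
  }) |> bind_rows()
  res <- list(
    auc = analyzed, interval = c(start = start_week, end = end_week),
    excluded_died = died, outliers = out, comparisons = cmp
  )
  class(res) <- "txs_auc"
  res
}

#' @export
print.txs_auc <- function(x, ...) {
  cat(sprintf("Body-weight AUC over weeks %d-%d: %d animals (%d died excluded, %d outlier removed)\n",
              x$interval["start"], x$interval["end"], nrow(x$auc),
              length(x$excluded_died), nrow(x$outliers)))
  print(x$comparisons)
  invisible(x)
}

#' @method tidy txs_auc
#' @export
tidy.txs_auc <- function(x, ...) x$auc

#' @method glance txs_auc
#' @export
glance.txs_auc <- function(x, ...) x$comparisons
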