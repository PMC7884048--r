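weights_tbl <- function(animal_id, group, weeks, w) {
  tibble::tibble(animal_id = animal_id, group = group, week = weeks, weight_g = w)
}

test_that("AUC interval ends at the last week every group keeps >= 80% survival", {
  # 10 animals, deaths at weeks 10, 11, 12: survival 0.9, 0.8, 0.7
  surv <- surv_tbl(c(10, 11, 12, rep(40, 7)), c(1, 1, 1, rep(0, 7)), "A")
  w <- weights_tbl(rep("A_004", 31), "A", 0:30, rep(20, 31))
  expect_equal(auc_interval(w, surv, start_week = 0), 11)

  # no deaths before the last observed week: interval runs to that week
  surv2 <- surv_tbl(rep(40, 10), 0, "A")
  expect_equal(auc_interval(w, surv2, start_week = 0), 30)

  # exactly 0.80 at w is included (>= is inclusive)
  surv3 <- surv_tbl(c(5, 5, rep(40, 8)), c(1, 1, rep(0, 8)), "A")
  expect_equal(auc_interval(w, surv3, start_week = 0), 30)

  # already below the floor at the start week
  surv4 <- surv_tbl(c(1, 1, 1, rep(40, 7)), c(1, 1, 1, rep(0, 7)), "A")
  expect_error(auc_interval(w, surv4, start_week = 2), "below")
})

test_that("normalisation is the documented global-min log10 shift", {
  w <- dplyr::bind_rows(
    weights_tbl("a1", "A", c(0, 1), c(20, 20)),
    weights_tbl("a2", "A", c(0, 1), c(10, 12))
  )
  norm <- normalize_weights(w, start_week = 0)
  # animal with 20 g baseline vs global min baseline 10 g
  expect_equal(norm$norm_weight[norm$animal_id == "a1" & norm$week == 1],
               log10(20) - log10(10))
  expect_equal(norm$norm_weight[norm$animal_id == "a2" & norm$week == 0], 0)

  # identical constant weights -> all values equal (constant after the shift)
  cw <- dplyr::bind_rows(weights_tbl("a1", "A", 0:3, 15),
                         weights_tbl("a2", "A", 0:3, 15))
  expect_true(all(normalize_weights(cw, 0)$norm_weight == 0))

  # the shift is additive: week-to-week differences are unchanged
  d_raw <- diff(log10(w$weight_g[w$animal_id == "a2"]))
  d_norm <- diff(norm$norm_weight[norm$animal_id == "a2"])
  expect_equal(d_norm, d_raw)

  # missing baseline excludes the animal with a warning
  nob <- dplyr::bind_rows(weights_tbl("a1", "A", 0:1, 20),
                          weights_tbl("a3", "A", 1:2, 18))
  expect_warning(out <- normalize_weights(nob, 0), "a3")
  expect_false("a3" %in% out$animal_id)
})

test_that("trapezoid AUC matches closed forms and a fine-grid refinement", {
  const <- weights_tbl("a1", "A", 0:10, 10^0.5) # constant on the log10 scale
  norm <- normalize_weights(const, 0) |>
    dplyr::mutate(norm_weight = 0.5) # constant value c = 0.5 over [0, 10]
  expect_equal(trapezoid_auc(norm, 0, 10)$auc, 0.5 * 10)

  tri <- tibble::tibble(animal_id = "a1", group = "A", week = 0:2,
                        norm_weight = c(0, 1, 0))
  expect_equal(trapezoid_auc(tri, 0, 2)$auc, 1.0)

  # random 20-week series vs numeric integration of the linear interpolant
  set.seed(77)
  ser <- tibble::tibble(animal_id = "a1", group = "A", week = 0:20,
                        norm_weight = cumsum(rnorm(21, 0, 0.05)))
  got <- trapezoid_auc(ser, 0, 20)$auc
  f <- approxfun(ser$week, ser$norm_weight)
  grid <- seq(0, 20, by = 1e-3)
  fine <- sum((f(grid[-1]) + f(grid[-length(grid)])) / 2 * diff(grid))
  expect_equal(got, fine, tolerance = 1e-9)

  # interior gaps are bridged by the flanking trapezoid
  gap <- ser[ser$week != 10, ]
  f2 <- approxfun(gap$week, gap$norm_weight)
  fine2 <- sum((f2(grid[-1]) + f2(grid[-length(grid)])) / 2 * diff(grid))
  expect_equal(trapezoid_auc(gap, 0, 20)$auc, fine2, tolerance = 1e-9)

  single <- tibble::tibble(animal_id = "a1", group = "A", week = 3,
                           norm_weight = 1)
  expect_error(trapezoid_auc(single, 0, 20), "< 2 observations")
})

test_that("Grubbs screen applies the published critical value once", {
  # published table value for n = 4, alpha = 0.01 (two-sided): 1.496
  expect_equal(grubbs_critical(4, 0.01), 1.496, tolerance = 5e-4)

  out <- grubbs_screen(c(1, 1.01, 0.99, 5), ids = c("a", "b", "c", "d"))
  expect_equal(out$id, "d")
  expect_equal(out$value, 5)
  expect_gt(out$G, out$critical)

  # symmetric data with no extreme point: nothing flagged
  expect_equal(nrow(grubbs_screen(c(1, 2, 3, 4, 5))), 0)

  # one pass removes at most one point, and is idempotent on the reduced set
  many <- c(rnorm(10), 50, -50)
  expect_lte(nrow(grubbs_screen(many)), 1)

  expect_warning(none <- grubbs_screen(c(2, 2, 2)), "zero variance")
  expect_equal(nrow(none), 0)
  expect_error(grubbs_screen(c(1, 2)), "n >= 3")
})

test_that("Welch comparison matches hand arithmetic and degenerate contracts", {
  res <- welch_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(-3 / sqrt(2 / 3), 4))
  expect_equal(round(res$p_value, 4), 0.0213)

  same <- welch_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  const <- welch_compare(c(2, 2), c(2, 2))
  expect_equal(const$p_value, 1)
  expect_error(welch_compare(1, c(1, 2)), ">= 2")
})

test_that("Welch test holds its size under unequal variances", {
  set.seed(31)
  rej <- mean(vapply(1:400, function(r) {
    welch_compare(rnorm(10, 0, 1), rnorm(10, 0, 3))$p_value < 0.05
  }, logical(1)))
  expect_lt(abs(rej - 0.05), 0.035)
})

test_that("the full AUC ledger detects a -7% asymptote effect with the right sign", {
  run_once <- function(r) {
    surv <- simulate_survival(
      survival_params(list(A = list(a = 1e-4, b = 0.05, n = 15),
                           B = list(a = 1e-4, b = 0.05, n = 15)),
                      censor_time = 30),
      seed = 4000 + r
    )
    wp <- weight_params(list(
      A = list(noise_sd = 0.5),
      B = list(asymptote = 25 * 0.93, noise_sd = 0.5)
    ))
    w <- simulate_weights(wp, surv, seed = 4000 + r)
    res <- bodyweight_auc(w, surv, start_week = 0)
    res$comparisons$mean_b - res$comparisons$mean_a
  }
  diffs <- vapply(1:20, run_once, numeric(1))
  expect_gte(mean(diffs < 0), 0.9)
})

test_that("the global-min shift cannot change between-group AUC differences", {
  set.seed(12)
  w <- dplyr::bind_rows(
    weights_tbl("a1", "A", 0:10, 20 + rnorm(11, 0, 0.3)),
    weights_tbl("a2", "A", 0:10, 22 + rnorm(11, 0, 0.3)),
    weights_tbl("b1", "B", 0:10, 18 + rnorm(11, 0, 0.3)),
    weights_tbl("b2", "B", 0:10, 19 + rnorm(11, 0, 0.3))
  )
  auc_diff <- function(weights) {
    a <- trapezoid_auc(normalize_weights(weights, 0), 0, 10)
    mean(a$auc[a$group == "A"]) - mean(a$auc[a$group == "B"])
  }
  base <- auc_diff(w)
  heavier <- w |> dplyr::mutate(weight_g = .data$weight_g * 3)
  # scaling all weights shifts every log10 trajectory identically
  expect_equal(auc_diff(heavier), base, tolerance = 1e-12)
})
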