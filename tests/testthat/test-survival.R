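test_that("Kaplan-Meier matches hand product-limit arithmetic", {
  km <- kaplan_meier(surv_tbl(c(1, 2, 3), 1, "A"), "A")
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))

  all_cens <- kaplan_meier(surv_tbl(c(5, 8, 10), 0, "A"), "A")
  expect_true(all(all_cens$survival == 1))

  expect_error(kaplan_meier(surv_tbl(1, 1, "A"), "B"), "no records")
})

test_that("Kaplan-Meier equals a brute-force risk-set recomputation", {
  set.seed(55)
  tab <- surv_tbl(round(rexp(30, 0.05), 1) + 0.5, rbinom(30, 1, 0.7), "A")
  km <- kaplan_meier(tab, "A")
  oracle <- km_oracle(tab$time_weeks, tab$event)
  expect_equal(km$time, oracle$time)
  expect_equal(km$n_risk, oracle$n_risk)
  expect_equal(km$survival, oracle$survival, tolerance = 1e-12)
})

test_that("log-rank O, E, V match full 2x2 table enumeration on the 4-animal toy", {
  tab <- dplyr::bind_rows(surv_tbl(c(1, 2), 1, "A"), surv_tbl(c(3, 4), 1, "B"))
  lr <- logrank_test(tab, "A", "B")
  # hand enumeration: E_A = 1/2 + 1/3, V = 1/4 + 2/9
  expect_equal(unname(lr$expected["A"]), 1 / 2 + 1 / 3)
  expect_equal(lr$var, 1 / 4 + 2 / 9)
  expect_equal(unname(lr$observed["A"]), 2)
  expect_equal(lr$chisq, (2 - 5 / 6)^2 / (1 / 4 + 2 / 9))
  # independent oracle agrees
  o <- logrank_oracle(tab$time_weeks, tab$event, tab$group == "A")
  expect_equal(lr$chisq, o$chisq)
  # O - E sums to zero across the two groups
  expect_equal(sum(lr$observed - lr$expected), 0)
})

test_that("log-rank is symmetric under identical groups and relabeling", {
  a <- surv_tbl(c(3, 5, 8, 8, 12), c(1, 1, 0, 1, 1), "A")
  b <- a; b$group <- "B"; b$animal_id <- paste0(b$animal_id, "_copy")
  tab <- dplyr::bind_rows(a, b)
  lr <- logrank_test(tab, "A", "B")
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  # relabeling animal ids does not change O/E/V
  tab2 <- tab; tab2$animal_id <- paste0(tab2$animal_id, "_x")
  lr2 <- logrank_test(tab2, "A", "B")
  expect_equal(lr2$expected, lr$expected)
  expect_equal(lr2$var, lr$var)
})

test_that("stratified log-rank reduces to unstratified with one stratum and drops bad strata", {
  set.seed(9)
  tab <- dplyr::bind_rows(
    surv_tbl(rexp(20, 0.05), rbinom(20, 1, 0.8), "A"),
    surv_tbl(rexp(20, 0.08), rbinom(20, 1, 0.8), "B")
  )
  tab$sex <- "F"
  expect_equal(logrank_test(tab, "A", "B", strata = "sex")$chisq,
               logrank_test(tab, "A", "B")$chisq)

  # a stratum holding only one group is dropped with a warning
  tab2 <- tab
  tab2$sex[tab2$group == "A"][1:3] <- "M"
  expect_warning(lr <- logrank_test(tab2, "A", "B", strata = "sex"), "dropped")
  ref <- logrank_test(tab2[tab2$sex == "F", ], "A", "B")
  expect_equal(lr$chisq, ref$chisq)
})

test_that("zero total events yields p = 1 with a warning, not a crash", {
  tab <- dplyr::bind_rows(surv_tbl(c(3, 4), 0, "A"), surv_tbl(c(5, 6), 0, "B"))
  expect_warning(lr <- logrank_test(tab, "A", "B"), "no events")
  expect_equal(lr$p_value, 1)
})

test_that("hazard-ratio estimators match hand arithmetic and conventions", {
  tab <- dplyr::bind_rows(surv_tbl(c(1, 2), 1, "A"), surv_tbl(c(3, 4), 1, "B"))
  ea <- 5 / 6; eb <- 4 - ea; v <- 1 / 4 + 2 / 9 # 4 events in total
  mh <- log_hazard_ratio(tab, "A", "B")
  expect_equal(mh$log_hr, log((2 / ea) / (2 / eb)))
  expect_equal(mh$se, sqrt(1 / ea + 1 / eb))
  expect_equal(mh$ci95, mh$log_hr + c(-1.96, 1.96) * mh$se)
  sc <- log_hazard_ratio(tab, "A", "B", "score")
  expect_equal(sc$log_hr, (2 - ea) / v)
  expect_equal(sc$se, 1 / sqrt(v))

  # identical groups: both estimators at zero
  b <- tab[tab$group == "A", ]; b$group <- "B"; b$animal_id <- paste0(b$animal_id, "c")
  same <- dplyr::bind_rows(tab[tab$group == "A", ], b)
  expect_equal(log_hazard_ratio(same, "A", "B")$log_hr, 0)
  expect_equal(log_hazard_ratio(same, "A", "B", "score")$log_hr, 0)

  # protective first-listed group (longer lives) gives a negative log HR
  prot <- dplyr::bind_rows(surv_tbl(c(30, 35, 40), 1, "A"),
                           surv_tbl(c(5, 8, 10), 1, "B"))
  expect_lt(log_hazard_ratio(prot, "A", "B")$log_hr, 0)

  noev <- dplyr::bind_rows(surv_tbl(c(1, 2), 0, "A"), surv_tbl(c(3, 4), 1, "B"))
  expect_error(suppressWarnings(log_hazard_ratio(noev, "A", "B")), "zero events")
})

test_that("both estimators recover a true hazard ratio of 2", {
  # censored follow-up (~50% events): the O/E-based estimators compress toward
  # the null as the event fraction approaches 1
  est <- vapply(1:50, function(r) {
    tab <- simulate_survival(
      survival_params(list(A = list(a = 0.10, b = 0, n = 200),
                           B = list(a = 0.05, b = 0, n = 200)),
                      censor_time = 10),
      seed = 500 + r
    )
    c(log_hazard_ratio(tab, "A", "B")$log_hr,
      log_hazard_ratio(tab, "A", "B", "score")$log_hr)
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - log(2)) / log(2), 0.10)
  expect_lt(abs(mean(est[2, ]) - log(2)) / log(2), 0.10)
})

test_that("score and Mantel-Haenszel agree to first order near HR = 1", {
  diff_at <- function(hr) {
    mean(vapply(1:30, function(r) {
      tab <- simulate_survival(
        survival_params(list(A = list(a = 0.05 * hr, b = 0, n = 150),
                             B = list(a = 0.05, b = 0, n = 150))),
        seed = 900 + r
      )
      abs(log_hazard_ratio(tab, "A", "B")$log_hr -
            log_hazard_ratio(tab, "A", "B", "score")$log_hr)
    }, numeric(1)))
  }
  d105 <- diff_at(1.05); d110 <- diff_at(1.10); d200 <- diff_at(2.0)
  expect_lt(d105, 0.02)
  expect_lt(d110, 0.02)
  expect_lt(d105, d200)
})

test_that("onset analysis treats death-before-onset as censoring", {
  # five animals, onset at 4/5 in A (one dies at 3 before onset)
  tab <- dplyr::bind_rows(
    surv_tbl(c(4, 4, 3, 5, 6), c(1, 1, 0, 1, 1), "A"),
    surv_tbl(c(4, 4, 5, 5, 6), c(1, 1, 1, 1, 1), "B")
  )
  res <- onset_analysis(tab, "A", "B")
  km_a <- res$km$A
  # hand risk sets: t=3 censor only; t=4 risk 4, 2 events -> S = 1/2
  expect_equal(km_a$time, c(3, 4, 5, 6))
  expect_equal(km_a$n_risk, c(5, 4, 2, 1))
  expect_equal(km_a$survival[km_a$time == 4], 0.5)

  # identical onset distributions: log-rank p = 1
  mir <- dplyr::bind_rows(surv_tbl(c(4, 5, 6), 1, "A"), surv_tbl(c(4, 5, 6), 1, "B"))
  expect_equal(onset_analysis(mir, "A", "B")$logrank$p_value, 1)

  # all animals show the phenotype in the same week: one-step drop to 0
  onest <- surv_tbl(rep(7, 4), 1, "A")
  km1 <- kaplan_meier(onest, "A")
  expect_equal(km1$survival, 0)
})

test_that("forest assembly is order-stable and round-trips through CSV", {
  tab <- dplyr::bind_rows(surv_tbl(c(1, 2, 5), 1, "A"), surv_tbl(c(3, 4, 8), 1, "B"))
  hr1 <- log_hazard_ratio(tab, "A", "B")
  hr2 <- log_hazard_ratio(tab, "B", "A")
  ft <- forest_assemble(list(hr1, hr2), c("first", "second"))
  expect_equal(ft$label, c("first", "second"))
  expect_equal(ft$log_hr[1], hr1$log_hr)

  one <- forest_assemble(list(hr1))
  expect_equal(nrow(one), 1)
  expect_equal(one$log_hr, hr1$log_hr)

  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ft, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(ft), tolerance = 1e-12)
  expect_error(forest_assemble(list()), ">= 1")
})
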