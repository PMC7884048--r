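# Independent brute-force oracles, deliberately written from first principles
# rather than reusing the package's code paths.

# Product-limit estimator by explicit risk-set recomputation at every distinct
# time (deaths precede censorings at tied times).
km_oracle <- function(time, event) {
  times <- sort(unique(time))
  surv <- 1
  out <- data.frame(time = times, n_risk = NA_real_, n_event = NA_real_,
                    survival = NA_real_)
  for (i in seq_along(times)) {
    t <- times[i]
    at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    surv <- surv * (1 - d / at_risk)
    out$n_risk[i] <- at_risk
    out$n_event[i] <- d
    out$survival[i] <- surv
  }
  out
}

# Log-rank O/E/V for group A by enumerating the 2x2 table at each event time.
logrank_oracle <- function(time, event, is_a) {
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    n <- sum(time >= t)
    n_a <- sum(time >= t & is_a)
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & is_a)
    O <- O + d_a
    E <- E + d * n_a / n
    if (n > 1) V <- V + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  list(O = O, E = E, V = V, chisq = (O - E)^2 / V)
}

# A tiny survival tibble builder.
surv_tbl <- function(time, event, group, sex = "F") {
  tibble::tibble(
    animal_id = sprintf("%s_%03d", group, seq_along(time)),
    group = group, sex = rep_len(sex, length(time)),
    time_weeks = time, event = as.integer(event)
  )
}

# Two-group expression simulation used across tests.
sim_two_groups <- function(n_genes, lambda_a, lambda_b, seed,
                           n_samples = 5, noise = 0.25,
                           prog_a = 0, prog_b = 0, prog_fc = 1) {
  catalog <- simulate_gene_catalog(n_genes, seed = seed)
  sim <- simulate_expression(
    catalog,
    list(
      A = lesion_params(lambda_a, n_samples = n_samples, noise_sd_log2 = noise,
                        prog_de_fraction = prog_a, prog_de_log2fc = prog_fc),
      B = lesion_params(lambda_b, n_samples = n_samples, noise_sd_log2 = noise,
                        prog_de_fraction = prog_b, prog_de_log2fc = prog_fc)
    ),
    seed = seed
  )
  c(sim, list(catalog = catalog))
}
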