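#' Gompertz survival parameters for a cohort
#'
#' Hazard is `h(t) = a * exp(b * t)` with `t` in weeks; `b = 0` is the
#' exponential special case. Event times are drawn by inverting the Gompertz
#' survivor function, `t = log(1 - (b/a) * log(U)) / b` for `U ~ Unif(0, 1)`.
#'
#' @param groups Named list; each element a list with `a` (> 0), `b` (>= 0) and
#'   `n` (animals in the group).
#' @param censor_time Administrative censoring time in weeks, or `NULL` for none.
#' @return A `survival_params` list.
#' @export
survival_params <- function(groups, censor_time = NULL) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == "")) {
    abort("`groups` must be a named list of lists with a, b, n.")
  }
  for (lab in names(groups)) {
    g <- groups[[lab]]
    if (is.null(g$a) || g$a <= 0) abort(sprintf("group '%s': `a` must be > 0.", lab))
    if (is.null(g$b) || g$b < 0) abort(sprintf("group '%s': `b` must be >= 0.", lab))
    if (is.null(g$n) || g$n < 1) abort(sprintf("group '%s': `n` must be >= 1.", lab))
  }
  structure(list(groups = groups, censor_time = censor_time),
            class = "survival_params")
}

# Inverse-CDF Gompertz draw; b = 0 falls back to the exponential closed form.
rgompertz_inv <- function(u, a, b) {
  if (b == 0) -log(u) / a else log(1 - (b / a) * log(u)) / b
}

#' Simulate a survival table from Gompertz hazards
#'
#' @param params [survival_params()].
#' @param seed Master seed; one derived substream per group.
#' @return A tibble with `animal_id`, `group`, `sex`, `time_weeks`, `event`
#'   (1 = death observed, 0 = censored). Times past `censor_time` are recorded
#'   at `censor_time` with `event = 0`.
#' @export
simulate_survival <- function(params, seed = 1L) {
  stopifnot(inherits(params, "survival_params"))
  rows <- list()
  for (lab in names(params$groups)) {
    g <- params$groups[[lab]]
    t <- with_seed(derive_seed(seed, paste0("survival/", lab)), {
      rgompertz_inv(runif(g$n), g$a, g$b)
    })
    event <- rep(1L, g$n)
    if (!is.null(params$censor_time)) {
      cens <- t >= params$censor_time
      t[cens] <- params$censor_time
      event[cens] <- 0L
    }
    rows[[lab]] <- tibble(
      animal_id = sprintf("%s_a%03d", lab, seq_len(g$n)),
      group = lab, sex = rep_len(c("F", "M"), g$n),
      time_weeks = t, event = event
    )
  }
  bind_rows(rows)
}

#' Growth-curve parameters for weekly body weights
#'
#' The deterministic trajectory is a logistic rise from `w0` toward `asymptote`
#' (midpoint `t_mid` weeks, rate `growth_rate` per week) followed by an
#' exponential late-life decline of `decline_rate` per week starting at
#' `decline_onset`; observation noise is additive Gaussian in grams.
#'
#' @param groups Named list; per group a list with any of `w0`, `asymptote`,
#'   `growth_rate`, `t_mid`, `decline_rate`, `decline_onset`, `noise_sd`
#'   (defaults 8 g, 25 g, 0.35 /wk, 8 wk, 0.005 /wk, 40 wk, 0.5 g).
#' @return A `weight_params` list.
#' @export
weight_params <- function(groups) {
  defaults <- list(w0 = 8, asymptote = 25, growth_rate = 0.35, t_mid = 8,
                   decline_rate = 0.005, decline_onset = 40, noise_sd = 0.5)
  if (!is.list(groups) || is.null(names(groups))) {
    abort("`groups` must be a named list.")
  }
  groups <- lapply(groups, function(g) {
    g <- utils::modifyList(defaults, g)
    if (g$asymptote <= 0) abort("`asymptote` must be > 0.")
    if (g$noise_sd < 0) abort("`noise_sd` must be >= 0.")
    g
  })
  structure(list(groups = groups), class = "weight_params")
}

# Deterministic mean trajectory in grams at age t weeks.
weight_curve <- function(t, g) {
  rise <- g$w0 + (g$asymptote - g$w0) / (1 + exp(-g$growth_rate * (t - g$t_mid)))
  rise * exp(-g$decline_rate * pmax(0, t - g$decline_onset))
}

#' Simulate weekly body weights coupled to simulated lifespans
#'
#' Every animal in `survival` gets weekly weights from week 0 up to (and
#' including) its last completed week of life, `floor(time_weeks)`; no weights
#' are recorded after death. Noise is independent across weeks and animals.
#'
#' @param params [weight_params()] covering every group in `survival`.
#' @param survival Survival tibble from [simulate_survival()].
#' @param seed Master seed.
#' @return Long tibble: `animal_id`, `group`, `week`, `weight_g`.
#' @export
simulate_weights <- function(params, survival, seed = 1L) {
  stopifnot(inherits(params, "weight_params"))
  assert_survival_table(survival)
  missing <- setdiff(unique(survival$group), names(params$groups))
  if (length(missing)) {
    abort(sprintf("no weight trajectory spec for group(s): %s",
                  paste(missing, collapse = ", ")))
  }
  rows <- vector("list", nrow(survival))
  for (i in seq_len(nrow(survival))) {
    g <- params$groups[[survival$group[i]]]
    weeks <- 0:floor(survival$time_weeks[i])
    w <- with_seed(derive_seed(seed, paste0("weights/", survival$animal_id[i])), {
      pmax(0.1, weight_curve(weeks, g) + rnorm(length(weeks), 0, g$noise_sd))
    })
    rows[[i]] <- tibble(
      animal_id = survival$animal_id[i], group = survival$group[i],
      week = weeks, weight_g = w
    )
  }
  bind_rows(rows)
}

#' Simulate a tissue slab as a homogeneous Poisson point cloud
#'
#' Cell nuclei are reduced to centroid points scattered uniformly in a slab of
#' `dims_um[1] x dims_um[2]` um in x/y and `n_sections * cut_thickness_um` um
#' in z, with the total count Poisson at the requested density.
#'
#' @param density_per_mm3 Expected nuclei per cubic millimetre (>= 0).
#' @param dims_um Numeric length-2: slab x and y extent in um (> 0).
#' @param n_sections Number of cut sections stacked along z.
#' @param cut_thickness_um Cut thickness of each section in um.
#' @param seed Seed; the cloud is deterministic given the seed.
#' @return A `tissue_volume` list: `points` tibble (x, y, z in um), `dims_um`,
#'   `n_sections`, `cut_thickness_um`, `true_count`.
#' @export
simulate_tissue <- function(density_per_mm3, dims_um = c(2000, 2000),
                            n_sections = 8L, cut_thickness_um = 40,
                            seed = 1L) {
  assert_scalar_number(density_per_mm3, "density_per_mm3", min = 0)
  if (length(dims_um) != 2 || any(dims_um <= 0)) {
    abort("`dims_um` must be two positive extents (um).")
  }
  assert_scalar_number(n_sections, "n_sections", min = 1)
  assert_scalar_number(cut_thickness_um, "cut_thickness_um", min = 0, strict = TRUE)
  z_um <- n_sections * cut_thickness_um
  vol_mm3 <- dims_um[1] * dims_um[2] * z_um / 1e9
  pts <- with_seed(derive_seed(seed, "tissue"), {
    n <- rpois(1, density_per_mm3 * vol_mm3)
    tibble(
      x = runif(n, 0, dims_um[1]),
      y = runif(n, 0, dims_um[2]),
      z = runif(n, 0, z_um)
    )
  })
  structure(
    list(points = pts, dims_um = dims_um, n_sections = as.integer(n_sections),
         cut_thickness_um = cut_thickness_um, true_count = nrow(pts)),
    class = "tissue_volume"
  )
}
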