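#' Active-compound concentration of an encapsulated diet supplement
#'
#' A supplement added at `encapsulated_mg_per_kg` milligrams per kilogram of
#' food, of which `active_fraction` is active compound, yields
#' `encapsulated_mg_per_kg * active_fraction` mg active compound per kg food,
#' which is numerically the concentration in ppm. E.g. 420 mg/kg encapsulated
#' rapamycin at 10% active gives a 42 ppm diet.
#'
#' @param encapsulated_mg_per_kg Supplement dose in mg per kg food (>= 0).
#' @param active_fraction Active-compound fraction in `[0, 1]`.
#' @return Concentration in ppm.
#' @export
#' @examples
#' diet_ppm(420, 0.10)
diet_ppm <- function(encapsulated_mg_per_kg, active_fraction) {
  assert_scalar_number(encapsulated_mg_per_kg, "encapsulated_mg_per_kg", min = 0)
  assert_scalar_number(active_fraction, "active_fraction", min = 0)
  if (active_fraction > 1) abort("`active_fraction` must be in [0, 1].")
  encapsulated_mg_per_kg * active_fraction
}

#' Daily ration under dietary restriction
#'
#' The restricted ration is the ad libitum intake reduced by the restriction
#' fraction, rounded half-up to one decimal as rations are printed: 30%
#' restriction of a 2.3 g/day intake gives 1.6 g/day.
#'
#' @param adlib_intake_g_per_day Ad libitum intake in g/day (> 0).
#' @param restriction_fraction Fractional reduction in `[0, 1)`.
#' @return Ration in g/day, one decimal.
#' @export
#' @examples
#' dr_ration(2.3, 0.30)
dr_ration <- function(adlib_intake_g_per_day, restriction_fraction) {
  assert_scalar_number(adlib_intake_g_per_day, "adlib_intake_g_per_day",
                       min = 0, strict = TRUE)
  assert_scalar_number(restriction_fraction, "restriction_fraction", min = 0)
  if (restriction_fraction >= 1) abort("`restriction_fraction` must be < 1.")
  round_half_up(adlib_intake_g_per_day * (1 - restriction_fraction), 1)
}
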