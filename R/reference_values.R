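# reference values from the C. sorokiniana photobioreactor study this
# package models: the 3^2 design summary, the published reduced response
# surfaces, their ANOVA tables, and the desirability validation experiment.
# These are inputs (printed tables), not things the package computes.

#' Treatment-level summary of the 3^2 factorial experiment
#'
#' Mean and standard deviation of final-day (day 14) biomass concentration
#' and lipid content for the nine CO2-by-light treatments, three replicates
#' each, as reported for the *C. sorokiniana* bubble-column cultures. Use
#' [reconstitute_replicates()] to expand these into replicate-level rows for
#' ANOVA.
#'
#' @return A tibble with columns `treatment`, `light_umol_m2_s`, `co2_pct`,
#'   `biomass_g_L`, `biomass_sd`, `lipid_pct`, `lipid_sd`.
#' @export
#' @examples
#' reference_design_summary()
reference_design_summary <- function() {
  tibble(
    treatment = paste0("T", 1:9),
    light_umol_m2_s = c(13, 39, 65, 13, 39, 65, 13, 39, 65),
    co2_pct = c(0.03, 0.03, 0.03, 10, 10, 10, 20, 20, 20),
    biomass_g_L = c(0.44, 2.81, 3.45, 2.21, 2.02, 2.93, 1.08, 2.28, 1.72),
    biomass_sd = c(0.14, 0.16, 0.20, 0.16, 0.91, 0.30, 0.52, 0.39, 0.29),
    lipid_pct = c(37.1, 15.8, 13.5, 31.4, 15.4, 17.2, 49.1, 22.3, 38.9),
    lipid_sd = c(3.5, 1.5, 4.1, 13.5, 4.4, 1.1, 0.5, 5.1, 1.8)
  )
}

#' Published reduced response-surface models
#'
#' The reduced quadratic equations reported for the factorial experiment, in
#' natural units (A = CO2 %, B = light in umol m-2 s-1):
#' biomass (g/L) `= -0.645 + 0.145 A + 0.113 B - 0.0022 AB - 0.00077 B^2`
#' (the A^2 term was pruned as non-significant) and lipid content (%)
#' `= 58.75 - 1.21 A - 1.84 B + 0.0745 A^2 + 0.018 B^2` (the AB term was
#' pruned).
#'
#' @param response `"biomass"` or `"lipid"`.
#' @return A `quadratic_model` built from the published coefficients.
#' @export
#' @examples
#' predict_response(reference_model("biomass"), A = 0.03, B = 13)
reference_model <- function(response = c("biomass", "lipid")) {
  response <- match.arg(response)
  if (response == "biomass") {
    quadratic_model(
      c(`(Intercept)` = -0.645, A = 0.145, B = 0.113, AB = -0.0022, BB = -0.00077),
      response = "biomass_g_L"
    )
  } else {
    quadratic_model(
      c(`(Intercept)` = 58.75, A = -1.21, B = -1.84, AA = 0.0745, BB = 0.018),
      response = "lipid_pct"
    )
  }
}

#' Published ANOVA tables for the full quadratic models
#'
#' Per-term sums of squares, F values and p-values reported for the full
#' five-term quadratic fits of biomass and lipid content; the usual inputs
#' to [terms_to_drop()] when reproducing the published term pruning.
#'
#' @param response `"biomass"` or `"lipid"`.
#' @return A tibble with columns `term`, `sum_of_squares`, `df`,
#'   `mean_square`, `F_value`, `p_value` (error and corrected-total rows
#'   carry NA where not reported).
#' @export
#' @examples
#' terms_to_drop(reference_anova("biomass")) # "AA"
reference_anova <- function(response = c("biomass", "lipid")) {
  response <- match.arg(response)
  if (response == "biomass") {
    tibble(
      term = c("A", "B", "AA", "AB", "BB", "error", "total"),
      sum_of_squares = c(1.30008, 10.037, 0.863873, 4.20206, 1.48127, 5.19205, 23.2575),
      df = c(1L, 1L, 1L, 1L, 1L, 19L, 24L),
      mean_square = c(1.30008, 10.037, 0.863873, 4.20206, 1.48127, 0.273266, NA),
      F_value = c(4.76, 36.73, 3.16, 15.38, 5.42, NA, NA),
      p_value = c(0.0419, 0.0000, 0.0914, 0.0009, 0.0311, NA, NA)
    )
  } else {
    tibble(
      term = c("A", "B", "AA", "AB", "BB", "error", "total"),
      sum_of_squares = c(639.147, 1102.9, 262.257, 63.9982, 712.514, 528.822, 3256.24),
      df = c(1L, 1L, 1L, 1L, 1L, 16L, 21L),
      mean_square = c(639.147, 1102.9, 262.257, 63.9982, 712.514, 33.0514, NA),
      F_value = c(19.34, 33.37, 7.93, 1.94, 21.56, NA, NA),
      p_value = c(0.0004, 0.0000, 0.0124, 0.1831, 0.0003, NA, NA)
    )
  }
}

#' Desirability-optimum validation experiment
#'
#' The model-optimized operating point (20% CO2, 29.9 umol m-2 s-1 light)
#' with the predicted responses and the triplicate validation measurements:
#' predicted biomass 2.01 g/L vs 1.66 +/- 0.09 observed; predicted lipid
#' fraction 30.9% vs 32.8 +/- 5.9; predicted lipid concentration 0.62 g/L
#' (= 2.01 x 30.9%) vs 0.54 +/- 0.09.
#'
#' @return A tibble with columns `response`, `predicted`, `observed`,
#'   `observed_sd`, `pct_error` (whole-number percent as printed).
#' @export
#' @examples
#' reference_validation()
reference_validation <- function() {
  tibble(
    response = c("biomass_g_L", "lipid_pct", "lipid_g_L"),
    predicted = c(2.01, 30.9, 0.62),
    observed = c(1.66, 32.8, 0.54),
    observed_sd = c(0.09, 5.9, 0.09),
    pct_error = c(17L, 6L, 13L)
  )
}
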