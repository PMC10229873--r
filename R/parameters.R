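#' Kinetic and mass-transfer parameters of the culture model
#'
#' Bundles every rate constant, half-saturation constant, yield and
#' gas-transfer coefficient of the batch photobioreactor model into a
#' validated named list. All concentrations are carried in mg/L and time in
#' days; nitrate and phosphate are expressed as the mass of their salts
#' (KNO3 and potassium phosphate respectively), matching how experimental
#' yields are usually quoted.
#'
#' @param mu_max Maximum specific growth rate (1/day).
#' @param mu_d First-order biomass decay (maintenance) rate (1/day).
#' @param K_N,K_P,K_C Half-saturation constants for nitrate, phosphate and
#'   dissolved CO2 (mg/L).
#' @param K_I Half-saturation constant for light (umol m-2 s-1). Note: some
#'   published parameter tables mislabel this constant as a carbon-dioxide
#'   constant; here it is, as in the growth law, the light constant.
#' @param mu_mP,mu_mN,mu_mC,mu_mO2 First-order maintenance consumption rates
#'   of phosphate, nitrate, dissolved CO2 and dissolved O2 (1/day).
#' @param Y_PX,Y_NX,Y_CX Substrate-per-biomass yields (mg substrate per mg
#'   biomass) for phosphate, nitrate and CO2.
#' @param Y_O2X Oxygen produced per biomass formed (mg/mg).
#' @param kla_C,kla_O2 Volumetric gas-liquid mass-transfer coefficients for
#'   CO2 and O2 (1/day).
#' @param C_star_C,C_star_O2 Liquid-phase equilibrium concentrations of CO2
#'   and O2 (mg/L).
#' @param K_pH Proportionality constant coupling pH change to dissolved-CO2
#'   change (L/mg, positive; pH rises as CO2 falls).
#' @param alpha Maximum fraction of incident light lost to shading by the
#'   biomass and reactor wall, in \[0, 1\] (dimensionless).
#' @param K_IX Biomass half-saturation constant of the shading term (mg/L).
#'
#' @return An object of class `kinetic_parameters`: a named list of the 21
#'   parameters above.
#' @seealso [chlorella_kinetics()] for the fitted *Chlorella sorokiniana*
#'   values, [simulate_culture()] for the model they drive.
#' @export
#' @examples
#' p <- chlorella_kinetics()
#' p$mu_max
kinetic_parameters <- function(mu_max = 2.19, mu_d = 0.0004,
                               K_N = 31.5, K_P = 42, K_C = 0.0120,
                               K_I = 67.34,
                               mu_mP = 0.0162, mu_mN = 0.4042,
                               mu_mC = 0.0013, mu_mO2 = 0.0019,
                               Y_PX = 0.116, Y_NX = 0.0315,
                               Y_CX = 0.00095, Y_O2X = 0.0019,
                               kla_C = 3.45, C_star_C = 0.81,
                               kla_O2 = 3.87, C_star_O2 = 6.00,
                               K_pH = 6.11, alpha = 0.263, K_IX = 0.0252) {
  p <- list(
    mu_max = mu_max, mu_d = mu_d, K_N = K_N, K_P = K_P, K_C = K_C,
    K_I = K_I, mu_mP = mu_mP, mu_mN = mu_mN, mu_mC = mu_mC,
    mu_mO2 = mu_mO2, Y_PX = Y_PX, Y_NX = Y_NX, Y_CX = Y_CX,
    Y_O2X = Y_O2X, kla_C = kla_C, C_star_C = C_star_C,
    kla_O2 = kla_O2, C_star_O2 = C_star_O2, K_pH = K_pH,
    alpha = alpha, K_IX = K_IX
  )
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))]
  if (length(bad) > 0) {
    abort(paste0("kinetic parameters must be finite scalars: ", paste(bad, collapse = ", ")))
  }
  neg <- names(p)[vapply(p, function(x) x < 0, logical(1))]
  if (length(neg) > 0) {
    abort(paste0("kinetic parameters must be non-negative: ", paste(neg, collapse = ", ")))
  }
  if (p$alpha > 1) {
    abort("`alpha` is a fraction and must lie in [0, 1]")
  }
  structure(p, class = "kinetic_parameters")
}

#' Fitted parameter set for *Chlorella sorokiniana*
#'
#' The full parameter vector estimated for a wild *C. sorokiniana* strain
#' grown in a 0.2-L bubble-column photobioreactor under 20% CO2 and
#' 29.9 umol m-2 s-1 light. These are the package's reference values, used as
#' defaults throughout and as the generating truth of the synthetic-data
#' module.
#'
#' @param ... Named overrides passed to [kinetic_parameters()].
#' @return A `kinetic_parameters` object.
#' @export
chlorella_kinetics <- function(...) {
  kinetic_parameters(...)
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("<kinetic_parameters>\n")
  print(tibble(parameter = names(x), value = unlist(x)), n = Inf)
  invisible(x)
}

#' Culture state vector
#'
#' A single snapshot of the six model variables: biomass `X`, nitrate `N`
#' (as KNO3), phosphate `P` (as phosphate salt), dissolved CO2 `C`, dissolved
#' O2 `O2` (all mg/L) and `pH`.
#'
#' @param X,N,P,C,O2 Concentrations in mg/L, all non-negative.
#' @param pH Culture pH in \[0, 14\].
#' @return A named numeric vector of class `culture_state`.
#' @export
#' @examples
#' culture_state(X = 100, N = 670, P = 800)
culture_state <- function(X = 100, N = 670, P = 800, C = 0.81,
                          O2 = 6.00, pH = 7.0) {
  s <- c(X = X, N = N, P = P, C = C, O2 = O2, pH = pH)
  if (any(!is.finite(s))) abort("culture state values must be finite")
  if (any(s[c("X", "N", "P", "C", "O2")] < 0)) {
    abort("concentrations X, N, P, C, O2 must be non-negative")
  }
  if (pH < 0 || pH > 14) abort("`pH` must lie in [0, 14]")
  structure(s, class = "culture_state")
}

#' Reactor and simulation configuration
#'
#' Incident light, the light-attenuation law, photoperiod, initial state and
#' the output time grid for [simulate_culture()].
#'
#' The three attenuation laws (see [effective_light()]):
#' `"bounded_shading"` (default) ramps from no shading at zero biomass down
#' to a floor of `I0 * (1 - alpha)`; `"literal_eq"` is the typeset form
#' `I0 * (1 - alpha * (1 + X) / (K_IX + X))`, which can go negative and is
#' clamped at 0; `"available_fraction"` is `I0 * alpha * K_IX / (K_IX + X)`.
#' Only the default is dimensionally consistent and non-negative over the
#' biomass range of interest.
#'
#' @param I0 Incident light intensity (umol m-2 s-1), non-negative.
#' @param attenuation_model One of `"bounded_shading"`, `"literal_eq"`,
#'   `"available_fraction"`.
#' @param photoperiod_fraction Fraction of each day with light on, in (0, 1].
#'   The default 1 models the constant-light assumption of the growth model;
#'   values below 1 switch to a square-wave light signal.
#' @param initial_state A [culture_state()].
#' @param t_end Culture duration in days, positive.
#' @param output_grid Strictly increasing times (days) within \[0, t_end\] at
#'   which the trajectory is reported.
#' @param rtol,atol Relative and absolute solver tolerances, recorded in the
#'   simulation metadata.
#' @return An object of class `reactor_config`.
#' @export
#' @examples
#' reactor_config(I0 = 29.9, t_end = 14)
reactor_config <- function(I0 = 29.9,
                           attenuation_model = c("bounded_shading", "literal_eq", "available_fraction"),
                           photoperiod_fraction = 1.0,
                           initial_state = culture_state(),
                           t_end = 14,
                           output_grid = seq(0, t_end, by = 0.1),
                           rtol = 1e-6, atol = 1e-9) {
  attenuation_model <- match.arg(attenuation_model)
  if (!is.numeric(I0) || I0 < 0) abort("`I0` must be non-negative")
  if (photoperiod_fraction <= 0 || photoperiod_fraction > 1) {
    abort("`photoperiod_fraction` must lie in (0, 1]")
  }
  if (!inherits(initial_state, "culture_state")) {
    initial_state <- do.call(culture_state, as.list(initial_state))
  }
  if (t_end <= 0) abort("`t_end` must be positive")
  output_grid <- as.numeric(output_grid)
  if (any(diff(output_grid) <= 0)) abort("`output_grid` must be strictly increasing")
  if (min(output_grid) < 0 || max(output_grid) > t_end) {
    abort("`output_grid` must lie within [0, t_end]")
  }
  structure(
    list(
      I0 = I0, attenuation_model = attenuation_model,
      photoperiod_fraction = photoperiod_fraction,
      initial_state = initial_state, t_end = t_end,
      output_grid = output_grid, rtol = rtol, atol = atol
    ),
    class = "reactor_config"
  )
}

#' @export
print.reactor_config <- function(x, ...) {
  cat("<reactor_config>\n")
  cat("  I0:", x$I0, "umol m-2 s-1; attenuation:", x$attenuation_model, "\n")
  cat("  photoperiod fraction:", x$photoperiod_fraction, "\n")
  cat("  t_end:", x$t_end, "d; output points:", length(x$output_grid), "\n")
  cat("  initial state:", paste(names(x$initial_state),
    signif(unname(x$initial_state), 4),
    sep = "=", collapse = ", "
  ), "\n")
  invisible(x)
}

# the six model variables, in canonical order
culture_variables <- function() c("X", "N", "P", "C", "O2", "pH")
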