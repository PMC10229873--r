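#' Light intensity reaching the culture after biomass shading
#'
#' As biomass accumulates, absorption and scattering by the cells (and
#' fouling of the reactor wall) attenuate the incident light. The default
#' bounded-shading law saturates at a fraction `alpha` of the incident
#' intensity:
#' \deqn{I(X) = I_0 \left(1 - \alpha \frac{X}{K_{IX} + X}\right)}
#' so `I(0) = I0` and `I` never falls below `I0 * (1 - alpha)`. Two
#' alternative readings of the attenuation law are provided for comparison;
#' both are clamped at zero where they would go negative.
#'
#' @param X Biomass concentration (mg/L), non-negative; vectorized.
#' @param I0 Incident light (umol m-2 s-1), non-negative.
#' @param alpha Maximum shaded fraction, in \[0, 1\].
#' @param K_IX Biomass half-saturation constant of shading (mg/L), positive.
#' @param model Attenuation law; see [reactor_config()].
#' @return Effective light intensity (umol m-2 s-1), same length as `X`.
#' @export
#' @examples
#' effective_light(X = 0, I0 = 29.9)                 # no biomass, no shading
#' effective_light(X = 1e4, I0 = 29.9)               # near the 1 - alpha floor
effective_light <- function(X, I0, alpha = 0.263, K_IX = 0.0252,
                            model = c("bounded_shading", "literal_eq", "available_fraction")) {
  model <- match.arg(model)
  if (any(X < 0)) abort("`X` must be non-negative")
  if (any(I0 < 0)) abort("`I0` must be non-negative")
  if (any(K_IX <= 0)) abort("`K_IX` must be positive")
  if (any(alpha < 0 | alpha > 1)) abort("`alpha` must lie in [0, 1]")
  I <- switch(model,
    bounded_shading = I0 * (1 - alpha * X / (K_IX + X)),
    literal_eq = I0 * (1 - alpha * (1 + X) / (K_IX + X)),
    available_fraction = I0 * alpha * K_IX / (K_IX + X)
  )
  pmax(I, 0)
}

#' Multi-substrate Monod specific growth rate
#'
#' The specific growth rate is the product of four saturating Monod factors,
#' one per limiting resource (nitrate, phosphate, dissolved CO2, light):
#' \deqn{\mu = \mu_{max} \frac{N}{K_N + N} \frac{P}{K_P + P}
#'   \frac{C}{K_C + C} \frac{I}{K_I + I}}
#' Any absent resource drives growth to zero; saturating all four drives
#' \eqn{\mu \to \mu_{max}}.
#'
#' @param params A [kinetic_parameters()] object.
#' @param N,P,C Nitrate, phosphate and dissolved-CO2 concentrations (mg/L),
#'   non-negative; vectorized.
#' @param I_eff Effective light at the cells (umol m-2 s-1), non-negative,
#'   typically from [effective_light()].
#' @return Specific growth rate (1/day), in \[0, `mu_max`\].
#' @export
#' @examples
#' p <- chlorella_kinetics()
#' specific_growth_rate(p, N = 670, P = 800, C = 0.81, I_eff = 22)
specific_growth_rate <- function(params, N, P, C, I_eff) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (any(c(N, P, C, I_eff) < 0)) {
    abort("substrate concentrations and light must be non-negative")
  }
  params$mu_max *
    (N / (params$K_N + N)) *
    (P / (params$K_P + P)) *
    (C / (params$K_C + C)) *
    (I_eff / (params$K_I + I_eff))
}

# light signal at time t: constant, or square-wave when photoperiod < 1
incident_light <- function(t, config) {
  if (config$photoperiod_fraction >= 1) {
    return(config$I0)
  }
  ifelse((t %% 1) < config$photoperiod_fraction, config$I0, 0)
}

#' Time derivatives of the culture mass balances
#'
#' The right-hand side of the batch-reactor model. Biomass grows at the
#' Monod rate and decays by maintenance; each substrate is consumed in
#' proportion to growth (yield) plus a first-order maintenance term; the two
#' dissolved gases additionally exchange with the sparged gas phase through a
#' `kla * (C* - C)` transfer term; and pH moves opposite to dissolved CO2:
#' \deqn{dX/dt = (\mu - \mu_d) X}
#' \deqn{dN/dt = -Y_{NX} \mu X - \mu_{mN} N \qquad
#'       dP/dt = -Y_{PX} \mu X - \mu_{mP} P}
#' \deqn{dC/dt = -Y_{CX} \mu X + k_La_C (C^*_C - C) - \mu_{mC} C}
#' \deqn{dO_2/dt = +Y_{O_2X} \mu X + k_La_{O_2} (C^*_{O_2} - O_2) - \mu_{mO_2} O_2}
#' \deqn{dpH/dt = -K_{pH} \, dC/dt}
#'
#' Negative components of `state` are clamped to zero before evaluation so
#' that Monod factors stay non-negative during stiff integration.
#'
#' @param state A [culture_state()] (or named vector with the same fields).
#' @param params A [kinetic_parameters()] object.
#' @param config A [reactor_config()]; supplies incident light and the
#'   attenuation law.
#' @param t Time (days), only relevant when a photoperiod is configured.
#' @return A named numeric vector of derivatives for X, N, P, C, O2, pH
#'   (per day).
#' @export
#' @examples
#' culture_derivatives(culture_state(), chlorella_kinetics(), reactor_config())
culture_derivatives <- function(state, params, config, t = 0) {
  s <- pmax(unclass(state)[culture_variables()[1:5]], 0)
  I0_t <- incident_light(t, config)
  I <- effective_light(s[["X"]], I0_t,
    alpha = params$alpha, K_IX = params$K_IX,
    model = config$attenuation_model
  )
  mu <- specific_growth_rate(params, N = s[["N"]], P = s[["P"]], C = s[["C"]], I_eff = I)
  dX <- (mu - params$mu_d) * s[["X"]]
  dN <- -params$Y_NX * mu * s[["X"]] - params$mu_mN * s[["N"]]
  dP <- -params$Y_PX * mu * s[["X"]] - params$mu_mP * s[["P"]]
  dC <- -params$Y_CX * mu * s[["X"]] + params$kla_C * (params$C_star_C - s[["C"]]) -
    params$mu_mC * s[["C"]]
  dO2 <- params$Y_O2X * mu * s[["X"]] + params$kla_O2 * (params$C_star_O2 - s[["O2"]]) -
    params$mu_mO2 * s[["O2"]]
  c(X = dX, N = dN, P = dP, C = dC, O2 = dO2, pH = -params$K_pH * dC)
}

#' Simulate a batch culture
#'
#' Integrates the five mass-balance equations (biomass, nitrate, phosphate,
#' dissolved CO2, dissolved O2) with the stiff-capable `lsoda` solver from
#' \pkg{deSolve} and reports the trajectory on the configured output grid.
#' pH is an affine image of dissolved CO2 (`dpH = -K_pH dC`), so it is
#' reconstructed exactly as `pH0 - K_pH * (C - C0)` rather than integrated as
#' a sixth state.
#'
#' @param params A [kinetic_parameters()] object.
#' @param config A [reactor_config()] with initial state and output grid.
#' @return A tibble of class `culture_simulation` with columns `time` (days)
#'   and the six state variables, one row per output time. Attributes
#'   `params`, `config` record the generating inputs.
#' @export
#' @examples
#' sim <- simulate_culture(chlorella_kinetics(), reactor_config(t_end = 14))
#' tail(sim)
simulate_culture <- function(params, config) {
  stopifnot(inherits(params, "kinetic_parameters"), inherits(config, "reactor_config"))
  y0 <- unclass(config$initial_state)[culture_variables()[1:5]]
  times <- config$output_grid
  prepend0 <- times[1] > 0
  if (prepend0) times <- c(0, times)

  rhs <- function(t, y, p) {
    d <- culture_derivatives(y, params, config, t = t)
    list(d[1:5])
  }
  sol <- deSolve::ode(
    y = y0, times = times, func = rhs, parms = NULL,
    method = "lsoda", rtol = config$rtol, atol = config$atol
  )
  if (attr(sol, "istate")[1] < 0) {
    abort(paste0(
      "culture integration failed near t = ",
      signif(max(sol[, "time"]), 5), " days (solver step-size collapse)"
    ))
  }
  out <- as_tibble(as.data.frame(unclass(sol)))
  if (prepend0) out <- out[-1, ]
  # clamp tolerance-level negative excursions
  out[c("X", "N", "P", "C", "O2")] <- lapply(out[c("X", "N", "P", "C", "O2")], pmax, 0)
  pH0 <- unclass(config$initial_state)[["pH"]]
  C0 <- y0[["C"]]
  out$pH <- pH0 - params$K_pH * (out$C - C0)
  structure(
    as_tibble(out),
    params = params, config = config,
    class = c("culture_simulation", class(tibble())))
}

#' Doubling time of exponential growth
#'
#' @param mu Specific growth rate (1/day), positive; vectorized.
#' @return Doubling time `ln(2) / mu` in days.
#' @export
#' @examples
#' doubling_time(0.61) # about 1.1 days
doubling_time <- function(mu) {
  if (any(mu <= 0)) abort("`mu` must be positive")
  log(2) / mu
}
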