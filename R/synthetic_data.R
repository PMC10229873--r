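# synthetic-data generators: noisy culture trajectories from the ODE model
# and replicate-level factorial tables from a quadratic truth. These stand in
# for the study's unpublished raw measurements and are labelled as synthetic
# in their metadata.

#' Observation-noise model for synthetic culture data
#'
#' @param kind `"multiplicative_gaussian"` (default; observation =
#'   truth * (1 + e), e ~ N(0, sd)) or `"additive_gaussian"` (truth + e,
#'   e ~ N(0, sd) in the variable's units). pH noise is always additive, in
#'   pH units, regardless of `kind`.
#' @param sd Noise scale: a fraction for multiplicative noise, absolute
#'   units for additive. Non-negative.
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG.
#' @param missingness Named per-variable probabilities of dropping an
#'   observation (NA), each in \[0, 1).
#' @return An object of class `noise_model`.
#' @export
#' @examples
#' noise_model(sd = 0.02, seed = 1)
noise_model <- function(kind = c("multiplicative_gaussian", "additive_gaussian"),
                        sd = 0.02, seed = NULL, missingness = NULL) {
  kind <- match.arg(kind)
  if (sd < 0) abort("`sd` must be non-negative")
  if (!is.null(missingness)) {
    if (is.null(names(missingness)) || any(missingness < 0 | missingness >= 1)) {
      abort("`missingness` must be named per-variable probabilities in [0, 1)")
    }
  }
  structure(list(kind = kind, sd = sd, seed = seed, missingness = missingness),
    class = "noise_model"
  )
}

#' Generate a noisy synthetic culture time series
#'
#' Simulates the culture model at the requested sampling times and corrupts
#' each variable with observation noise. The noiseless generating trajectory
#' and all generator settings are kept in the `truth` and `noise` attributes
#' so recovery studies can close the loop.
#'
#' @param params Generating [kinetic_parameters()].
#' @param config A [reactor_config()]; `sample_times` must lie within
#'   \[0, t_end\].
#' @param sample_times Observation times in days (default daily over the
#'   culture: 0 to `t_end` by 1).
#' @param noise A [noise_model()].
#' @return A tibble with `time` and the six state variables; attribute
#'   `truth` holds the noiseless values, attribute `meta` records the
#'   generator provenance (synthetic data, seed, noise kind and sd).
#' @export
#' @examples
#' ts <- generate_timeseries(chlorella_kinetics(), reactor_config(),
#'   noise = noise_model(sd = 0.02, seed = 7)
#' )
generate_timeseries <- function(params, config,
                                sample_times = seq(0, config$t_end, by = 1),
                                noise = noise_model()) {
  if (min(sample_times) < 0 || max(sample_times) > config$t_end) {
    abort("`sample_times` must lie within [0, t_end]")
  }
  config$output_grid <- sort(unique(sample_times))
  clean <- simulate_culture(params, config)

  out <- with_local_seed(noise$seed, function() {
    noisy <- clean
    n <- nrow(clean)
    for (v in culture_variables()) {
      if (noise$sd > 0) {
        e <- rnorm(n, 0, noise$sd)
        noisy[[v]] <- if (v == "pH" || noise$kind == "additive_gaussian") {
          clean[[v]] + e
        } else {
          clean[[v]] * (1 + e)
        }
        if (v != "pH") noisy[[v]] <- pmax(noisy[[v]], 0)
      }
      pmiss <- if (is.null(noise$missingness) || !v %in% names(noise$missingness)) {
        0
      } else {
        noise$missingness[[v]]
      }
      if (pmiss > 0) {
        drop <- runif(n) < pmiss
        noisy[[v]][drop] <- NA_real_
      }
    }
    noisy
  })

  structure(
    as_tibble(as.data.frame(out)),
    truth = as_tibble(as.data.frame(clean)),
    params = params, config = config, noise = noise,
    meta = list(
      origin = "synthetic (model-generated, not experimental)",
      seed = noise$seed, noise_kind = noise$kind, noise_sd = noise$sd
    )
  )
}

#' Generate a replicate-level factorial design table
#'
#' Full crossing of the CO2 and light levels with `reps` replicates per
#' cell; responses are the truth models' predictions plus Gaussian noise.
#' Negative draws are clamped to zero with a message.
#'
#' @param truth_biomass,truth_lipid `quadratic_model` objects supplying the
#'   noiseless response surfaces.
#' @param levels_A CO2 levels in percent (default the 3^2 design levels
#'   0.03, 10, 20).
#' @param levels_B Light levels in umol m-2 s-1 (default 13, 39, 65).
#' @param reps Replicates per cell (default 3).
#' @param noise_sd Named vector `c(biomass = , lipid = )` of response noise
#'   standard deviations (response units).
#' @param seed Integer seed.
#' @return A design tibble with columns `co2_pct`, `light_umol_m2_s`,
#'   `replicate`, `biomass_g_L`, `lipid_pct`; attribute `meta` records the
#'   synthetic provenance.
#' @export
#' @examples
#' d <- generate_factorial(reference_model("biomass"), reference_model("lipid"),
#'   noise_sd = c(biomass = 0, lipid = 0), seed = 1
#' )
#' nrow(d) # 27
generate_factorial <- function(truth_biomass, truth_lipid,
                               levels_A = c(0.03, 10, 20),
                               levels_B = c(13, 39, 65),
                               reps = 3,
                               noise_sd = c(biomass = 0.3, lipid = 4),
                               seed = NULL) {
  stopifnot(
    inherits(truth_biomass, "quadratic_model"),
    inherits(truth_lipid, "quadratic_model"), reps >= 1
  )
  grid <- tidyr::expand_grid(
    co2_pct = levels_A, light_umol_m2_s = levels_B,
    replicate = seq_len(reps)
  )
  mu_b <- predict_response(truth_biomass, grid$co2_pct, grid$light_umol_m2_s,
    warn_extrapolation = FALSE
  )
  mu_l <- predict_response(truth_lipid, grid$co2_pct, grid$light_umol_m2_s,
    warn_extrapolation = FALSE
  )
  out <- with_local_seed(seed, function() {
    grid$biomass_g_L <- mu_b + rnorm(nrow(grid), 0, noise_sd[["biomass"]])
    grid$lipid_pct <- mu_l + rnorm(nrow(grid), 0, noise_sd[["lipid"]])
    grid
  })
  n_clamped <- sum(out$biomass_g_L < 0) + sum(out$lipid_pct < 0)
  if (n_clamped > 0) {
    rlang::inform(paste0(n_clamped, " negative response draw(s) clamped to 0"))
  }
  out$biomass_g_L <- pmax(out$biomass_g_L, 0)
  out$lipid_pct <- pmax(out$lipid_pct, 0)
  structure(out, meta = list(
    origin = "synthetic (model-generated, not experimental)",
    seed = seed, noise_sd = noise_sd
  ))
}

#' Reconstitute replicate-level data from treatment means and SDs
#'
#' Draws `reps` pseudo-replicates per treatment cell from a seeded standard
#' normal, then shifts and rescales them so that each cell's sample mean and
#' sample standard deviation match the summary exactly. This gives ANOVA a
#' replicate-level error term consistent with published cell-level
#' dispersions when the raw replicates themselves are unavailable.
#'
#' @param summary Tibble as returned by [reference_design_summary()]:
#'   columns `treatment`, `light_umol_m2_s`, `co2_pct`, `biomass_g_L`,
#'   `biomass_sd`, `lipid_pct`, `lipid_sd`.
#' @param reps Replicates per cell (default 3, matching the 3^2 design).
#' @param seed Integer seed.
#' @return A replicate-level design tibble (same columns as
#'   [generate_factorial()]).
#' @export
#' @examples
#' d <- reconstitute_replicates(reference_design_summary(), seed = 1)
#' nrow(d) # 27
reconstitute_replicates <- function(summary, reps = 3, seed = NULL) {
  stopifnot(reps >= 2)
  match_moments <- function(z, m, s) {
    if (sd(z) == 0) z <- seq_along(z) # degenerate draw; any spread works
    m + s * (z - mean(z)) / sd(z)
  }
  with_local_seed(seed, function() {
    purrr::map_dfr(seq_len(nrow(summary)), function(i) {
      row <- summary[i, ]
      zb <- rnorm(reps)
      zl <- rnorm(reps)
      tibble(
        co2_pct = row$co2_pct,
        light_umol_m2_s = row$light_umol_m2_s,
        replicate = seq_len(reps),
        biomass_g_L = match_moments(zb, row$biomass_g_L, row$biomass_sd),
        lipid_pct = match_moments(zl, row$lipid_pct, row$lipid_sd)
      )
    })
  })
}
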