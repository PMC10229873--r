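# delimited-text readers/writers for culture time series, factorial design
# tables, and the structured YAML run configuration. Comma-delimited,
# dot-decimal, UTF-8, header required; units are declared in column-name
# suffixes (`_mg_L` vs `_g_L`) and converted to mg/L at parse time.

ts_column_pattern <- "^(X|N|P|C|O2)_(mg|g)_L$"

#' Read a culture time series from delimited text
#'
#' Expected header: `time_d` plus any of `X_mg_L, N_mg_L, P_mg_L, C_mg_L,
#' O2_mg_L, pH` (a `_g_L` suffix is accepted and converted to mg/L). Empty
#' cells become missing observations. Times must be strictly increasing and
#' concentrations non-negative; violations are reported with the offending
#' line number.
#'
#' @param path Path to a CSV file.
#' @return A tibble with `time` (days) and the present state variables in
#'   mg/L (pH unitless).
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE
  )
  if (!"time_d" %in% names(raw)) abort("missing required column `time_d`")
  out <- tibble(time = raw$time_d)
  for (nm in setdiff(names(raw), "time_d")) {
    if (nm == "pH") {
      out$pH <- raw$pH
    } else if (grepl(ts_column_pattern, nm)) {
      var <- sub("_(mg|g)_L$", "", nm)
      scale <- if (grepl("_g_L$", nm)) 1000 else 1
      out[[var]] <- raw[[nm]] * scale
    } else {
      abort(paste0("unknown column `", nm, "` in ", path))
    }
  }
  bad_t <- which(diff(out$time) <= 0)
  if (length(bad_t) > 0) {
    abort(paste0(
      "times must be strictly increasing; violation at line ",
      bad_t[1] + 2, " of ", path
    ))
  }
  for (v in intersect(c("X", "N", "P", "C", "O2"), names(out))) {
    bad <- which(out[[v]] < 0)
    if (length(bad) > 0) {
      abort(paste0(
        "negative concentration in column ", v, " at line ",
        bad[1] + 1, " of ", path
      ))
    }
  }
  out
}

#' Write a culture time series as delimited text
#'
#' Inverse of [read_timeseries()]: writes the canonical
#' `time_d,X_mg_L,...,pH` header with concentrations in mg/L.
#'
#' @param ts Tibble with `time` and state-variable columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  out <- tibble(time_d = ts$time)
  for (v in intersect(culture_variables(), names(ts))) {
    nm <- if (v == "pH") "pH" else paste0(v, "_mg_L")
    out[[nm]] <- ts[[v]]
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a replicate-level factorial design table
#'
#' Expected header: `co2_pct,light_umol_m2_s,replicate,biomass_g_L,lipid_pct`.
#' Validations: responses non-negative, lipid content at most 100%, factor
#' levels within the declared ranges, and no duplicated replicate index
#' within a treatment cell.
#'
#' @param path Path to a CSV file.
#' @param factor_ranges List with `A` (CO2 %) and `B` (light) ranges; rows
#'   outside them are rejected.
#' @return A design tibble.
#' @export
read_design <- function(path, factor_ranges = list(A = c(0.03, 20), B = c(13, 65))) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  d <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE
  )
  need <- c("co2_pct", "light_umol_m2_s", "replicate", "biomass_g_L", "lipid_pct")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    abort(paste0("missing design columns: ", paste(miss, collapse = ", ")))
  }
  if (any(d$lipid_pct > 100, na.rm = TRUE)) {
    abort("lipid_pct above 100% is not a valid mass fraction")
  }
  if (any(d$biomass_g_L < 0 | d$lipid_pct < 0, na.rm = TRUE)) {
    abort("responses must be non-negative")
  }
  if (any(d$co2_pct < factor_ranges$A[1] | d$co2_pct > factor_ranges$A[2])) {
    abort("co2_pct outside the declared factor range")
  }
  if (any(d$light_umol_m2_s < factor_ranges$B[1] | d$light_umol_m2_s > factor_ranges$B[2])) {
    abort("light_umol_m2_s outside the declared factor range")
  }
  dup <- d |>
    dplyr::count(.data$co2_pct, .data$light_umol_m2_s, .data$replicate) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("duplicated replicate index within a treatment cell")
  }
  d
}

#' Write a factorial design table as delimited text
#'
#' @param design Design tibble (see [read_design()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  cols <- c("co2_pct", "light_umol_m2_s", "replicate", "biomass_g_L", "lipid_pct")
  readr::write_csv(design[cols], path, na = "")
  invisible(path)
}

#' Read a structured culture-model configuration
#'
#' A YAML file with two blocks: `params` (fields of [kinetic_parameters()])
#' and `reactor` (fields of [reactor_config()], with `initial_state` as a
#' nested block of [culture_state()] fields). Missing keys take the package
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `params` (`kinetic_parameters`) and `config`
#'   (`reactor_config`).
#' @export
read_culture_config <- function(path) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  raw <- yaml::read_yaml(path)
  params <- do.call(kinetic_parameters, raw$params %||% list())
  reactor <- raw$reactor %||% list()
  if (!is.null(reactor$initial_state)) {
    reactor$initial_state <- do.call(culture_state, reactor$initial_state)
  }
  config <- do.call(reactor_config, reactor)
  list(params = params, config = config)
}

#' Write a culture-model configuration to YAML
#'
#' @param params A [kinetic_parameters()] object.
#' @param config A [reactor_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_culture_config <- function(params, config, path) {
  yaml::write_yaml(
    list(
      params = unclass(params),
      reactor = list(
        I0 = config$I0,
        attenuation_model = config$attenuation_model,
        photoperiod_fraction = config$photoperiod_fraction,
        initial_state = as.list(unclass(config$initial_state)),
        t_end = config$t_end,
        output_grid = config$output_grid,
        rtol = config$rtol, atol = config$atol
      )
    ),
    path
  )
  invisible(path)
}
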