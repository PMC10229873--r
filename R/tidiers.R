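# broom-style tidiers for the package's fitted objects

#' Tidy a quadratic response-surface model
#'
#' @param x A `quadratic_model`.
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `estimate`, `included`.
#' @export
tidy.quadratic_model <- function(x, ...) {
  terms <- c("(Intercept)", rsm_terms())
  tibble(
    term = terms,
    estimate = unname(x$coefficients[terms]),
    included = terms %in% c("(Intercept)", x$included_terms)
  )
}

#' @rdname tidy.quadratic_model
#' @return For `glance()`: a one-row tibble with `r.squared`, `sigma`,
#'   `df.residual`, `nobs`, `response`.
#' @export
glance.quadratic_model <- function(x, ...) {
  tibble(
    r.squared = x$r_squared, sigma = x$sigma,
    df.residual = x$df_residual, nobs = x$nobs,
    response = x$response
  )
}

#' Tidy a fitted culture model
#'
#' @param x A `culture_fit` from [fit_culture()].
#' @param ... Unused.
#' @return A tibble with one row per kinetic parameter: `parameter`,
#'   `estimate`, `free`.
#' @export
tidy.culture_fit <- function(x, ...) {
  tibble(
    parameter = names(x$params),
    estimate = unlist(x$params),
    free = names(x$params) %in% x$free
  )
}

#' @rdname tidy.culture_fit
#' @return For `glance()`: a one-row tibble with `sse`, `n_evaluations`,
#'   `converged`, `n_free` and the per-variable r-squared spread into
#'   `r2_<variable>` columns.
#' @export
glance.culture_fit <- function(x, ...) {
  out <- tibble(
    sse = x$sse, n_evaluations = x$n_evaluations,
    converged = x$converged, n_free = length(x$free)
  )
  r2 <- setNames(
    as.list(x$r_squared$r_squared),
    paste0("r2_", x$r_squared$variable)
  )
  dplyr::bind_cols(out, as_tibble(r2))
}

#' Tidy a desirability optimization result
#'
#' @param x A `desirability_result`.
#' @param ... Unused.
#' @return A tibble with one row per response: predicted value at the
#'   optimum plus the optimum coordinates and overall desirability.
#' @export
tidy.desirability_result <- function(x, ...) {
  dplyr::mutate(x$predictions,
    co2_pct = x$A, light_umol_m2_s = x$B, desirability = x$D
  )
}
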