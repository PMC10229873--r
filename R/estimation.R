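#' Sum-of-squares discrepancy between observed and predicted trajectories
#'
#' The estimation objective: the sum over state variables and observation
#' times of the (optionally weighted) squared difference between observed and
#' predicted values,
#' \deqn{SSE = \sum_{i} w_i \sum_t (y_i^{obs}(t) - y_i^{pred}(t))^2.}
#' Missing observations (NA cells) contribute nothing. The predicted series
#' must contain every observation time.
#'
#' All six variables enter unscaled by default, faithful to the original
#' objective; because the variables live on very different scales (nitrate in
#' hundreds of mg/L, dissolved CO2 below 1 mg/L), per-variable weights
#' (e.g. inverse observation variance) are recommended in practice — see the
#' `weights` argument of [fit_culture()].
#'
#' @param observed,predicted Tibbles with a `time` column and one column per
#'   state variable (any subset of X, N, P, C, O2, pH). `predicted` must be
#'   evaluated on (at least) the observation times.
#' @param weights Optional named per-variable positive scale factors;
#'   unnamed variables default to 1.
#' @return A non-negative scalar.
#' @export
#' @examples
#' obs <- tibble::tibble(time = 0:2, X = c(100, 150, 220))
#' pred <- tibble::tibble(time = 0:2, X = c(100, 160, 200))
#' sse_objective(obs, pred)
sse_objective <- function(observed, predicted, weights = NULL) {
  vars <- intersect(culture_variables(), names(observed))
  if (length(vars) == 0) abort("`observed` contains no state-variable columns")
  idx <- match(round(observed$time, 10), round(predicted$time, 10))
  if (anyNA(idx)) {
    abort(paste0(
      "observation times absent from the predicted grid: ",
      paste(signif(observed$time[is.na(idx)], 6), collapse = ", ")
    ))
  }
  w <- rep(1, length(vars))
  names(w) <- vars
  if (!is.null(weights)) {
    if (is.null(names(weights))) abort("`weights` must be a named vector")
    if (any(weights <= 0)) abort("`weights` must be positive")
    w[intersect(names(weights), vars)] <- weights[intersect(names(weights), vars)]
  }
  total <- 0
  for (v in vars) {
    if (!v %in% names(predicted)) abort(paste0("`predicted` lacks variable ", v))
    r <- observed[[v]] - predicted[[v]][idx]
    total <- total + w[[v]] * sum(r^2, na.rm = TRUE)
  }
  total
}

#' Per-variable goodness of fit (squared Pearson correlation)
#'
#' @param observed,predicted Tibbles as in [sse_objective()]. At least three
#'   paired non-missing points per variable are required; a variable with
#'   zero variance in either series gets `NA`.
#' @return A tibble with columns `variable`, `n` (paired points) and
#'   `r_squared`.
#' @export
goodness_of_fit <- function(observed, predicted) {
  vars <- intersect(culture_variables(), names(observed))
  idx <- match(round(observed$time, 10), round(predicted$time, 10))
  if (anyNA(idx)) abort("observation times absent from the predicted grid")
  purrr::map_dfr(vars, function(v) {
    o <- observed[[v]]
    p <- predicted[[v]][idx]
    keep <- !is.na(o) & !is.na(p)
    if (sum(keep) < 3) {
      abort(paste0("fewer than 3 paired observations for variable ", v))
    }
    r2 <- if (sd(o[keep]) == 0 || sd(p[keep]) == 0) {
      NA_real_
    } else {
      cor(o[keep], p[keep])^2
    }
    tibble(variable = v, n = sum(keep), r_squared = r2)
  })
}

# logistic box transform: unconstrained z <-> bounded p
box_to_z <- function(p, low, high) qlogis(pmin(pmax((p - low) / (high - low), 1e-12), 1 - 1e-12))
z_to_box <- function(z, low, high) low + (high - low) * plogis(z)

#' Fit kinetic parameters to culture observations
#'
#' Minimizes [sse_objective()] over a chosen subset of the kinetic
#' parameters by bounded derivative-free local search: Nelder-Mead simplex on
#' a logistic transform of the box constraints, restarted from `n_starts`
#' initial points drawn uniformly within the bounds. The best of the local
#' optima is returned; with a fixed `seed` the result is fully reproducible.
#'
#' @param data Tibble of observations: a `time` column (days) plus any subset
#'   of the state variables X, N, P, C, O2, pH (mg/L except pH); NA cells are
#'   skipped, not imputed.
#' @param free Character vector of parameter names to estimate (fields of
#'   [kinetic_parameters()]). Empty means "evaluate only": the fixed
#'   parameters are returned with their SSE.
#' @param bounds Named list of `c(low, high)` per free parameter.
#' @param params Fixed parameter values (defaults for everything not in
#'   `free`); defaults to [chlorella_kinetics()].
#' @param config A [reactor_config()]; its output grid is replaced by the
#'   observation times.
#' @param weights `"raw"` (all ones, the default), `"variance"` (inverse
#'   observation variance per variable), or a named numeric vector.
#' @param n_starts Number of multistart points (default 5).
#' @param seed Integer seed for the start draws.
#' @param maxit,reltol Per-start Nelder-Mead evaluation cap and relative
#'   convergence tolerance.
#' @return An object of class `culture_fit`: a list with elements `params`
#'   (fitted [kinetic_parameters()]), `sse`, `r_squared` (tibble from
#'   [goodness_of_fit()]), `n_evaluations`, `converged`, `free`, `starts`
#'   (tibble of start points and their final objective values) and `seed`.
#' @export
#' @examples
#' \donttest{
#' truth <- chlorella_kinetics()
#' cfg <- reactor_config(t_end = 14, output_grid = 0:14)
#' obs <- generate_timeseries(truth, cfg, sample_times = 0:14,
#'                            noise = noise_model(sd = 0))
#' fit <- fit_culture(obs, free = "mu_max", bounds = list(mu_max = c(0.1, 5)),
#'                    seed = 1)
#' fit$params$mu_max
#' }
fit_culture <- function(data, free = character(), bounds = NULL,
                        params = chlorella_kinetics(),
                        config = reactor_config(
                          t_end = max(data$time),
                          output_grid = sort(unique(data$time))
                        ),
                        weights = c("raw", "variance"),
                        n_starts = 5, seed = 1,
                        maxit = 2000, reltol = 1e-8) {
  stopifnot(is.data.frame(data), "time" %in% names(data))
  vars <- intersect(culture_variables(), names(data))
  if (length(vars) == 0) abort("`data` contains no state-variable columns")
  bad <- setdiff(free, names(params))
  if (length(bad) > 0) {
    abort(paste0("unknown free parameters: ", paste(bad, collapse = ", ")))
  }

  obs_times <- sort(unique(data$time))
  config$output_grid <- obs_times
  config$t_end <- max(config$t_end, max(obs_times))

  if (is.character(weights)) {
    weights <- match.arg(weights)
    w <- if (weights == "variance") {
      vapply(vars, function(v) {
        vv <- var(data[[v]], na.rm = TRUE)
        if (is.na(vv) || vv == 0) 1 else 1 / vv
      }, numeric(1))
    } else {
      setNames(rep(1, length(vars)), vars)
    }
  } else {
    w <- weights
  }

  n_obs <- sum(!is.na(as.matrix(data[vars])))
  if (length(free) > 0 && n_obs < length(free)) {
    abort("fewer observations than free parameters")
  }

  simulate_at <- function(p) {
    simulate_culture(p, config)
  }

  if (length(free) == 0) {
    pred <- simulate_at(params)
    return(structure(
      list(
        params = params, sse = sse_objective(data, pred, w),
        r_squared = goodness_of_fit(data, pred),
        n_evaluations = 1L, converged = TRUE,
        free = free, starts = tibble(), seed = seed
      ),
      class = "culture_fit"
    ))
  }

  if (is.null(bounds) || !all(free %in% names(bounds))) {
    abort("`bounds` must provide c(low, high) for every free parameter")
  }
  low <- vapply(bounds[free], `[`, numeric(1), 1)
  high <- vapply(bounds[free], `[`, numeric(1), 2)
  if (any(low >= high)) abort("each bound must satisfy low < high")
  p0 <- unlist(params[free])
  if (any(p0 < low | p0 > high)) {
    abort("default values of the free parameters violate their bounds")
  }

  n_eval <- 0L
  objective <- function(z) {
    n_eval <<- n_eval + 1L
    p <- params
    p[free] <- as.list(z_to_box(z, low, high))
    pred <- tryCatch(simulate_at(p), error = function(e) NULL)
    if (is.null(pred)) {
      return(1e12)
    }
    sse_objective(data, pred, w)
  }

  starts <- with_local_seed(seed, function() {
    matrix(runif(n_starts * length(free), low, high),
      nrow = n_starts, byrow = TRUE,
      dimnames = list(NULL, free)
    )
  })

  results <- purrr::map(seq_len(n_starts), function(i) {
    z0 <- box_to_z(starts[i, ], low, high)
    if (length(free) == 1) {
      # Nelder-Mead degenerates in 1-D; use Brent on the bounded scale
      o <- optim(starts[i, ],
        function(p) objective(box_to_z(p, low, high)),
        method = "Brent", lower = low, upper = high,
        control = list(maxit = maxit)
      )
      list(par = box_to_z(o$par, low, high), value = o$value, convergence = o$convergence)
    } else {
      o <- optim(z0, objective,
        method = "Nelder-Mead",
        control = list(maxit = maxit, reltol = reltol)
      )
      list(par = o$par, value = o$value, convergence = o$convergence)
    }
  })
  values <- vapply(results, `[[`, numeric(1), "value")
  best <- results[[which.min(values)]]
  fitted <- params
  fitted[free] <- as.list(z_to_box(best$par, low, high))
  fitted <- do.call(kinetic_parameters, fitted[names(kinetic_parameters())])
  pred <- simulate_at(fitted)

  structure(
    list(
      params = fitted,
      sse = sse_objective(data, pred, w),
      r_squared = goodness_of_fit(data, pred),
      n_evaluations = n_eval,
      converged = best$convergence == 0,
      free = free,
      starts = as_tibble(as.data.frame(starts)) |> dplyr::mutate(final_sse = values),
      seed = seed
    ),
    class = "culture_fit"
  )
}

#' @export
print.culture_fit <- function(x, ...) {
  cat("<culture_fit>\n")
  if (length(x$free) > 0) {
    cat("  free:", paste(x$free, collapse = ", "), "\n")
    for (f in x$free) cat("   ", f, "=", signif(x$params[[f]], 6), "\n")
  } else {
    cat("  no free parameters (evaluation only)\n")
  }
  cat("  SSE:", signif(x$sse, 6), " evaluations:", x$n_evaluations,
      " converged:", x$converged, "\n")
  print(x$r_squared)
  invisible(x)
}
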