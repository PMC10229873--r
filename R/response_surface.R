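# response-surface machinery for the 3^2 (CO2 x light) factorial:
# quadratic OLS in natural units, partial-SS ANOVA, single-pass alpha
# pruning, and Derringer-Suich desirability optimization.

rsm_terms <- function() c("A", "B", "AB", "AA", "BB")

# resolve a response argument to a design column
resolve_response <- function(design, response) {
  aliases <- c(
    biomass = "biomass_g_L", lipid = "lipid_pct",
    biomass_g_L = "biomass_g_L", lipid_pct = "lipid_pct"
  )
  col <- if (response %in% names(aliases)) aliases[[response]] else response
  if (!col %in% names(design)) {
    abort(paste0("response column `", col, "` not found in the design table"))
  }
  col
}

# model frame with the five polynomial regressors in natural factor units
rsm_frame <- function(design, response_col) {
  tibble(
    y = design[[response_col]],
    A = design$co2_pct,
    B = design$light_umol_m2_s,
    AB = design$co2_pct * design$light_umol_m2_s,
    AA = design$co2_pct^2,
    BB = design$light_umol_m2_s^2
  )
}

#' Fit a quadratic response surface to a two-factor factorial design
#'
#' Ordinary least squares for the second-order polynomial
#' \deqn{Y = \beta_0 + \beta_A A + \beta_B B + \beta_{AB} A B +
#'       \beta_{AA} A^2 + \beta_{BB} B^2}
#' in natural (uncoded) factor units, where `A` is CO2 content (%) and `B`
#' is light intensity (umol m-2 s-1). Any subset of the five non-intercept
#' terms may be included; excluded terms carry a coefficient of exactly 0.
#'
#' @param design Tibble with columns `co2_pct`, `light_umol_m2_s`,
#'   `replicate`, and the response columns `biomass_g_L` and/or `lipid_pct`
#'   (see [read_design()]).
#' @param response Response to fit: `"biomass"` (alias of `biomass_g_L`) or
#'   `"lipid"` (alias of `lipid_pct`), or a column name.
#' @param terms Character subset of `c("A", "B", "AB", "AA", "BB")`.
#' @param coded If `TRUE`, factors are first rescaled to coded -1..1 units
#'   (centre of the observed range at 0). Default `FALSE`: natural units.
#' @return An object of class `quadratic_model`: coefficients (all six,
#'   zeros for excluded terms), `included_terms`, `response`, `r_squared`,
#'   the residual degrees of freedom, and the data needed for [anova()].
#' @export
#' @examples
#' d <- reconstitute_replicates(reference_design_summary(), seed = 1)
#' m <- fit_quadratic(d, "biomass")
#' tidy(m)
fit_quadratic <- function(design, response, terms = rsm_terms(), coded = FALSE) {
  stopifnot(is.data.frame(design))
  terms <- match.arg(terms, rsm_terms(), several.ok = TRUE)
  col <- resolve_response(design, response)
  mf <- rsm_frame(design, col)
  if (coded) {
    code <- function(x) {
      r <- range(x)
      if (diff(r) == 0) abort("cannot code a constant factor")
      2 * (x - mean(r)) / diff(r)
    }
    A <- code(design$co2_pct)
    B <- code(design$light_umol_m2_s)
    mf <- tibble(y = mf$y, A = A, B = B, AB = A * B, AA = A^2, BB = B^2)
  }
  if (nrow(mf) < length(terms) + 2) {
    abort("need at least one more observation than fitted terms")
  }
  fml <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  fit <- lm(fml, data = mf)
  if (anyNA(coef(fit))) {
    abort("singular design: the requested terms are collinear")
  }
  beta <- setNames(numeric(6), c("(Intercept)", rsm_terms()))
  beta[names(coef(fit))] <- coef(fit)
  y <- mf$y
  ss_tot <- sum((y - mean(y))^2)
  ss_err <- sum(stats::residuals(fit)^2)
  structure(
    list(
      coefficients = beta,
      included_terms = terms,
      response = col,
      r_squared = if (ss_tot > 0) 1 - ss_err / ss_tot else NA_real_,
      df_residual = fit$df.residual,
      nobs = nrow(mf),
      sigma = sqrt(ss_err / max(fit$df.residual, 1)),
      coded = coded,
      factor_ranges = list(
        A = range(design$co2_pct),
        B = range(design$light_umol_m2_s)
      ),
      lm_fit = fit,
      frame = mf
    ),
    class = "quadratic_model"
  )
}

#' Construct a quadratic model directly from coefficients
#'
#' Builds a `quadratic_model` from known coefficient values, e.g. published
#' response-surface equations, so that [predict_response()] and
#' [desirability_optimize()] can use them without replicate-level data.
#'
#' @param coefficients Named numeric vector with `(Intercept)` and any of
#'   `A`, `B`, `AB`, `AA`, `BB`; missing terms are 0 and marked excluded.
#' @param response Response label.
#' @param factor_ranges List with elements `A`, `B` of `c(min, max)` giving
#'   the factor region the model is meant for.
#' @return A `quadratic_model` (without ANOVA support, as it holds no data).
#' @export
#' @examples
#' quadratic_model(c(`(Intercept)` = -0.645, A = 0.145, B = 0.113,
#'                   AB = -0.0022, BB = -0.00077), "biomass_g_L")
quadratic_model <- function(coefficients, response,
                            factor_ranges = list(A = c(0.03, 20), B = c(13, 65))) {
  beta <- setNames(numeric(6), c("(Intercept)", rsm_terms()))
  unknown <- setdiff(names(coefficients), names(beta))
  if (length(unknown) > 0) {
    abort(paste0("unknown terms: ", paste(unknown, collapse = ", ")))
  }
  beta[names(coefficients)] <- coefficients
  structure(
    list(
      coefficients = beta,
      included_terms = setdiff(names(coefficients), "(Intercept)"),
      response = response,
      r_squared = NA_real_,
      df_residual = NA_integer_,
      nobs = NA_integer_,
      sigma = NA_real_,
      coded = FALSE,
      factor_ranges = factor_ranges,
      lm_fit = NULL,
      frame = NULL
    ),
    class = "quadratic_model"
  )
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat("<quadratic_model> response:", x$response, "\n")
  cat("  terms:", paste(x$included_terms, collapse = ", "), "\n")
  b <- x$coefficients[c("(Intercept)", x$included_terms)]
  cat("  ", paste(names(b), signif(b, 5), sep = " = ", collapse = "; "), "\n")
  if (!is.na(x$r_squared)) cat("  R-squared:", round(x$r_squared, 4), "\n")
  invisible(x)
}

#' ANOVA for a fitted quadratic response surface
#'
#' Partial (Type III) sums of squares per model term: each single-degree-of-
#' freedom term's SS is the increase in residual SS that deleting the term
#' would cause, computed here from the OLS t statistic as
#' \eqn{SS_j = t_j^2 \times MS_{err}}. F is the term mean square over the
#' replicate-level error mean square, with p from the F distribution.
#'
#' @param object A `quadratic_model` from [fit_quadratic()].
#' @param ... Unused.
#' @return A tibble of class `rsm_anova` with columns `term`,
#'   `sum_of_squares`, `df`, `mean_square`, `F_value`, `p_value`; the last
#'   two rows are the error and corrected-total rows.
#' @export
anova.quadratic_model <- function(object, ...) {
  if (is.null(object$lm_fit)) {
    abort("this model was built from coefficients only; no data for ANOVA")
  }
  fit <- object$lm_fit
  if (fit$df.residual < 1) {
    abort("no residual degrees of freedom: replicate-level data required")
  }
  ss_err <- sum(stats::residuals(fit)^2)
  ms_err <- max(ss_err / fit$df.residual, .Machine$double.eps)
  # summary.lm warns on an essentially perfect fit; the degenerate case is
  # handled explicitly below
  tt <- suppressWarnings(summary(fit))$coefficients
  terms <- object$included_terms
  t2 <- (tt[terms, "Estimate"] / tt[terms, "Std. Error"])^2
  t2[is.nan(t2)] <- 0 # zero coefficient with zero residual variance
  ss <- t2 * ms_err
  y <- object$frame$y
  out <- tibble(
    term = c(terms, "error", "total"),
    sum_of_squares = c(ss, ss_err, sum((y - mean(y))^2)),
    df = c(rep(1L, length(terms)), fit$df.residual, length(y) - 1L),
    mean_square = c(ss, ms_err, NA_real_),
    F_value = c(t2, NA_real_, NA_real_),
    p_value = c(pf(t2, 1, fit$df.residual, lower.tail = FALSE), NA_real_, NA_real_)
  )
  class(out) <- c("rsm_anova", class(out))
  out
}

#' Which model terms fail a significance threshold
#'
#' The single-pass pruning rule: every term whose p-value exceeds `alpha` is
#' dropped, in one pass from the full model, without enforcing hierarchy (an
#' interaction may be kept while a quadratic term is dropped).
#'
#' @param p_values Named numeric vector of per-term p-values (names from
#'   `A`, `B`, `AB`, `AA`, `BB`), or an [anova.quadratic_model()] table.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of term names to drop (possibly empty).
#' @export
#' @examples
#' terms_to_drop(c(A = 0.0419, B = 1e-5, AA = 0.0914, AB = 9e-4, BB = 0.0311))
terms_to_drop <- function(p_values, alpha = 0.05) {
  if (is.data.frame(p_values)) {
    keep <- p_values$term %in% rsm_terms()
    p_values <- setNames(p_values$p_value[keep], p_values$term[keep])
  }
  # an undefined p-value (degenerate fit) gives no evidence to keep the term
  names(p_values)[is.na(p_values) | p_values > alpha]
}

#' Prune non-significant terms from the full quadratic model
#'
#' Fits the full five-term quadratic, runs the partial-SS ANOVA, removes in a
#' single pass every term with `p > alpha`, and refits with the surviving
#' terms.
#'
#' @inheritParams fit_quadratic
#' @param alpha Significance level for term retention (default 0.05).
#' @return The refitted, reduced `quadratic_model`; its `pruned` attribute
#'   lists the dropped terms. If every term is dropped, an intercept-only
#'   model is returned with a warning.
#' @export
#' @examples
#' d <- reconstitute_replicates(reference_design_summary(), seed = 1)
#' prune_terms(d, "biomass")
prune_terms <- function(design, response, alpha = 0.05) {
  full <- fit_quadratic(design, response, terms = rsm_terms())
  tab <- anova(full)
  drop <- terms_to_drop(tab, alpha)
  keep <- setdiff(rsm_terms(), drop)
  if (length(keep) == 0) {
    warn("all terms non-significant; returning intercept-only model")
    col <- resolve_response(design, response)
    out <- quadratic_model(
      c(`(Intercept)` = mean(design[[col]])),
      response = col,
      factor_ranges = list(
        A = range(design$co2_pct),
        B = range(design$light_umol_m2_s)
      )
    )
    out$included_terms <- character(0)
    attr(out, "pruned") <- drop
    return(out)
  }
  out <- fit_quadratic(design, response, terms = keep)
  attr(out, "pruned") <- drop
  out
}

#' Evaluate a quadratic response surface
#'
#' Polynomial evaluation with exactly the included terms. Points outside the
#' model's factor region are extrapolations and trigger a warning.
#'
#' @param model A `quadratic_model`.
#' @param A CO2 content (%); vectorized.
#' @param B Light intensity (umol m-2 s-1); vectorized.
#' @param warn_extrapolation Warn when (A, B) leaves the factor region.
#' @return Predicted response values.
#' @export
#' @examples
#' m <- reference_model("biomass")
#' predict_response(m, A = 20, B = 29.9)
predict_response <- function(model, A, B, warn_extrapolation = TRUE) {
  stopifnot(inherits(model, "quadratic_model"))
  if (model$coded) {
    abort("coded-unit models must be evaluated through predict() on a design table")
  }
  r <- model$factor_ranges
  if (warn_extrapolation &&
    (any(A < r$A[1] | A > r$A[2]) || any(B < r$B[1] | B > r$B[2]))) {
    warn("predicting outside the model's factor region (extrapolation)")
  }
  b <- model$coefficients
  b[["(Intercept)"]] + b[["A"]] * A + b[["B"]] * B +
    b[["AB"]] * A * B + b[["AA"]] * A^2 + b[["BB"]] * B^2
}

#' @export
predict.quadratic_model <- function(object, newdata, ...) {
  predict_response(object, A = newdata$co2_pct, B = newdata$light_umol_m2_s)
}

#' Validation error between a model prediction and an observation
#'
#' The relative deviation of an observed validation measurement from the
#' model's predicted value, as a whole-number percentage (rounded half away
#' from zero, matching how such tables are usually printed).
#'
#' @param predicted Model-predicted value (non-zero).
#' @param observed Observed value.
#' @return Integer percent error `round(100 * |predicted - observed| / predicted)`.
#' @export
#' @examples
#' validation_error(2.01, 1.66) # 17
validation_error <- function(predicted, observed) {
  if (any(predicted == 0)) abort("`predicted` must be non-zero")
  x <- 100 * abs(predicted - observed) / abs(predicted)
  # round half away from zero (x >= 0 here); snap away float fuzz first so a
  # value like 2.4999999999999996 (exactly 2.5 in real arithmetic) rounds up
  floor(round(x, 9) + 0.5)
}

#' Multi-response desirability optimization over the factor region
#'
#' Derringer-Suich desirability for simultaneous maximization of several
#' response surfaces. Each response is mapped to
#' \eqn{d_i = \mathrm{clamp}((\hat y_i - low_i)/(high_i - low_i), 0, 1)^{w_i}}
#' and the overall desirability is the geometric mean
#' \eqn{D = (\prod_i d_i)^{1/k}}. Anchors default to each model's predicted
#' minimum and maximum over the factor box. The maximizer is located by a
#' dense grid search (default step 0.05% CO2 by 0.1 umol m-2 s-1) followed by
#' a local polish; grid ties break toward smaller A, then smaller B.
#'
#' @param models Named list of `quadratic_model` objects (all maximized).
#' @param ranges List with elements `A`, `B` of `c(min, max)` bounding the
#'   search box.
#' @param weights Per-response desirability exponents (default 1).
#' @param anchors Optional named list of `c(low, high)` anchors per response.
#' @param grid_step Named vector `c(A = , B = )` of grid spacings.
#' @return An object of class `desirability_result`: optimum `A`, `B`,
#'   overall desirability `D`, per-response predictions at the optimum, the
#'   anchors used, and the best raw grid point.
#' @export
#' @examples
#' opt <- desirability_optimize(list(
#'   biomass = reference_model("biomass"),
#'   lipid = reference_model("lipid")
#' ))
#' c(opt$A, opt$B)
desirability_optimize <- function(models,
                                  ranges = list(A = c(0.03, 20), B = c(13, 65)),
                                  weights = NULL,
                                  anchors = NULL,
                                  grid_step = c(A = 0.05, B = 0.1)) {
  if (length(models) == 0) abort("`models` must contain at least one quadratic_model")
  stopifnot(all(vapply(models, inherits, logical(1), "quadratic_model")))
  if (is.null(names(models))) {
    names(models) <- vapply(models, `[[`, character(1), "response")
  }
  k <- length(models)
  w <- weights %||% setNames(rep(1, k), names(models))
  if (any(w <= 0)) abort("`weights` must be positive")

  A_grid <- unique(c(seq(ranges$A[1], ranges$A[2], by = grid_step[["A"]]), ranges$A[2]))
  B_grid <- unique(c(seq(ranges$B[1], ranges$B[2], by = grid_step[["B"]]), ranges$B[2]))
  # lexicographic order (A, then B) so which.max resolves ties toward
  # smaller A then smaller B
  grid <- tidyr::expand_grid(A = A_grid, B = B_grid)

  preds <- purrr::map(models, predict_response,
    A = grid$A, B = grid$B, warn_extrapolation = FALSE
  )
  if (is.null(anchors)) {
    # anchor at the surface's true extrema over the box: grid extrema
    # refined by a bounded local polish, so d = 1 is attainable exactly at
    # the response's own maximizer
    anchors <- purrr::map(names(models), function(nm) {
      m <- models[[nm]]
      obj <- function(p, s) {
        s * predict_response(m, p[1], p[2], warn_extrapolation = FALSE)
      }
      refine <- function(i0, s) {
        o <- optim(c(grid$A[i0], grid$B[i0]), obj,
          s = s, method = "L-BFGS-B",
          lower = c(ranges$A[1], ranges$B[1]),
          upper = c(ranges$A[2], ranges$B[2])
        )
        o$value * s
      }
      p <- preds[[nm]]
      c(
        low = min(min(p), refine(which.min(p), 1)),
        high = max(max(p), refine(which.max(p), -1))
      )
    })
    names(anchors) <- names(models)
  }
  for (nm in names(models)) {
    a <- anchors[[nm]]
    if (is.null(a) || a[1] >= a[2]) {
      abort(paste0("invalid anchors for response `", nm, "` (need low < high)"))
    }
  }

  desirability_at <- function(A, B) {
    d <- 1
    for (nm in names(models)) {
      yhat <- predict_response(models[[nm]], A, B, warn_extrapolation = FALSE)
      a <- anchors[[nm]]
      di <- pmin(pmax((yhat - a[[1]]) / (a[[2]] - a[[1]]), 0), 1)^w[[nm]]
      d <- d * di
    }
    d^(1 / k)
  }

  D_grid <- desirability_at(grid$A, grid$B)
  i_best <- which.max(D_grid)
  grid_best <- list(A = grid$A[i_best], B = grid$B[i_best], D = D_grid[i_best])

  polish <- optim(
    c(grid_best$A, grid_best$B),
    function(p) -desirability_at(p[1], p[2]),
    method = "L-BFGS-B",
    lower = c(ranges$A[1], ranges$B[1]),
    upper = c(ranges$A[2], ranges$B[2])
  )
  if (-polish$value >= grid_best$D) {
    A_opt <- polish$par[1]
    B_opt <- polish$par[2]
    D_opt <- -polish$value
  } else {
    A_opt <- grid_best$A
    B_opt <- grid_best$B
    D_opt <- grid_best$D
  }

  structure(
    list(
      A = A_opt, B = B_opt, D = D_opt,
      predictions = tibble(
        response = names(models),
        predicted = vapply(
          models, predict_response, numeric(1),
          A = A_opt, B = B_opt, warn_extrapolation = FALSE
        )
      ),
      anchors = anchors, weights = w,
      grid_best = grid_best, ranges = ranges, models = models
    ),
    class = "desirability_result"
  )
}

#' @export
print.desirability_result <- function(x, ...) {
  cat("<desirability_result>\n")
  cat(
    "  optimum: CO2 =", signif(x$A, 4), "%, light =", signif(x$B, 4),
    "umol m-2 s-1 (D =", signif(x$D, 4), ")\n"
  )
  print(x$predictions)
  invisible(x)
}
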