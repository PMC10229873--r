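# ggplot2 methods for the package's result types

#' Plot a simulated culture trajectory
#'
#' One panel per state variable (free y scales), time in days on the x axis.
#'
#' @param object A `culture_simulation` from [simulate_culture()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.culture_simulation <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object), -"time",
    names_to = "variable", values_to = "value"
  )
  long$variable <- factor(long$variable, levels = culture_variables())
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable), scales = "free_y") +
    ggplot2::labs(
      x = "time (d)", y = NULL,
      title = "Simulated batch culture trajectory"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a quadratic response surface as filled contours
#'
#' @param object A `quadratic_model`.
#' @param n Grid resolution per axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quadratic_model <- function(object, n = 80, ...) {
  r <- object$factor_ranges
  grid <- tidyr::expand_grid(
    co2_pct = seq(r$A[1], r$A[2], length.out = n),
    light_umol_m2_s = seq(r$B[1], r$B[2], length.out = n)
  )
  grid$response <- predict_response(object, grid$co2_pct, grid$light_umol_m2_s,
    warn_extrapolation = FALSE
  )
  ggplot2::ggplot(grid, ggplot2::aes(
    x = .data$co2_pct, y = .data$light_umol_m2_s, z = .data$response
  )) +
    ggplot2::geom_contour_filled() +
    ggplot2::labs(
      x = "CO2 (%)", y = "light (umol m-2 s-1)",
      fill = object$response,
      title = paste("Response surface:", object$response)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the overall desirability surface with its optimum
#'
#' @param object A `desirability_result` from [desirability_optimize()].
#' @param n Grid resolution per axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.desirability_result <- function(object, n = 80, ...) {
  r <- object$ranges
  grid <- tidyr::expand_grid(
    co2_pct = seq(r$A[1], r$A[2], length.out = n),
    light_umol_m2_s = seq(r$B[1], r$B[2], length.out = n)
  )
  k <- length(object$models)
  d <- rep(1, nrow(grid))
  for (nm in names(object$models)) {
    yhat <- predict_response(object$models[[nm]], grid$co2_pct,
      grid$light_umol_m2_s,
      warn_extrapolation = FALSE
    )
    a <- object$anchors[[nm]]
    d <- d * pmin(pmax((yhat - a[[1]]) / (a[[2]] - a[[1]]), 0), 1)^object$weights[[nm]]
  }
  grid$D <- d^(1 / k)
  ggplot2::ggplot(grid, ggplot2::aes(
    x = .data$co2_pct, y = .data$light_umol_m2_s
  )) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$D)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$D), colour = "white", alpha = 0.5) +
    ggplot2::annotate("point", x = object$A, y = object$B, colour = "red", size = 2) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(
      x = "CO2 (%)", y = "light (umol m-2 s-1)",
      title = "Overall desirability", fill = "D"
    ) +
    ggplot2::theme_minimal()
}
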