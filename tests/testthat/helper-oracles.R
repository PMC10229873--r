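# independent oracles, deliberately re-derived from the model equations
# rather than calling the package's right-hand side

# hand-coded RHS of the six-variable model (pH integrated as a state here,
# unlike the package, which reconstructs it algebraically)
oracle_rhs <- function(y, p, I0) {
  y <- pmax(y, 0)
  I <- I0 * (1 - p$alpha * y[1] / (p$K_IX + y[1]))
  mu <- p$mu_max * y[2] / (p$K_N + y[2]) * y[3] / (p$K_P + y[3]) *
    y[4] / (p$K_C + y[4]) * I / (p$K_I + I)
  dX <- (mu - p$mu_d) * y[1]
  dN <- -p$Y_NX * mu * y[1] - p$mu_mN * y[2]
  dP <- -p$Y_PX * mu * y[1] - p$mu_mP * y[3]
  dC <- -p$Y_CX * mu * y[1] + p$kla_C * (p$C_star_C - y[4]) - p$mu_mC * y[4]
  dO <- p$Y_O2X * mu * y[1] + p$kla_O2 * (p$C_star_O2 - y[5]) - p$mu_mO2 * y[5]
  c(dX, dN, dP, dC, dO, -p$K_pH * dC)
}

# fixed-step classical fourth-order Runge-Kutta on [0, max(t_out)]
rk4_oracle <- function(y0, p, I0, t_out, dt = 1e-3) {
  res <- matrix(NA_real_, length(t_out), 6,
    dimnames = list(NULL, c("X", "N", "P", "C", "O2", "pH"))
  )
  y <- y0
  i <- 1
  if (t_out[1] == 0) {
    res[1, ] <- y
    i <- 2
  }
  for (s in seq_len(round(max(t_out) / dt))) {
    k1 <- oracle_rhs(y, p, I0)
    k2 <- oracle_rhs(y + dt / 2 * k1, p, I0)
    k3 <- oracle_rhs(y + dt / 2 * k2, p, I0)
    k4 <- oracle_rhs(y + dt * k3, p, I0)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- s * dt
    while (i <= length(t_out) && abs(t - t_out[i]) < dt / 2) {
      res[i, ] <- y
      i <- i + 1
    }
  }
  res
}

# brute-force partial SS: increase in residual SS from deleting one term
# and refitting the reduced model
partial_ss_by_refit <- function(design, response, terms) {
  full <- fit_quadratic(design, response, terms = terms)
  sse <- function(m) sum(stats::residuals(m$lm_fit)^2)
  sse_full <- sse(full)
  vapply(terms, function(tm) {
    reduced <- fit_quadratic(design, response, terms = setdiff(terms, tm))
    sse(reduced) - sse_full
  }, numeric(1))
}

# exhaustive coarse-grid oracle for the overall desirability maximum
desirability_grid_oracle <- function(models, anchors, ranges, step = 0.5) {
  k <- length(models)
  best <- -Inf
  for (a in seq(ranges$A[1], ranges$A[2], by = step)) {
    for (b in seq(ranges$B[1], ranges$B[2], by = step)) {
      d <- 1
      for (nm in names(models)) {
        yhat <- predict_response(models[[nm]], a, b, warn_extrapolation = FALSE)
        an <- anchors[[nm]]
        d <- d * min(max((yhat - an[[1]]) / (an[[2]] - an[[1]]), 0), 1)
      }
      best <- max(best, d^(1 / k))
    }
  }
  best
}

# a 3x3x3 replicate-level null design grid (no response columns)
null_design_grid <- function(reps = 3) {
  tidyr::expand_grid(
    co2_pct = c(0.03, 10, 20), light_umol_m2_s = c(13, 39, 65),
    replicate = seq_len(reps)
  )
}
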