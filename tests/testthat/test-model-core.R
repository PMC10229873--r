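test_that("effective light reproduces the bounded-shading law", {
  # no biomass, no shading
  expect_equal(effective_light(X = 0, I0 = 29.9), 29.9)
  # at the biomass half-saturation point the shaded fraction is alpha/2
  expect_equal(effective_light(X = 1, I0 = 100, alpha = 0.5, K_IX = 1), 75.0)
  # dense-culture limit approaches the I0 * (1 - alpha) floor
  expect_equal(effective_light(X = 1e4, I0 = 29.9, alpha = 0.263, K_IX = 0.0252),
    22.04, tolerance = 1e-3
  )
  expect_error(effective_light(X = -1, I0 = 10), "non-negative")
  expect_error(effective_light(X = 1, I0 = -10), "non-negative")
})

test_that("attenuation models are non-negative; saturating forms are non-increasing", {
  X <- seq(0, 5000, length.out = 400)
  for (m in c("bounded_shading", "literal_eq", "available_fraction")) {
    I <- effective_light(X, I0 = 29.9, model = m)
    expect_true(all(I >= 0), info = m)
  }
  for (m in c("bounded_shading", "available_fraction")) {
    I <- effective_light(X, I0 = 29.9, model = m)
    expect_true(all(diff(I) <= 1e-12), info = m)
  }
  # the literal typeset form would go negative at low biomass with the
  # reference parameters (its shading factor starts near 10); it is clamped
  # to zero there and only recovers the 1 - alpha floor at high biomass
  expect_equal(effective_light(0, 29.9, model = "literal_eq"), 0)
  expect_equal(effective_light(1e5, 29.9, model = "literal_eq"),
    29.9 * (1 - 0.263),
    tolerance = 1e-4
  )
  expect_equal(effective_light(0, 29.9, model = "bounded_shading"), 29.9)
})

test_that("specific growth rate multiplies four Monod factors", {
  p <- chlorella_kinetics()
  # each factor at half saturation
  expect_equal(
    specific_growth_rate(p, N = p$K_N, P = p$K_P, C = p$K_C, I_eff = p$K_I),
    p$mu_max / 16
  )
  # any absent resource shuts growth off
  expect_equal(specific_growth_rate(p, N = 0, P = 1e6, C = 1e6, I_eff = 1e6), 0)
  expect_equal(specific_growth_rate(p, N = 1e6, P = 1e6, C = 0, I_eff = 1e6), 0)
  # reference scenario, hand arithmetic: 2.19 x 0.9551 x 0.9501 x 0.9854 x 0.2466
  expect_equal(
    specific_growth_rate(p, N = 670, P = 800, C = 0.81, I_eff = 22.04),
    0.483, tolerance = 1e-3
  )
  # saturation limit
  expect_lt(
    p$mu_max - specific_growth_rate(p, 1e9, 1e9, 1e9, 1e9),
    1e-5 * p$mu_max
  )
})

test_that("growth rate is non-decreasing in every resource", {
  p <- chlorella_kinetics()
  g <- seq(0, 1000, length.out = 50)
  base <- list(N = 300, P = 400, C = 0.5, I_eff = 25)
  for (v in names(base)) {
    args <- base
    mu <- vapply(g, function(x) {
      args[[v]] <- x
      do.call(specific_growth_rate, c(list(p), args))
    }, numeric(1))
    expect_true(all(diff(mu) >= -1e-14), info = v)
  }
})

test_that("mass-balance derivatives follow the model equations", {
  p <- chlorella_kinetics()
  cfg <- reactor_config()
  # no biomass: only maintenance decay
  d0 <- culture_derivatives(culture_state(X = 0, N = 100, P = 200), p, cfg)
  expect_equal(d0[["X"]], 0)
  expect_equal(d0[["N"]], -p$mu_mN * 100)
  expect_equal(d0[["P"]], -p$mu_mP * 200)
  # CO2 at equilibrium with no sinks: dC = 0, hence dpH = 0
  p2 <- chlorella_kinetics(mu_mC = 0)
  d1 <- culture_derivatives(culture_state(X = 50, N = 0, C = p2$C_star_C), p2, cfg)
  expect_equal(d1[["C"]], 0)
  expect_equal(d1[["pH"]], 0)
  # reference state: dX = (mu - mu_d) X with mu ~ 0.4829
  d2 <- culture_derivatives(
    culture_state(X = 100, N = 670, P = 800, C = 0.81, O2 = 6.0), p, cfg
  )
  expect_equal(d2[["X"]], 48.25, tolerance = 1e-3)
  # pH always moves opposite to carbon
  expect_equal(d2[["pH"]], -p$K_pH * d2[["C"]])
})

test_that("zero dynamics leave the state constant", {
  p <- chlorella_kinetics(
    mu_max = 0, mu_d = 0, mu_mP = 0, mu_mN = 0, mu_mC = 0,
    mu_mO2 = 0, kla_C = 0, kla_O2 = 0
  )
  cfg <- reactor_config(t_end = 10, output_grid = 0:10)
  sim <- simulate_culture(p, cfg)
  for (v in c("X", "N", "P", "C", "O2", "pH")) {
    expect_equal(sim[[v]], rep(sim[[v]][1], 11), tolerance = 1e-10, info = v)
  }
})

test_that("single-equation reduction recovers exponential growth", {
  p <- chlorella_kinetics(
    mu_d = 0, mu_mP = 0, mu_mN = 0, mu_mC = 0, mu_mO2 = 0,
    Y_PX = 0, Y_NX = 0, Y_CX = 0, Y_O2X = 0, kla_C = 0, kla_O2 = 0
  )
  cfg <- reactor_config(
    I0 = 1e9, t_end = 3, output_grid = seq(0, 3, by = 0.5),
    initial_state = culture_state(X = 100, N = 1e9, P = 1e9, C = 1e9, O2 = 6)
  )
  sim <- simulate_culture(p, cfg)
  expect_equal(sim$X, 100 * exp(p$mu_max * sim$time), tolerance = 1e-3)
})

test_that("reference-scenario trajectory stays non-negative with sensible shape", {
  sim <- simulate_culture(
    chlorella_kinetics(),
    reactor_config(t_end = 14, output_grid = 0:14)
  )
  expect_true(all(as.matrix(sim[c("X", "N", "P", "C", "O2")]) >= 0))
  # nitrate monotone decreasing; biomass non-decreasing until N exhaustion
  expect_true(all(diff(sim$N) < 0))
  expect_true(all(diff(sim$X)[sim$N[-1] > 1] > 0))
  # near-flat biomass once nitrogen is gone
  late <- which(sim$N < 0.01 * sim$N[1])
  expect_lt(
    abs(sim$X[15] - sim$X[late[1]]) / sim$X[15],
    0.05
  )
})

test_that("pH is an exact affine image of dissolved CO2", {
  p <- chlorella_kinetics()
  sim <- simulate_culture(p, reactor_config(t_end = 14, output_grid = 0:14))
  expect_equal(
    sim$pH - sim$pH[1],
    -p$K_pH * (sim$C - sim$C[1]),
    tolerance = 1e-12
  )
})

test_that("substrate consumption per biomass equals the yield with maintenance off", {
  p <- chlorella_kinetics(
    mu_d = 0, mu_mP = 0, mu_mN = 0, mu_mC = 0, mu_mO2 = 0,
    kla_C = 0, kla_O2 = 0
  )
  cfg <- reactor_config(t_end = 6, output_grid = seq(0, 6, by = 0.5))
  sim <- simulate_culture(p, cfg)
  grew <- sim$X > sim$X[1] * (1 + 1e-6)
  dX <- sim$X[grew] - sim$X[1]
  expect_equal((sim$N[1] - sim$N[grew]) / dX, rep(p$Y_NX, sum(grew)),
    tolerance = 1e-6
  )
  expect_equal((sim$P[1] - sim$P[grew]) / dX, rep(p$Y_PX, sum(grew)),
    tolerance = 1e-6
  )
})

test_that("doubling time is ln(2) over the growth rate", {
  expect_equal(signif(doubling_time(0.61), 2), 1.1)
  expect_equal(doubling_time(log(2)), 1.0)
  expect_equal(doubling_time(2.19), 0.3165, tolerance = 1e-4)
  expect_error(doubling_time(0), "positive")
  expect_error(doubling_time(-1), "positive")
})

test_that("configuration objects validate their inputs", {
  expect_error(reactor_config(I0 = -5), "non-negative")
  expect_error(reactor_config(t_end = 0), "positive")
  expect_error(reactor_config(output_grid = c(0, 2, 1)), "increasing")
  expect_error(reactor_config(t_end = 5, output_grid = c(0, 6)), "within")
  expect_error(culture_state(X = -1), "non-negative")
  expect_error(culture_state(pH = 15), "pH")
  expect_error(kinetic_parameters(mu_max = -1), "non-negative")
  expect_error(kinetic_parameters(alpha = 1.2), "alpha")
})
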