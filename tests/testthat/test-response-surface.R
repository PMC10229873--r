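test_that("noiseless quadratic data are recovered to machine precision", {
  grid <- null_design_grid()
  # published reduced biomass surface as the generating truth
  truth <- reference_model("biomass")
  grid$biomass_g_L <- predict_response(truth, grid$co2_pct, grid$light_umol_m2_s,
    warn_extrapolation = FALSE
  )
  m <- fit_quadratic(grid, "biomass", terms = truth$included_terms)
  expect_equal(m$coefficients, truth$coefficients, tolerance = 1e-10)

  # arbitrary full-quadratic coefficient vectors, full 3x3x3 grid
  set.seed(31)
  for (i in 1:5) {
    beta <- setNames(rnorm(6, sd = c(5, 1, 0.2, 0.05, 0.05, 0.01)),
                     c("(Intercept)", "A", "B", "AB", "AA", "BB"))
    gen <- quadratic_model(beta, "biomass_g_L")
    g <- grid
    g$biomass_g_L <- predict_response(gen, g$co2_pct, g$light_umol_m2_s,
      warn_extrapolation = FALSE
    )
    fit <- fit_quadratic(g, "biomass")
    expect_equal(fit$coefficients, beta[names(fit$coefficients)],
      tolerance = 1e-10
    )
  }
})

test_that("a constant response collapses onto the intercept", {
  grid <- null_design_grid()
  grid$biomass_g_L <- 3.2
  m <- fit_quadratic(grid, "biomass")
  expect_equal(unname(m$coefficients["(Intercept)"]), 3.2, tolerance = 1e-10)
  expect_equal(unname(m$coefficients[c("A", "B", "AB", "AA", "BB")]),
    rep(0, 5),
    tolerance = 1e-10
  )
})

test_that("coded-unit fitting reproduces the same fitted surface", {
  set.seed(5)
  grid <- null_design_grid()
  grid$biomass_g_L <- rnorm(nrow(grid), 2, 0.5)
  nat <- fit_quadratic(grid, "biomass")
  cod <- fit_quadratic(grid, "biomass", coded = TRUE)
  expect_equal(cod$r_squared, nat$r_squared, tolerance = 1e-10)
  expect_equal(
    stats::fitted(cod$lm_fit), stats::fitted(nat$lm_fit),
    tolerance = 1e-10
  )
})

test_that("partial sums of squares match the classical decomposition on a 2x2x3 design", {
  set.seed(77)
  d <- tidyr::expand_grid(
    co2_pct = c(5, 15), light_umol_m2_s = c(20, 60), replicate = 1:3
  )
  d$biomass_g_L <- rnorm(nrow(d), 2, 0.4)
  # coded units give the orthogonal +/-1 contrasts the classical cell-mean
  # decomposition assumes
  m <- fit_quadratic(d, "biomass", terms = c("A", "B", "AB"), coded = TRUE)
  tab <- anova(m)
  # brute-force sums over cell means for the balanced two-level layout
  cell <- dplyr::summarise(
    dplyr::group_by(d, co2_pct, light_umol_m2_s),
    m = mean(biomass_g_L), .groups = "drop"
  )
  grand <- mean(d$biomass_g_L)
  a_means <- tapply(d$biomass_g_L, d$co2_pct, mean)
  b_means <- tapply(d$biomass_g_L, d$light_umol_m2_s, mean)
  ss_a <- 6 * sum((a_means - grand)^2)
  ss_b <- 6 * sum((b_means - grand)^2)
  ss_ab <- 3 * sum((cell$m -
    a_means[as.character(cell$co2_pct)] -
    b_means[as.character(cell$light_umol_m2_s)] + grand)^2)
  got <- setNames(tab$sum_of_squares[1:3], tab$term[1:3])
  expect_equal(unname(got["A"]), ss_a, tolerance = 1e-8)
  expect_equal(unname(got["B"]), ss_b, tolerance = 1e-8)
  expect_equal(unname(got["AB"]), ss_ab, tolerance = 1e-8)
  # error SS from replicate scatter about cell means
  merged <- dplyr::left_join(d, cell, by = c("co2_pct", "light_umol_m2_s"))
  expect_equal(
    unname(tab$sum_of_squares[tab$term == "error"]),
    sum((merged$biomass_g_L - merged$m)^2),
    tolerance = 1e-8
  )
})

test_that("every term's partial SS equals its delete-and-refit SSE increase", {
  set.seed(19)
  grid <- null_design_grid()
  truth <- reference_model("biomass")
  grid$biomass_g_L <- pmax(
    predict_response(truth, grid$co2_pct, grid$light_umol_m2_s,
      warn_extrapolation = FALSE
    ) + rnorm(nrow(grid), 0, 0.4), 0
  )
  m <- fit_quadratic(grid, "biomass")
  tab <- anova(m)
  oracle <- partial_ss_by_refit(grid, "biomass", m$included_terms)
  got <- setNames(tab$sum_of_squares[seq_along(m$included_terms)], tab$term[seq_along(m$included_terms)])
  expect_equal(got[names(oracle)], oracle, tolerance = 1e-8)
})

test_that("a pure-signal response drives its term's p-value to zero without overflow", {
  grid <- null_design_grid()
  grid$biomass_g_L <- 0.1 * grid$co2_pct + 1
  m <- fit_quadratic(grid, "biomass", terms = c("A", "B", "AB"))
  tab <- anova(m)
  p_A <- tab$p_value[tab$term == "A"]
  expect_lt(p_A, 1e-12)
  expect_true(all(is.finite(tab$sum_of_squares)))
})

test_that("single-pass pruning drops exactly the non-significant terms", {
  # published ANOVA p-values: the biomass model loses only its CO2 quadratic,
  # the lipid model only its interaction
  expect_identical(terms_to_drop(reference_anova("biomass")), "AA")
  expect_identical(terms_to_drop(reference_anova("lipid")), "AB")
  # all significant: nothing dropped
  expect_identical(
    terms_to_drop(c(A = 0.01, B = 0.001, AB = 0.04, AA = 0.02, BB = 0.049)),
    character(0)
  )
  # undefined p-values count as non-significant
  expect_identical(terms_to_drop(c(A = NA_real_, B = 0.01)), "A")
})

test_that("prune_terms refits with the surviving terms and keeps zeros elsewhere", {
  set.seed(13)
  grid <- null_design_grid()
  truth <- reference_model("biomass") # has no AA term
  grid$biomass_g_L <- pmax(
    predict_response(truth, grid$co2_pct, grid$light_umol_m2_s,
      warn_extrapolation = FALSE
    ) + rnorm(nrow(grid), 0, 0.3), 0
  )
  m <- prune_terms(grid, "biomass")
  expect_true(all(m$coefficients[setdiff(c("A", "B", "AB", "AA", "BB"), m$included_terms)] == 0))
  expect_setequal(c(m$included_terms, attr(m, "pruned")), c("A", "B", "AB", "AA", "BB"))
  # an all-noise response prunes down to the intercept with a warning
  set.seed(101)
  for (s in 1:50) {
    grid$biomass_g_L <- rnorm(nrow(grid))
    full <- anova(fit_quadratic(grid, "biomass"))
    if (all(full$p_value > 0.05, na.rm = TRUE)) {
      expect_warning(m0 <- prune_terms(grid, "biomass"), "intercept-only")
      expect_length(m0$included_terms, 0)
      break
    }
  }
})

test_that("predictions evaluate the polynomial with exactly the included terms", {
  mb <- reference_model("biomass")
  ml <- reference_model("lipid")
  expect_equal(predict_response(mb, 0, 0, warn_extrapolation = FALSE), -0.645)
  # hand arithmetic: -0.645 + 0.00435 + 1.469 - 0.000858 - 0.13013
  expect_equal(predict_response(mb, 0.03, 13), 0.6974, tolerance = 1e-4)
  # hand arithmetic: 58.75 - 0.0363 - 23.92 + 0.000067 + 3.042
  expect_equal(predict_response(ml, 0.03, 13), 37.836, tolerance = 1e-4)
  expect_warning(predict_response(mb, 25, 13), "extrapolation")
  nd <- tibble::tibble(co2_pct = c(0.03, 20), light_umol_m2_s = c(13, 65))
  expect_equal(
    predict(mb, nd),
    predict_response(mb, nd$co2_pct, nd$light_umol_m2_s)
  )
})

test_that("validation error is a whole-number percent, half away from zero", {
  expect_equal(validation_error(2.01, 1.66), 17)
  expect_equal(validation_error(30.9, 32.8), 6)
  expect_equal(validation_error(0.62, 0.54), 13)
  expect_equal(validation_error(5, 5), 0)
  expect_equal(validation_error(2, 2.05), 3) # 2.5% rounds away from zero
  expect_error(validation_error(0, 1), "non-zero")
})

test_that("desirability reduces to the single response's maximizer", {
  m <- quadratic_model(c(`(Intercept)` = 0, A = 1, B = 0.02), "r")
  opt <- desirability_optimize(list(r = m))
  expect_equal(opt$A, 20, tolerance = 1e-6)
  expect_equal(opt$B, 65, tolerance = 1e-6)
  expect_equal(opt$D, 1, tolerance = 1e-9)
})

test_that("identical concave surfaces yield their common interior maximum", {
  beta <- c(`(Intercept)` = -(100 + 1521), A = 20, B = 78, AA = -1, BB = -1)
  m1 <- quadratic_model(beta, "r1")
  m2 <- quadratic_model(beta, "r2")
  opt <- desirability_optimize(list(r1 = m1, r2 = m2))
  expect_equal(opt$A, 10, tolerance = 1e-3)
  expect_equal(opt$B, 39, tolerance = 1e-3)
  expect_equal(opt$D, 1, tolerance = 1e-6)
})

test_that("desirability stays in [0,1] and the polish never loses to the grid", {
  m1 <- quadratic_model(c(`(Intercept)` = 0, A = 1, B = 0.02), "r1")
  m2 <- quadratic_model(c(`(Intercept)` = 25, A = -1, B = -0.02), "r2")
  opt <- desirability_optimize(list(r1 = m1, r2 = m2))
  expect_gte(opt$D, opt$grid_best$D)
  expect_true(opt$D >= 0 && opt$D <= 1)
  # the optimum dominates the box corners and centre
  corners <- rbind(c(0.03, 13), c(0.03, 65), c(20, 13), c(20, 65), c(10.015, 39))
  for (i in seq_len(nrow(corners))) {
    d <- 1
    for (nm in names(opt$models)) {
      yhat <- predict_response(opt$models[[nm]], corners[i, 1], corners[i, 2],
        warn_extrapolation = FALSE
      )
      a <- opt$anchors[[nm]]
      d <- d * min(max((yhat - a[[1]]) / (a[[2]] - a[[1]]), 0), 1)
    }
    expect_gte(opt$D + 1e-6, sqrt(d))
  }
  expect_error(desirability_optimize(list()), "at least one")
})

test_that("rsm tidiers report terms and fit summaries", {
  d <- reconstitute_replicates(reference_design_summary(), seed = 3)
  m <- fit_quadratic(d, "biomass")
  td <- tidy(m)
  expect_equal(nrow(td), 6)
  expect_true(all(td$included))
  gl <- glance(m)
  expect_equal(gl$nobs, 27)
  expect_true(gl$r.squared > 0 && gl$r.squared <= 1)
})
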