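test_that("constrained cubic self-fit recovers a feasible cubic exactly", {
  b_true <- feasible_cubic(c(7.44, -29.74, 37.17, -13.87))
  l <- seq(0.83, 1.33, by = 0.05)
  fit <- fit_active_lt_constrained(l, active_length_tension(l, b_true))
  expect_equal(fit$coefficients, as.numeric(b_true), tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("constrained cubic always satisfies its KKT conditions", {
  set.seed(42)
  for (k in 1:20) {
    l <- sort(runif(12, 0.7, 1.4))
    y <- 1 - 3 * (l - 1)^2 + rnorm(12, sd = 0.05)
    fit <- fit_active_lt_constrained(l, y)
    b <- fit$coefficients
    expect_lt(max(abs(fit$diagnostics$eq_residual)), 1e-8)
    expect_true(all(fit$diagnostics$ineq_slack >= -1e-8))
    expect_equal(active_length_tension(1, b), 1, tolerance = 1e-8)
    expect_equal(3 * b[1] + 2 * b[2] + b[3], 0, tolerance = 1e-8)
    # concave over the fitted range
    expect_true(all(6 * b[1] * range(l) + 2 * b[2] <= 1e-8))
  }
})

test_that("concavity constraints bind when the data demand convexity", {
  # convex data: unconstrained cubic would curve upward; the fit must not
  l <- seq(0.8, 1.2, by = 0.05)
  y <- 1 + 2 * (l - 1)^2
  fit <- fit_active_lt_constrained(l, y)
  b <- fit$coefficients
  expect_true(all(6 * b[1] * range(l) + 2 * b[2] <= 1e-8))
  expect_true(length(fit$diagnostics$active_set) >= 1)
})

test_that("force-frequency self-fit reproduces the published curve", {
  A <- c(1.55, 7.90, 0.33, 8.33)
  f <- seq(2, 38, by = 6)
  fit <- fit_force_frequency(f, force_frequency_response(f, A))
  grid <- seq(2, 38, by = 0.5)
  expect_lt(max(abs(force_frequency_response(grid, fit$coefficients) -
                      force_frequency_response(grid, A))), 1e-4)
})

test_that("degenerate saturated force-frequency data fit a flat curve", {
  f <- seq(2, 38, by = 6)
  fit <- fit_force_frequency(f, rep(1, length(f)))
  expect_true(all(abs(force_frequency_response(f, fit$coefficients) - 1) < 0.01))
})

test_that("passive exponential self-fit agrees in curve and threshold", {
  C <- c(-1.89, 1.70, 0.75, 0.55)
  l <- seq(0.87, 1.2, by = 0.02)
  fit <- fit_passive_lt(l, passive_length_tension(l, C, threshold = 0.87))
  grid <- seq(0.9, 1.2, by = 0.01)
  expect_lt(max(abs(passive_length_tension(grid, fit$coefficients, 0) -
                      passive_length_tension(grid, C, 0))), 1e-3)
  # zero crossing of the published branch sits at 0.8746
  expect_equal(fit$diagnostics$threshold, 0.8746, tolerance = 0.005)
})

test_that("all-zero passive data yield a flagged degenerate fit", {
  l <- seq(0.8, 1.2, by = 0.05)
  fit <- fit_passive_lt(l, rep(0, length(l)))
  expect_false(fit$converged)
  expect_true(isTRUE(fit$diagnostics$degenerate))
  expect_equal(fit$diagnostics$threshold, max(l))
})

test_that("piecewise hyperbola self-fit recovers each branch within 1 percent", {
  D <- c(-0.82, 0.07, 0.37, 0.01)
  v <- c(seq(-0.25, -0.01, by = 0.02), seq(0.01, 0.5, by = 0.02))
  fit <- fit_fv_piecewise(v, force_velocity(v, D))
  expect_lt(max(abs(fit$coefficients - D) / abs(D)), 0.01)
})

test_that("one-sided force-velocity data yield a flagged partial fit", {
  D <- c(-0.82, 0.07, 0.37, 0.01)
  v <- seq(0.01, 0.5, by = 0.02)
  fit <- fit_fv_piecewise(v, force_velocity(v, D))
  expect_false(fit$converged)
  expect_identical(fit$diagnostics$missing_branch, "lengthening")
  expect_true(all(is.na(fit$coefficients[3:4])))
  expect_lt(max(abs(fit$coefficients[1:2] - D[1:2]) / abs(D[1:2])), 0.01)
})

test_that("inverse force-velocity fit is monotone and isometric-consistent", {
  D <- c(-0.77, 0.07, 0.35, 0.07)
  v <- seq(-0.25, 0.5, by = 0.025)
  fv <- force_velocity(v, D)
  fit <- fit_inverse_fv(fv, v)
  E <- fit$coefficients
  # the double exponential cannot invert the printed hyperbolas below
  # ~0.025 max error over this range (verified global multistart optimum)
  expect_lt(max(abs(inverse_force_velocity(force_velocity(v, D), E) - v)), 0.03)
  r <- seq(min(fv), max(fv), by = 0.01)
  expect_true(all(diff(inverse_force_velocity(r, E)) < 0))
  expect_lt(abs(inverse_force_velocity(1, E)), 0.02)
})

test_that("series-elasticity length shift behaves at its limits", {
  expect_equal(shift_to_contractile_length(1.1, 0, 11.95), 1.1)
  expect_equal(shift_to_contractile_length(1.1, 0.5, 1e12), 1.1, tolerance = 1e-9)
  expect_equal(1.1 - shift_to_contractile_length(1.1, 0.5, 11.95), 0.0418,
               tolerance = 1e-3)
  expect_error(shift_to_contractile_length(1, 0.5, -1), "K_t")
})

test_that("activation fit rejects unexcited data and warns on rise-only data", {
  p <- truth_params()
  ex <- synthetic_experiments()
  quiet <- ex$ff[[5]]
  quiet$meta$stim_hz <- 0
  expect_error(fit_activation_parameters(p, list(quiet)), "excitation")

  rise_only <- ex$ff[[5]]
  keep <- rise_only$data$time_s <= rise_only$meta$stim_offset
  rise_only$data <- rise_only$data[keep, ]
  fit <- fit_activation_parameters(p, list(rise_only), maxit = 5, restarts = 0)
  expect_match(fit$diagnostics$warning, "identifiab")
})

test_that("every curve family refits its own sampled curve to high accuracy", {
  # self-fit property across the five families on published coefficient sets
  p <- truth_params()
  f <- seq(2, 38, by = 2)
  ff <- fit_force_frequency(f, force_frequency_response(f, p$A))
  expect_lt(sqrt(mean((force_frequency_response(f, ff$coefficients) -
                         force_frequency_response(f, p$A))^2)), 1e-3)
  l <- seq(0.85, 1.3, by = 0.025)
  bfeas <- feasible_cubic(p$B)
  bb <- fit_active_lt_constrained(l, active_length_tension(l, bfeas))
  expect_lt(sqrt(mean((active_length_tension(l, bb$coefficients) -
                         active_length_tension(l, bfeas))^2)), 1e-3)
  cc <- fit_passive_lt(l, passive_length_tension(l, p$C, 0.87))
  expect_lt(sqrt(mean((passive_length_tension(l, cc$coefficients,
                                              cc$diagnostics$threshold) -
                         passive_length_tension(l, p$C, 0.87))^2)), 2e-3)
  v <- seq(-0.25, 0.5, by = 0.025)
  dd <- fit_fv_piecewise(v, force_velocity(v, p$D))
  expect_lt(sqrt(mean((force_velocity(v, dd$coefficients) -
                         force_velocity(v, p$D))^2)), 1e-3)
  ee <- fit_inverse_fv(force_velocity(v, p$D), v)
  # family-capability limit of the double exponential, see the round-trip test
  expect_lt(sqrt(mean((inverse_force_velocity(force_velocity(v, p$D),
                                              ee$coefficients) - v)^2)), 0.015)
})
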