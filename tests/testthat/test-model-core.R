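# Frozen expected values below are hand evaluations of the published
# coefficient sets.

table2_A <- list(c(1.54, 7.97, 0.34, 8.40), c(2.90, 6.63, 0.27, 7.11),
                 c(1.55, 7.90, 0.33, 8.33), c(0.93, 7.06, 0.27, 6.83),
                 c(2.82, 6.70, 0.27, 7.17))
table2_D <- list(c(-0.79, 0.054, 0.49, 0.01), c(-0.77, 0.07, 0.35, 0.07),
                 c(-0.82, 0.07, 0.37, 0.01), c(-0.71, 0.06, 0.31, 0.04))

test_that("force-frequency sigmoid hits its hand-computed anchor points", {
  A <- c(1.55, 7.90, 0.33, 8.33)
  # exponent vanishes at f = A4, so the value is A1/(A1 + A2)
  expect_equal(force_frequency_response(8.33, A), 1.55 / 9.45, tolerance = 1e-12)
  expect_equal(force_frequency_response(38, A), 0.9997, tolerance = 1e-4)
  expect_equal(force_frequency_response(1e6, A), 1.0, tolerance = 1e-12)
  expect_error(force_frequency_response(-1, A), ">= 0")
  expect_error(force_frequency_response(10, c(1, NA, 1, 1)), "finite")
})

test_that("force-frequency response is monotone for every fitted cohort sigmoid", {
  f <- seq(0, 50, by = 0.25)
  for (A in table2_A) {
    expect_true(all(diff(force_frequency_response(f, A)) > 0))
  }
})

test_that("active length-tension cubic honors the printed constraint identities", {
  B <- c(7.44, -29.74, 37.17, -13.87)
  expect_equal(active_length_tension(1, B), 1.00, tolerance = 1e-9)
  expect_equal(3 * B[1] + 2 * B[2] + B[3], 0.01, tolerance = 1e-9)  # printed rounding
  Y <- c(5.44, -21.15, 25.16, -8.49)
  expect_equal(active_length_tension(1, Y), 0.96, tolerance = 1e-9)
  expect_error(active_length_tension(NA_real_, B), "finite")
})

test_that("passive length-tension is zero below threshold, clamped, increasing above", {
  C <- c(-1.89, 1.70, 0.75, 0.55)
  expect_identical(passive_length_tension(0.80, C), 0)
  # raw exponential branch is ~ -0.0065 at the threshold; clamped to zero
  expect_identical(passive_length_tension(0.87, C), 0)
  l <- seq(0.87, 1.4, by = 0.01)
  v <- passive_length_tension(l, C)
  expect_true(all(v >= 0))
  expect_true(all(diff(v[v > 0]) > 0))
  expect_equal(passive_length_tension(1, C), 0.1863847, tolerance = 1e-6)
})

test_that("force-velocity hyperbolas match anchors and are continuous at zero", {
  D <- c(-0.77, 0.07, 0.35, 0.07)
  # at v = D2 the shortening denominator is exactly 2
  expect_equal(force_velocity(0.07, D), 1 - 0.77 / 2, tolerance = 1e-12)
  expect_equal(force_velocity(-1e9, D), 1.35, tolerance = 1e-6)
  for (Dk in table2_D) {
    expect_equal(force_velocity(0, Dk), 1)
    expect_lt(abs(force_velocity(1e-9, Dk) - 1), 1e-6)
    expect_lt(abs(force_velocity(-1e-9, Dk) - 1), 1e-6)
  }
  expect_error(force_velocity(0.1, c(-0.77, -0.07, 0.35, 0.07)), "positive")
})

test_that("inverse force-velocity double exponential matches hand anchors", {
  E <- c(0.84, 6.37, 1.69, 1.36, -5.07)
  expect_lt(abs(inverse_force_velocity(1, E) - (-0.0018)), 1e-4)
  expect_equal(inverse_force_velocity(0, E), 1.36, tolerance = 1e-4)
  expect_equal(inverse_force_velocity(1.69, E), -0.8397, tolerance = 1e-3)
  # decreasing for the fitted sign pattern
  r <- seq(0, 1.8, by = 0.01)
  expect_true(all(diff(inverse_force_velocity(r, E)) < 0))
})

test_that("series elastic force is a linear spring with zero slack", {
  expect_identical(series_elastic_force(0, 11.95), 0)
  expect_equal(series_elastic_force(0.1, 11.95), 1.195)
  expect_equal(series_elastic_force(0.2, 11.95), 2 * series_elastic_force(0.1, 11.95))
  expect_error(series_elastic_force(0.1, 0), "positive")
})

test_that("activation dynamics derivative, fixed point and output scaling", {
  expect_equal(activation_derivative(0.3, 0, tau = 0.6, beta = 0.15),
               -0.15 * 0.3 / 0.6)
  expect_equal(activation_derivative(1, 1, tau = 0.6, beta = 0.15), 0)
  expect_equal(activation_derivative(0, 1, tau = 0.60, beta = 0.15),
               1 / 0.60, tolerance = 1e-12)
  # fixed point of the closed form equals the analytic steady state
  a_ss <- 0.5 / (0.15 + 0.85 * 0.5)
  expect_equal(activation_closed_form(1e4, 0.5, 0.6, 0.15, 0), a_ss)
  expect_equal(activation_output(0.74, 3.82, 0.74), 0)
  expect_equal(activation_output(1, 3.82, 0.74), 3.82 * 0.26, tolerance = 1e-12)
  expect_equal(activation_output(0.74 + 1.5 / 3.82, 3.82, 0.74), 1)
})

test_that("total muscle force assembles passive and series components", {
  p <- hill_parameters_i1i3()
  # slack series element at short length: zero force
  expect_equal(total_muscle_force(p, 0.8, 0.8), 0)
  # unstretched series element: passive only
  expect_equal(total_muscle_force(p, 1, 1), p$F_mto * 0.1863847,
               tolerance = 1e-6)
  # hand evaluation: f_PE(1) = 0.1863847, f_SEE = 11.95 * 0.05 = 0.5975
  expect_equal(total_muscle_force(p, 1, 0.95),
               1.61 * (0.1863847 + 0.5975), tolerance = 1e-6)
})

test_that("lab-frame velocity conversion is the single sign flip", {
  expect_equal(normalize_contractile_velocity(-2, 18.03), 2 / 18.03)
  expect_equal(normalize_contractile_velocity(8, 18.03), -8 / 18.03)
})

test_that("inverse force-velocity round-trips a freshly fitted inverse", {
  D <- c(-0.82, 0.07, 0.37, 0.01)
  v <- seq(-0.25, 0.5, by = 0.01)
  fv <- force_velocity(v, D)
  E <- fit_inverse_fv(fv, v)$coefficients
  rt <- inverse_force_velocity(force_velocity(v, D), E)
  resid_fit <- sqrt(mean((inverse_force_velocity(fv, E) - v)^2))
  expect_lt(max(abs(rt - v)), max(10 * resid_fit, 0.01))
})
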