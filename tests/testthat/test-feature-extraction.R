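# Extraction unit tests on hand-built traces (full control of the force
# channel), plus simulator-backed checks.

ff_meta <- list(protocol = "force_frequency", stim_hz = 26,
                stim_onset = 25, stim_offset = 30)

test_that("force-frequency extraction subtracts the baseline window", {
  t <- seq(0, 40, by = 0.01)
  # zero everywhere
  z <- manual_trace(t, rep(0, length(t)), meta = ff_meta)
  expect_equal(extract_ff_point(z)$F_CE_e, 0)
  # constant force cancels through baseline subtraction
  cst <- manual_trace(t, rep(3, length(t)), meta = ff_meta)
  expect_equal(extract_ff_point(cst)$F_CE_e, 0)
  # baseline + square pulse during stimulation is recovered exactly
  f <- 0.5 + ifelse(t >= 25 & t <= 30, 1.2, 0)
  sq <- manual_trace(t, f, meta = ff_meta)
  expect_equal(extract_ff_point(sq)$F_CE_e, 1.2, tolerance = 1e-9)
})

test_that("too little pre-stimulation data is a window error", {
  t <- seq(0, 40, by = 0.01)
  short <- manual_trace(t, rep(0, length(t)),
                        meta = utils::modifyList(ff_meta, list(stim_onset = 15,
                                                               stim_offset = 20)))
  expect_error(extract_ff_point(short), "pre-stimulation")
})

test_that("force-frequency normalization maps the peak to one", {
  pts <- data.frame(f_stim = c(2, 8, 14), F_CE_e = c(1, 2, 4))
  expect_equal(normalize_ff_series(pts)$u_f_e, c(0.25, 0.5, 1))
  one <- data.frame(f_stim = 26, F_CE_e = 0.7)
  expect_equal(normalize_ff_series(one)$u_f_e, 1)
  allz <- data.frame(f_stim = c(2, 8), F_CE_e = c(0, 0))
  expect_error(normalize_ff_series(allz), "degenerate")
})

test_that("length-tension two-pass normalization pins the peak at (1, 1)", {
  ex <- synthetic_experiments()
  pts <- extract_lt_points(ex$lt)
  i <- which.max(pts$LT_e)
  expect_equal(pts$l_mt_norm[i], 1)
  expect_equal(pts$LT_e[i], 1)
  expect_equal(nrow(pts), 10)  # conditioning episodes dropped
  # passive plateau with zero stimulation response
  p <- truth_params()
  t <- seq(0, 40, by = 0.01)
  f <- rep(0.4, length(t))
  tr <- manual_trace(t, f, length = rep(p$L_0 + 4, length(t)),
                     meta = list(protocol = "length_tension", stim_hz = 26,
                                 stim_onset = 25, stim_offset = 30))
  pt <- extract_lt_point(tr)
  expect_equal(pt$F_PE_e, 0.4)
  expect_equal(pt$F_CE_e, 0)
})

test_that("noiseless synthetic length-tension points land on the measurable curve", {
  p <- truth_params()
  ex <- synthetic_experiments()
  pts <- extract_lt_points(ex$lt)
  u26 <- force_frequency_response(26, p$A)
  oracle <- vapply(pts$L_mt, function(L) {
    isometric_steady_state(p, L / p$L_mto, u26)$f_ce
  }, numeric(1))
  oracle <- oracle / max(oracle)
  expect_lt(max(abs(pts$LT_e - oracle)), 0.03)
})

test_that("quartic force-rise slope is exact for polynomial force histories", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  meta_a <- list(t_a_start = 4, t_a_end = 6, fs = fs, V_mt = 1)
  meta_p <- list(t_p_start = 1, t_p_end = 3, fs = fs, V_mt = 1)
  L <- function(tt, t0) 16 + pmin(pmax(tt - t0, 0), 2)  # 1 mm/s ramp
  # passive force proportional to length; active adds a quartic in ramp time
  passive_f <- 0.1 * L(t, 1)
  quart <- function(s) 0.3 * s^4 - 0.2 * s^3 + 0.5 * s^2 + 0.8 * s + 2
  active_f <- 0.1 * L(t, 4) + ifelse(t >= 4 & t <= 6, quart(t - 4), 0)
  pas <- manual_trace(t, passive_f, length = L(t, 1), meta = meta_p)
  act <- manual_trace(t, active_f, length = L(t, 4), meta = meta_a)
  rise <- active_force_rise_slope(act, pas, eval_time = 6)
  s <- 2
  expect_equal(rise$slope, 4 * 0.3 * s^3 + 3 * (-0.2) * s^2 + 2 * 0.5 * s + 0.8,
               tolerance = 1e-6)
  expect_equal(rise$G, c(0.3, -0.2, 0.5, 0.8, 2), tolerance = 1e-6)

  # linear active force returns its slope
  lin_f <- 0.1 * L(t, 4) + ifelse(t >= 4 & t <= 6, 1.5 * (t - 4), 0)
  act2 <- manual_trace(t, lin_f, length = L(t, 4), meta = meta_a)
  expect_equal(active_force_rise_slope(act2, pas, eval_time = 5)$slope, 1.5,
               tolerance = 1e-8)
})

test_that("passive matching is by length even when ramp clocks differ", {
  fs <- 200
  t <- seq(0, 20, by = 1 / fs)
  # passive ramp runs 2-4 s, active ramp runs 11-13 s: same lengths, shifted times
  Lp <- 16 + pmin(pmax(t - 2, 0), 2)
  La <- 16 + pmin(pmax(t - 11, 0), 2)
  pas <- manual_trace(t, 0.25 * Lp, length = Lp,
                      meta = list(t_p_start = 2, t_p_end = 4, fs = fs, V_mt = 1))
  act <- manual_trace(t, 0.25 * La + ifelse(t >= 11 & t <= 13, 2 * (t - 11), 0),
                      length = La,
                      meta = list(t_a_start = 11, t_a_end = 13, fs = fs, V_mt = 1))
  # length-matched subtraction leaves the pure 2 N/s active rise
  expect_equal(active_force_rise_slope(act, pas, eval_time = 12)$slope, 2,
               tolerance = 1e-8)
})

test_that("an isometric 'ramp' yields the degenerate force-velocity point", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  L <- rep(16, length(t))
  f <- ifelse(t >= 4, 1.0, 0) + 0.2
  tr <- manual_trace(t, f, length = L,
                     meta = list(t_p_start = 1, t_p_end = 2, t_a_start = 5,
                                 t_a_end = 6, fs = fs, V_mt = 0))
  B <- c(7.44, -29.74, 37.17, -13.87)
  pt <- extract_fv_point(tr, tr, B = B, K_t = 11.95, L_mto = 16)
  expect_equal(pt$fv, 1, tolerance = 1e-6)
  expect_equal(pt$v_m_norm, 0, tolerance = 1e-6)
})

test_that("mismatched ramp velocities are a pairing error", {
  fs <- 100
  t <- seq(0, 5, by = 1 / fs)
  a <- manual_trace(t, t, meta = list(t_a_start = 1, t_a_end = 2,
                                      t_p_start = 0, t_p_end = 1,
                                      fs = fs, V_mt = 1))
  b <- manual_trace(t, t, meta = list(t_a_start = 1, t_a_end = 2,
                                      t_p_start = 0, t_p_end = 1,
                                      fs = fs, V_mt = 2))
  expect_error(extract_fv_point(a, b, B = c(0, 0, 0, 1), K_t = 10, L_mto = 16),
               "pairing")
})

test_that("lengthening episodes always enhance force above isometric", {
  p <- truth_params()
  fit <- pipeline_fit()
  pts <- fit$points$fv
  expect_true(all(pts$fv[pts$V_mt > 0] >= 1 - 0.02))
})

test_that("stiffness regression recovers an exact line and flags degeneracy", {
  K <- 9.3
  F_mto <- 1.5
  L_mto <- 18
  V <- c(-2, 1)
  pts <- data.frame(V_mt = V, dFCE_dt = K * F_mto / L_mto * V)
  est <- estimate_series_stiffness(pts, F_mto, L_mto)
  expect_equal(est$K_t, K, tolerance = 1e-9)
  expect_equal(est$intercept, 0, tolerance = 1e-9)
  same <- data.frame(V_mt = c(1, 1), dFCE_dt = c(0.5, 0.6))
  expect_error(estimate_series_stiffness(same, F_mto, L_mto), "rank-deficient")
  # intercept is reported, not constrained
  off <- data.frame(V_mt = c(-1, 0, 1), dFCE_dt = c(-0.8, 0.3, 1.4))
  expect_equal(estimate_series_stiffness(off, F_mto, L_mto)$intercept, 0.3,
               tolerance = 1e-9)
})

test_that("series stiffness is recovered from the synthetic isokinetic protocol", {
  fit <- pipeline_fit()
  expect_lt(abs(fit$fits$K_t$K_t - 11.95) / 11.95, 0.10)
  expect_gt(fit$fits$K_t$r_squared, 0.99)
})
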