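# EMG-driven validation and cohort summary statistics.

#' Upper envelope of a rectified EMG signal
#'
#' Full-wave rectifies the signal, normalizes by the maximum, and
#' constructs the upper envelope by linear interpolation across local
#' peaks separated by at least `min_separation` samples.  Additional knots
#' are inserted wherever the interpolant would dip below the rectified
#' signal, so the returned envelope is an upper bound of the normalized
#' rectified signal at every sample.
#'
#' The separation is kept in samples (at the 5 kHz rig rate the default of
#' 1000 samples is 0.2 s); choose it to exceed the carrier period but stay
#' below the burst spacing.
#'
#' @param signal Numeric EMG samples.
#' @param min_separation Minimum peak separation in samples.
#' @return List with `envelope` (normalized, peak 1), `rectified`
#'   (normalized rectified signal), `peaks` (knot indices), `scale`
#'   (`NA`; filled by [fit_emg_scale()]) and `shift_s` (0; alignment is
#'   reported, never silently applied).
#' @export
emg_envelope <- function(signal, min_separation = 1000) {
  n <- length(signal)
  if (n <= 2 * min_separation) {
    stop("signal too short for the requested peak separation")
  }
  rect <- abs(signal)
  mx <- max(rect)
  if (mx == 0) {
    warning("all-zero signal: returning a zero envelope")
    return(list(envelope = rect, rectified = rect, peaks = integer(0),
                scale = NA_real_, shift_s = 0))
  }
  rect <- rect / mx
  pk <- pracma::findpeaks(rect, minpeakdistance = as.integer(min_separation))
  knots <- sort(unique(c(1L, if (!is.null(pk)) as.integer(pk[, 2]), n)))
  repeat {
    env <- stats::approx(knots, rect[knots], xout = seq_len(n),
                         method = "linear", rule = 2)$y
    viol <- which(rect > env + 1e-9)
    if (length(viol) == 0L) break
    knots <- sort(unique(c(knots, viol[which.max(rect[viol] - env[viol])])))
  }
  list(envelope = env, rectified = rect, peaks = knots,
       scale = NA_real_, shift_s = 0)
}

#' Fit the EMG-to-drive scale factor
#'
#' The normalized EMG envelope, multiplied by a scalar, is used as the
#' stimulation-frequency input to the muscle model; the scale is chosen to
#' minimize the mean squared error between the simulated and measured
#' force (golden-section search over a bounded interval).  The residual
#' lead/lag between simulated and measured force is estimated by
#' cross-correlation and reported; it is never silently applied.
#'
#' @param params A [hill_parameters()] object.
#' @param envelope Data frame with columns `time_s` and `value` (normalized
#'   envelope, peak 1).
#' @param length_trajectory Data frame `time_s`, `length_mm` for the
#'   simulation.
#' @param measured_force Data frame `time_s`, `force_N`.
#' @param interval Search interval for the scale (Hz per unit envelope).
#' @param dt_out Simulation reporting interval (s).
#' @return List with `scale`, `mse`, `sim` (the simulated trace at the
#'   fitted scale), and `shift_s` (positive when the simulation leads the
#'   measurement).
#' @export
fit_emg_scale <- function(params, envelope, length_trajectory, measured_force,
                          interval = c(0.5, 200), dt_out = 0.02) {
  if (max(envelope$value) <= 0) {
    warning("zero envelope: scale is irrelevant")
    return(list(scale = NA_real_, mse = NA_real_, sim = NULL, shift_s = 0,
                degenerate = TRUE))
  }
  t0 <- max(min(envelope$time_s), min(measured_force$time_s))
  t1 <- min(max(envelope$time_s), max(measured_force$time_s))
  if (t1 <= t0) stop("envelope and measured force share no time span")
  f_meas <- stats::approxfun(measured_force$time_s, measured_force$force_N,
                             rule = 2)
  run <- function(scale) {
    drv <- drive_signal(envelope$time_s, scale * envelope$value,
                        mode = "frequency")
    simulate_episode(params, drv, length_trajectory, t_end = t1,
                     dt_out = dt_out)
  }
  mse_of <- function(scale) {
    sim <- run(scale)
    keep <- sim$time_s >= t0
    mean((sim$force_N[keep] - f_meas(sim$time_s[keep]))^2)
  }
  opt <- stats::optimize(mse_of, interval = interval)
  if (!is.finite(opt$objective)) stop("non-finite MSE in the EMG scale search")
  sim <- run(opt$minimum)
  # report (not apply) the residual lead of the simulation over the data
  meas <- f_meas(sim$time_s)
  a <- sim$force_N - mean(sim$force_N)
  b <- meas - mean(meas)
  cc <- stats::ccf(a, b, lag.max = min(length(a) - 1, round(5 / dt_out)),
                   plot = FALSE)
  shift_s <- cc$lag[which.max(cc$acf)] * dt_out
  list(scale = opt$minimum, mse = opt$objective, sim = sim, shift_s = shift_s)
}

#' One-sample two-sided t-test from summary statistics
#'
#' @param mean Sample mean.
#' @param sd Sample standard deviation (n - 1 denominator), > 0.
#' @param n Sample size, >= 2.
#' @param mu0 Reference value under the null hypothesis.
#' @return List with `t`, `df` and two-sided `p`.
#' @export
one_sample_t_test <- function(mean, sd, n, mu0) {
  if (n < 2) stop("need n >= 2")
  if (!is.finite(sd) || sd <= 0) stop("degenerate test: sd must be > 0")
  t <- (mean - mu0) / (sd / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  list(t = t, df = n - 1, p = p)
}

#' Summarize a cohort parameter and compare to a reference value
#'
#' Sample mean and standard deviation (n - 1 denominator) of the
#' per-animal values plus a one-sample two-sided t-test against a
#' reference value from another muscle.
#'
#' @param values Per-animal parameter values (>= 2).
#' @param reference Reference value.
#' @return A `cohort_summary` list with `mean`, `sd`, `n`, `reference`,
#'   `t`, `p`.
#' @export
summarize_cohort <- function(values, reference) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  tt <- one_sample_t_test(m, s, length(values), reference)
  structure(list(mean = m, sd = s, n = length(values),
                 reference = reference, t = tt$t, p = tt$p),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("%.4g +/- %.4g (n = %d) vs reference %.4g: t = %.3f, p = %.4g\n",
              x$mean, x$sd, x$n, x$reference, x$t, x$p))
  invisible(x)
}
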