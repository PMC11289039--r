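# Forward simulation of the muscle: the coupled ODEs for the activation
# state a'(t) and the normalized contractile-element length, integrated with
# an adaptive solver (deSolve::lsoda).  The contractile-element velocity is
# obtained by inverting the force-velocity relationship at the force carried
# by the series elastic element.

#' Construct a neural drive signal
#'
#' A sampled drive for [simulate_episode()].  In `"frequency"` mode the
#' values are stimulation frequencies in Hz and are mapped through the
#' force-frequency sigmoid; in `"drive"` mode the values are already a
#' normalized drive `u_f` in \[0, 1\].  The signal is zero-order-hold
#' interpolated during integration (a stimulation frequency is a held
#' value, not a ramp).
#'
#' @param time Sample times (s), strictly increasing.
#' @param value Non-negative drive values (Hz or dimensionless).
#' @param mode `"frequency"` or `"drive"`.
#' @return A `drive_signal` object.
#' @export
drive_signal <- function(time, value, mode = c("frequency", "drive")) {
  mode <- match.arg(mode)
  if (length(time) != length(value)) stop("time and value must have equal length")
  if (length(time) < 1L) stop("drive signal must contain at least one sample")
  if (any(diff(time) <= 0)) stop("drive time must be strictly increasing")
  if (any(!is.finite(value)) || any(value < 0)) stop("drive values must be finite and >= 0")
  if (mode == "drive" && any(value > 1)) stop("drive values must be <= 1 in 'drive' mode")
  structure(list(time = as.numeric(time), value = as.numeric(value), mode = mode),
            class = "drive_signal")
}

# Internal: guard constants for the algebraic force-velocity inversion.
.sim_guards <- function(params) {
  list(
    eps_a = 1e-6,      # activation floor / slack switch
    lt_floor = 1e-3,   # floor on the active LT multiplier
    v_len_cap = 20,    # L_mto/s, lengthening velocity cap (overflow guard)
    k_track = 50       # 1/s, slack CE tracking rate
  )
}

#' Contractile-element velocity from the series-elastic equilibrium
#'
#' Computes the force ratio carried by the contractile element,
#' `r = f_SEE / (a * LT(l_m))`, with guards making the inversion total:
#' the activation and length-tension factors are floored, `r` is clamped
#' below at 0 (the series element cannot push), and the inverted
#' lengthening velocity is capped at 20 optimal lengths per second purely
#' as an overflow guard.  The inverse force-velocity double exponential is
#' finite and monotone beyond the lengthening asymptote of the hyperbolic
#' force-velocity fit, so force ratios above `1 + D3` — which fast
#' lengthening transiently produces — invert smoothly.
#'
#' @param params A [hill_parameters()] object.
#' @param a Activation in \[0, 1\].
#' @param l_m_norm Normalized contractile-element length.
#' @param l_mt_norm Normalized total muscle length.
#' @return Normalized contractile velocity (shortening positive).
#' @export
contractile_velocity <- function(params, a, l_m_norm, l_mt_norm) {
  gd <- .sim_guards(params)
  f_see <- params$K_t * (l_mt_norm - l_m_norm)
  lt <- pmax(active_length_tension(l_m_norm, params$Y), gd$lt_floor)
  r <- pmax(f_see / (pmax(a, gd$eps_a) * lt), 0)
  pmax(inverse_force_velocity(r, params$E), -gd$v_len_cap)
}

#' Simulate one episode of muscle force generation
#'
#' Integrates the activation state and the contractile-element length under
#' an imposed length trajectory and a neural drive, and returns the force
#' trace.  Integration uses an adaptive solver with a 50 ms maximum step by
#' default; the length trajectory is linearly interpolated and the drive is
#' held between samples.
#'
#' When the activation is effectively zero the contractile element is slack
#' and cannot sustain series-elastic stretch at any rate the inverse
#' force-velocity fit can express, so the contractile-element length tracks
#' the imposed length directly (with a fast first-order pull-in of any
#' residual stretch).  This keeps passive episodes exactly force-free in
#' the series element; see the package vignette for the rationale.
#'
#' @param params A [hill_parameters()] object.
#' @param drive A [drive_signal()] object.
#' @param length_trajectory Data frame with columns `time_s` and
#'   `length_mm` (lab frame, piecewise linear).
#' @param t_end End of the simulation (s); defaults to the end of the
#'   length trajectory.
#' @param dt_out Reporting interval of the output trace (s).
#' @param initial_state Optional list with `a_prime` and `l_m_norm`;
#'   defaults to `a_prime = a0` (zero activation) and an unstretched series
#'   element (`l_m = l_mt(0)`).
#' @param hmax Maximum integrator step (s).
#' @param rtol,atol Relative and absolute integration tolerances.
#' @return A data frame of class `muscle_simulation` with columns
#'   `time_s`, `force_N`, `activation`, `a_prime`, `l_m_norm`, `f_pe`,
#'   `f_see`.  The force satisfies
#'   `force_N = F_mto * (f_pe + f_see)` at every sample.
#' @export
simulate_episode <- function(params, drive, length_trajectory,
                             t_end = NULL, dt_out = 0.002,
                             initial_state = NULL,
                             hmax = 0.05, rtol = 1e-6, atol = 1e-8) {
  validate_hill_parameters(params)
  if (!inherits(drive, "drive_signal")) stop("drive must be a drive_signal object")
  lt <- length_trajectory
  if (!all(c("time_s", "length_mm") %in% names(lt))) {
    stop("length_trajectory must have columns time_s and length_mm")
  }
  if (is.null(t_end)) t_end <- max(lt$time_s)
  if (max(lt$time_s) < t_end - 1e-9) {
    stop("length trajectory does not cover the requested time span")
  }

  # neural drive as u_f(t), zero-order hold (mapping through the sigmoid
  # commutes with the hold)
  uv <- if (drive$mode == "frequency") {
    force_frequency_response(drive$value, params$A)
  } else drive$value
  u_fun <- stats::approxfun(drive$time, uv, method = "constant",
                            yleft = uv[1], rule = 2, f = 0)

  l_norm <- lt$length_mm / params$L_mto
  l_fun <- stats::approxfun(lt$time_s, l_norm, method = "linear", rule = 2)
  nseg <- length(l_norm) - 1L
  slopes <- if (nseg >= 1L) diff(l_norm) / diff(lt$time_s) else 0
  dl_fun <- if (nseg >= 1L) {
    stats::approxfun(lt$time_s, c(slopes, 0), method = "constant", rule = 2, f = 0)
  } else function(t) rep(0, length(t))

  gd <- .sim_guards(params)
  p <- params

  rhs <- function(t, y, parms) {
    u <- u_fun(t)
    lmt <- l_fun(t)
    ap <- y[1]
    lm <- y[2]
    dap <- (u - (p$beta + (1 - p$beta) * u) * ap) / p$tau
    a <- min(1, max(0, p$g * (ap - p$a0)))
    if (a < gd$eps_a) {
      dlm <- dl_fun(t) + gd$k_track * (lmt - lm)
    } else {
      f_see <- p$K_t * (lmt - lm)
      ltv <- max(active_length_tension(lm, p$Y), gd$lt_floor)
      r <- max(f_see / (max(a, gd$eps_a) * ltv), 0)
      dlm <- -max(inverse_force_velocity(r, p$E), -gd$v_len_cap)
    }
    list(c(dap, dlm))
  }

  if (is.null(initial_state)) {
    initial_state <- list(a_prime = p$a0, l_m_norm = l_fun(0))
  }
  y0 <- c(ap = unname(initial_state$a_prime), lm = unname(initial_state$l_m_norm))
  times <- seq(0, t_end, by = dt_out)

  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = rtol, atol = atol, hmax = hmax)
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf("ODE integration failed near t = %.4f s", max(sol[, "time"])))
  }

  ap <- sol[, "ap"]
  lm <- sol[, "lm"]
  lmt <- l_fun(sol[, "time"])
  a <- activation_output(ap, p$g, p$a0)
  f_pe <- passive_length_tension(lmt, p$C, p$l_pe_threshold)
  f_see <- pmax(p$K_t * (lmt - lm), 0)
  out <- data.frame(
    time_s = sol[, "time"],
    force_N = p$F_mto * (f_pe + f_see),
    activation = a,
    a_prime = ap,
    l_m_norm = lm,
    f_pe = f_pe,
    f_see = f_see
  )
  class(out) <- c("muscle_simulation", "data.frame")
  out
}

#' Isometric steady state of the muscle model
#'
#' Solves the algebraic series-elastic equilibrium at a fixed total length
#' and constant drive, using the closed-form activation fixed point.  The
#' contractile element comes to rest where the inverse force-velocity
#' curve crosses zero, i.e. at `K_t * (l_mt - l_m) = r0 * a * LT(l_m)`
#' with `r0` the zero crossing of the fitted inverse (0.983 for the
#' shipped model, whose inverse fit gives a slightly negative velocity at
#' force ratio 1).  This is the independent oracle used to check simulated
#' isometric plateaus.
#'
#' @param params A [hill_parameters()] object.
#' @param l_mt_norm Normalized total muscle length.
#' @param u_f Constant neural drive in \[0, 1\].
#' @return List with `a`, `l_m_norm`, `f_ce` (normalized), `f_pe`, and
#'   `force_N`.
#' @export
isometric_steady_state <- function(params, l_mt_norm, u_f) {
  validate_hill_parameters(params)
  a_ss <- activation_output(u_f / (params$beta + (1 - params$beta) * u_f),
                            params$g, params$a0)
  if (a_ss <= 0) {
    l_m <- l_mt_norm
    f_ce <- 0
  } else {
    r0 <- stats::uniroot(function(r) inverse_force_velocity(r, params$E),
                         c(0, 4), tol = 1e-12)$root
    fn <- function(lm) {
      params$K_t * (l_mt_norm - lm) -
        r0 * a_ss * max(active_length_tension(lm, params$Y), 1e-3)
    }
    # CE can only shorten below l_mt at equilibrium (SEE stretch >= 0)
    lower <- l_mt_norm - 1.5 * a_ss * 2 / params$K_t - 0.5
    l_m <- stats::uniroot(fn, c(lower, l_mt_norm), tol = 1e-12)$root
    f_ce <- params$K_t * (l_mt_norm - l_m)
  }
  f_pe <- passive_length_tension(l_mt_norm, params$C, params$l_pe_threshold)
  list(a = a_ss, l_m_norm = l_m, f_ce = f_ce, f_pe = f_pe,
       force_N = params$F_mto * (f_pe + f_ce))
}
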