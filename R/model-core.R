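# Constitutive relationships of the Hill-type model.  All functions here are
# pure evaluations in normalized coordinates: forces in units of F_mto,
# lengths and velocities in units of L_mto (per second).  Shortening
# velocities are positive; ingestion code converts lab-frame ramp velocities
# with normalize_contractile_velocity(), the single place where the sign flip
# lives.

#' Force-frequency response (neural drive sigmoid)
#'
#' Maps a nerve stimulation frequency to the normalized steady active force
#' it evokes, using the four-coefficient sigmoid
#' `u_f = A1 / (A1 + A2 * exp(-A3 * (f - A4)))`.  With positive `A1..A3`
#' this is strictly increasing in `f_stim` with asymptote 1.
#'
#' @param f_stim Stimulation frequency (Hz), vectorized; must be >= 0.
#' @param A Length-4 coefficient vector.
#' @return Neural drive `u_f` in \[0, 1\].
#' @export
force_frequency_response <- function(f_stim, A) {
  if (length(A) != 4L || !all(is.finite(A))) {
    stop("A must be 4 finite force-frequency coefficients")
  }
  if (any(f_stim < 0)) stop("f_stim must be >= 0")
  A[1] / (A[1] + A[2] * exp(-A[3] * (f_stim - A[4])))
}

#' Active length-tension cubic
#'
#' Raw cubic polynomial `c1*l^3 + c2*l^2 + c3*l + c4`.  Used with the
#' `B` coefficients (argument: normalized total muscle length) or the `Y`
#' coefficients (argument: normalized contractile-element length).  The
#' value is returned unclamped so fitting diagnostics can see the raw
#' polynomial; the simulator floors it (see [simulate_episode()]).
#'
#' @param l_norm Normalized length, vectorized.
#' @param coeffs Length-4 cubic coefficient vector (descending powers).
#' @return Length-tension multiplier (raw polynomial value).
#' @export
active_length_tension <- function(l_norm, coeffs) {
  if (length(coeffs) != 4L || !all(is.finite(coeffs))) {
    stop("coeffs must be 4 finite cubic coefficients")
  }
  if (!all(is.finite(l_norm))) stop("l_norm must be finite")
  ((coeffs[1] * l_norm + coeffs[2]) * l_norm + coeffs[3]) * l_norm + coeffs[4]
}

#' Passive length-tension curve
#'
#' Exponential passive force `C1 + C2 * exp(C3 * l - C4)` above a threshold
#' length, identically zero below it.  The exponential branch is clamped at
#' zero so the passive element is never tensile-negative (the raw branch is
#' slightly negative just above the threshold, about -0.0065 at 0.87 for the
#' fitted I1/I3 coefficients, well below measurement noise).
#'
#' @param l_mt_norm Normalized total muscle length, vectorized.
#' @param C Length-4 coefficient vector.
#' @param threshold Normalized length below which passive force is zero.
#' @return Normalized passive force, >= 0.
#' @export
passive_length_tension <- function(l_mt_norm, C, threshold = 0.87) {
  if (length(C) != 4L || !all(is.finite(C))) {
    stop("C must be 4 finite passive length-tension coefficients")
  }
  out <- pmax(0, C[1] + C[2] * exp(C[3] * l_mt_norm - C[4]))
  out[l_mt_norm < threshold] <- 0
  out
}

#' Force-velocity curve (piecewise hyperbolas)
#'
#' Force multiplier as a function of normalized contractile-element
#' velocity (shortening positive):
#' `1 + D1/(1 + D2/v)` for shortening, `1 + D3/(1 - D4/v)` for lengthening,
#' continuous at `v = 0` with value 1.
#'
#' @param v_m_norm Normalized contractile velocity (shortening positive),
#'   vectorized.
#' @param D Length-4 coefficient vector with `D[2] > 0`, `D[4] > 0`.
#' @return Force-velocity multiplier.
#' @export
force_velocity <- function(v_m_norm, D) {
  if (length(D) != 4L || !all(is.finite(D))) {
    stop("D must be 4 finite force-velocity coefficients")
  }
  if (D[2] <= 0 || D[4] <= 0) {
    stop("force-velocity pole coefficients D[2] and D[4] must be positive")
  }
  if (!all(is.finite(v_m_norm))) stop("v_m_norm must be finite")
  out <- numeric(length(v_m_norm))
  sh <- v_m_norm > 0
  le <- v_m_norm < 0
  out[sh] <- 1 + D[1] / (1 + D[2] / v_m_norm[sh])
  out[le] <- 1 + D[3] / (1 - D[4] / v_m_norm[le])
  out[v_m_norm == 0] <- 1
  out
}

#' Inverse force-velocity curve (double exponential)
#'
#' Normalized contractile velocity as a function of the force-velocity
#' ratio: `v = -E1*exp(E2*(fv - E3)) + E4*exp(E5*fv)`.  With the fitted
#' coefficient signs (`E1, E2, E4 > 0`, `E5 < 0`) the curve is decreasing:
#' low force means fast shortening, force above isometric means
#' lengthening.
#'
#' @param fv_ratio Force-velocity multiplier, vectorized.
#' @param E Length-5 coefficient vector.
#' @return Normalized contractile velocity (shortening positive).
#' @export
inverse_force_velocity <- function(fv_ratio, E) {
  if (length(E) != 5L || !all(is.finite(E))) {
    stop("E must be 5 finite inverse force-velocity coefficients")
  }
  -E[1] * exp(E[2] * (fv_ratio - E[3])) + E[4] * exp(E[5] * fv_ratio)
}

#' Series elastic force (linear spring, zero slack length)
#'
#' @param l_t_norm Normalized series-elastic extension
#'   (`l_t = l_mt - l_m`), vectorized.
#' @param K_t Normalized stiffness (> 0).
#' @return Normalized series-elastic force `K_t * l_t_norm`.
#' @export
series_elastic_force <- function(l_t_norm, K_t) {
  if (!is.finite(K_t) || K_t <= 0) stop("K_t must be a positive number")
  K_t * l_t_norm
}

#' First-order activation dynamics
#'
#' Time derivative of the pre-scaling activation state:
#' `da'/dt = (u_f - (beta + (1 - beta) * u_f) * a') / tau`.
#' The effective time constant grades linearly with drive, from `tau` at
#' full drive to `tau/beta` in relaxation; the fixed point is
#' `u_f / (beta + (1 - beta) * u_f)`.
#'
#' @param a_prime Pre-scaling activation state.
#' @param u_f Neural drive in \[0, 1\].
#' @param tau Activation time constant (s), > 0.
#' @param beta Relaxation ratio in (0, 1].
#' @return `da'/dt` in 1/s.
#' @export
activation_derivative <- function(a_prime, u_f, tau, beta) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0")
  if (!is.finite(beta) || beta <= 0 || beta > 1) stop("beta must be in (0, 1]")
  (u_f - (beta + (1 - beta) * u_f) * a_prime) / tau
}

#' Closed-form activation response to a constant drive
#'
#' Analytic solution of the first-order activation equation under constant
#' drive: exponential approach to the fixed point with rate
#' `(beta + (1 - beta) * u_f) / tau`.  Used as the independent oracle for
#' the numerical integrator.
#'
#' @param t Time (s), vectorized.
#' @param u_f Constant neural drive.
#' @param tau,beta Activation parameters, see [activation_derivative()].
#' @param a_prime0 Initial pre-scaling activation at `t = 0`.
#' @return `a'(t)`.
#' @export
activation_closed_form <- function(t, u_f, tau, beta, a_prime0) {
  k <- beta + (1 - beta) * u_f
  a_ss <- u_f / k
  a_ss + (a_prime0 - a_ss) * exp(-t * k / tau)
}

#' Activation output scaling and thresholding
#'
#' `a = clamp(g * (a' - a0), 0, 1)`: the pre-scaling state is offset by
#' `a0`, scaled by `g` and clipped to the admissible activation range.
#'
#' @param a_prime Pre-scaling activation state, vectorized.
#' @param g Gain, > 0.
#' @param a0 Offset.
#' @return Activation `a` in \[0, 1\].
#' @export
activation_output <- function(a_prime, g, a0) {
  if (!is.finite(g) || g <= 0) stop("g must be > 0")
  pmin(1, pmax(0, g * (a_prime - a0)))
}

#' Total muscle force
#'
#' Dimensional muscle force `F_mto * (f_PE(l_mt) + K_t * (l_mt - l_m))`:
#' the passive element plus the series-elastic element, whose force equals
#' the contractile-element force at the model's internal equilibrium.
#'
#' @param params A [hill_parameters()] object.
#' @param l_mt_norm Normalized total muscle length.
#' @param l_m_norm Normalized contractile-element length.
#' @return Total force in N.
#' @export
total_muscle_force <- function(params, l_mt_norm, l_m_norm) {
  validate_hill_parameters(params)
  f_pe <- passive_length_tension(l_mt_norm, params$C, params$l_pe_threshold)
  f_see <- series_elastic_force(l_mt_norm - l_m_norm, params$K_t)
  params$F_mto * (f_pe + f_see)
}

#' Convert a lab-frame length rate to normalized contractile velocity
#'
#' The rig reports lengthening of the whole muscle as positive mm/s, while
#' the force-velocity relationship uses shortening-positive normalized
#' velocity.  This is the single conversion point:
#' `v_norm = -dL/dt / L_mto`.
#'
#' @param dL_dt Lab-frame rate of length change (mm/s, lengthening
#'   positive), vectorized.
#' @param L_mto Optimal muscle length (mm).
#' @return Normalized velocity, shortening positive (1/s in units of
#'   `L_mto`).
#' @export
normalize_contractile_velocity <- function(dL_dt, L_mto) {
  -dL_dt / L_mto
}
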