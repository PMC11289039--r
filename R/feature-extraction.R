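# Windowed feature extraction from episode traces.  Every averaging window
# is a pure function of declared episode metadata (stimulation onset/offset,
# ramp times, ramp velocity); nothing is searched for outside the declared
# stimulation interval.

.trace_fs <- function(trace) {
  fs <- trace$meta$fs
  if (is.null(fs)) fs <- 1 / stats::median(diff(trace$data$time_s))
  fs
}

.window_mean <- function(trace, from, to, what = "window") {
  d <- trace$data
  idx <- d$time_s >= from & d$time_s <= to
  if (!any(idx)) {
    stop(sprintf("%s [%g, %g] s contains no samples (trace spans [%g, %g] s)",
                 what, from, to, min(d$time_s), max(d$time_s)))
  }
  mean(d$force_N[idx])
}

# Mean force over the closed window of ceil(fs * width_s) samples centered
# on the sample nearest `t`; the bench convention for "the force at a time".
.endpoint_mean <- function(trace, t, width_s = 0.001) {
  d <- trace$data
  fs <- .trace_fs(trace)
  n <- ceiling(fs * width_s)
  i0 <- which.min(abs(d$time_s - t))
  half <- (n - 1L) %/% 2L
  idx <- max(1L, i0 - half):min(nrow(d), i0 + half + (n - 1L) %% 2L)
  mean(d$force_N[idx])
}

#' Extract a force-frequency point from an isometric episode
#'
#' Baseline passive force is the mean force 5 to 20 s before stimulation
#' onset; the active force is the mean of the baseline-subtracted force in
#' a 2 s window centered on the in-stimulation force peak (truncated at the
#' stimulation bounds if the peak sits near an edge).
#'
#' @param trace An `episode_trace` from a force-frequency episode with at
#'   least 20 s of pre-stimulation data.
#' @return List with `f_stim` (Hz) and `F_CE_e` (N, unnormalized).
#' @export
extract_ff_point <- function(trace) {
  m <- trace$meta
  if (is.null(m$stim_onset) || is.null(m$stim_offset)) {
    stop("episode metadata must declare stim_onset and stim_offset")
  }
  t0 <- min(trace$data$time_s)
  if (m$stim_onset - t0 < 20) {
    stop(sprintf("insufficient pre-stimulation data: %.1f s available, 20 s needed",
                 m$stim_onset - t0))
  }
  baseline <- .window_mean(trace, m$stim_onset - 20, m$stim_onset - 5,
                           "baseline window")
  d <- trace$data
  stim <- d$time_s >= m$stim_onset & d$time_s <= m$stim_offset
  f_ce <- d$force_N[stim] - baseline
  t_stim <- d$time_s[stim]
  t_peak <- t_stim[which.max(f_ce)]
  w_from <- max(m$stim_onset, t_peak - 1)
  w_to <- min(m$stim_offset, t_peak + 1)
  active <- mean(f_ce[t_stim >= w_from & t_stim <= w_to])
  list(f_stim = m$stim_hz, F_CE_e = active)
}

#' Normalize a series of force-frequency points
#'
#' Divides each active force by the maximum over the muscle's own
#' force-frequency trials, so the strongest response maps to exactly 1.
#'
#' @param points Data frame with columns `f_stim` and `F_CE_e` (one muscle).
#' @return The data frame with an added column `u_f_e`.
#' @export
normalize_ff_series <- function(points) {
  if (nrow(points) < 1L) stop("no force-frequency points supplied")
  f_max <- max(points$F_CE_e)
  if (!is.finite(f_max) || f_max <= 0) {
    stop("degenerate normalization: no positive active force among the trials")
  }
  points$u_f_e <- points$F_CE_e / f_max
  points
}

#' Extract a raw length-tension point from one episode
#'
#' Passive force: mean force 2 to 10 s before stimulation onset.  Active
#' force: mean total force in a 1 s window centered on the in-stimulation
#' peak, minus the passive force.
#'
#' @param trace An `episode_trace` from a length-tension episode.
#' @return List with `L_mt` (mm, length during stimulation), `F_PE_e` and
#'   `F_CE_e` (N).
#' @export
extract_lt_point <- function(trace) {
  m <- trace$meta
  if (is.null(m$stim_onset) || is.null(m$stim_offset)) {
    stop("length-tension episode lacks a declared stimulation window")
  }
  passive <- .window_mean(trace, m$stim_onset - 10, m$stim_onset - 2,
                          "passive window")
  d <- trace$data
  stim <- d$time_s >= m$stim_onset & d$time_s <= m$stim_offset
  if (!any(stim)) stop("stimulation window contains no samples")
  t_stim <- d$time_s[stim]
  f_stim <- d$force_N[stim]
  t_peak <- t_stim[which.max(f_stim)]
  w_from <- max(m$stim_onset, t_peak - 0.5)
  w_to <- min(m$stim_offset, t_peak + 0.5)
  active <- mean(f_stim[t_stim >= w_from & t_stim <= w_to]) - passive
  L_mt <- d$length_mm[which.min(abs(d$time_s - m$stim_onset))]
  list(L_mt = L_mt, F_PE_e = passive, F_CE_e = active)
}

#' Extract and normalize the length-tension series of one muscle
#'
#' Two-pass extraction: raw passive/active forces per episode, then
#' per-muscle normalization by the peak active force.  The optimal length
#' `L_mto_e` is the length at which the peak active force occurs, and both
#' lengths and forces are normalized by the muscle's own `L_mto_e` and
#' `F_mto_e`, so the peak point maps to (1, 1) exactly.
#'
#' @param traces List of `episode_trace`s from one muscle's length-tension
#'   protocol.
#' @param drop_conditioning Drop episodes tagged `conditioning = TRUE`
#'   (the first two bench episodes).
#' @return Data frame with columns `L_mt`, `F_PE_e`, `F_CE_e`,
#'   `l_mt_norm`, `LT_e`, `f_pe_e`, with attributes `F_mto_e` (N) and
#'   `L_mto_e` (mm).
#' @export
extract_lt_points <- function(traces, drop_conditioning = TRUE) {
  if (drop_conditioning) {
    traces <- Filter(function(tr) !isTRUE(tr$meta$conditioning), traces)
  }
  if (length(traces) < 1L) stop("no usable length-tension episodes")
  raw <- do.call(rbind, lapply(traces, function(tr) {
    as.data.frame(extract_lt_point(tr))
  }))
  i_max <- which.max(raw$F_CE_e)
  F_mto_e <- raw$F_CE_e[i_max]
  L_mto_e <- raw$L_mt[i_max]
  if (F_mto_e <= 0) stop("no positive active force in the length-tension series")
  raw$l_mt_norm <- raw$L_mt / L_mto_e
  raw$LT_e <- raw$F_CE_e / F_mto_e
  raw$f_pe_e <- raw$F_PE_e / F_mto_e
  attr(raw, "F_mto_e") <- F_mto_e
  attr(raw, "L_mto_e") <- L_mto_e
  raw
}

#' Slope of the active force rise during an isokinetic ramp
#'
#' Builds the contractile-element force over the active ramp by subtracting
#' the passive force measured during the passive ramp *at the same muscle
#' length* (linear interpolation of passive force against length), fits a
#' fourth-order polynomial in time over the ramp, and returns its analytic
#' derivative at `eval_time` along with the quartic coefficients.
#'
#' @param active Episode trace containing the stimulated ramp (metadata
#'   `t_a_start`, `t_a_end`).
#' @param passive Episode trace containing the unstimulated ramp (metadata
#'   `t_p_start`, `t_p_end`); may be the same trace.
#' @param eval_time Time (s) at which the derivative is evaluated.
#' @return List with `slope` (N/s), `G` (quartic coefficients, descending
#'   powers of `t - t_a_start`) and `eval_time`.
#' @export
active_force_rise_slope <- function(active, passive = active, eval_time) {
  ma <- active$meta
  mp <- passive$meta
  if (is.null(ma$t_a_start) || is.null(ma$t_a_end)) {
    stop("active episode lacks declared ramp times t_a_start/t_a_end")
  }
  if (is.null(mp$t_p_start) || is.null(mp$t_p_end)) {
    stop("passive episode lacks declared ramp times t_p_start/t_p_end")
  }
  dp <- passive$data
  pidx <- dp$time_s >= mp$t_p_start & dp$time_s <= mp$t_p_end
  if (diff(range(dp$length_mm[pidx])) < 1e-9) {
    # isometric degenerate "ramp": passive force is a constant of length
    pf <- mean(dp$force_N[pidx])
    pass_by_length <- function(l) rep(pf, length(l))
  } else {
    pass_by_length <- stats::approxfun(dp$length_mm[pidx], dp$force_N[pidx],
                                       method = "linear", rule = 2, ties = mean)
  }
  da <- active$data
  aidx <- da$time_s >= ma$t_a_start & da$time_s <= ma$t_a_end
  if (sum(aidx) < 5L) {
    stop(sprintf("underdetermined quartic fit: %d samples in the active ramp",
                 sum(aidx)))
  }
  s <- da$time_s[aidx] - ma$t_a_start
  f_ce <- da$force_N[aidx] - pass_by_length(da$length_mm[aidx])
  fit <- stats::lm(f_ce ~ stats::poly(s, 4, raw = TRUE))
  cf <- stats::coef(fit)            # intercept, s, s^2, s^3, s^4
  G <- rev(unname(cf))              # descending powers
  se <- eval_time - ma$t_a_start
  slope <- 4 * G[1] * se^3 + 3 * G[2] * se^2 + 2 * G[3] * se + G[4]
  list(slope = slope, G = G, eval_time = eval_time)
}

#' Extract a force-velocity point from a paired passive/active episode
#'
#' Implements the series-elasticity-corrected force-velocity estimate: the
#' active force at the end of the stimulated ramp (minus the passive force
#' at the end of the unstimulated ramp) is normalized by the corrected
#' isometric force and the active length-tension value at the end length,
#' while the contractile-element velocity is the ramp velocity corrected by
#' the series-elastic strain rate inferred from the active force-rise
#' slope.  Endpoint forces use a 1 ms averaging window.
#'
#' @param active Episode trace with the stimulated ramp.
#' @param passive Episode trace with the matched unstimulated ramp at the
#'   same `V_mt`; defaults to `active` when both phases share a trace.
#' @param B Active length-tension cubic coefficients (in normalized total
#'   length) from the length-tension stage.
#' @param K_t Normalized series stiffness.
#' @param L_mto Optimal muscle length (mm).
#' @param a Assumed activation during the ramp (1 at saturating
#'   stimulation).
#' @return List with `v_m_norm` (shortening positive), `fv`,
#'   `F_iso_est_max` (N), `slope` (N/s) and `V_mt` (mm/s, lab frame).
#' @export
extract_fv_point <- function(active, passive = active, B, K_t, L_mto, a = 1) {
  ma <- active$meta
  mp <- passive$meta
  if (!isTRUE(all.equal(ma$V_mt, mp$V_mt))) {
    stop("pairing error: active and passive episodes have different ramp velocities")
  }
  F_mt_end <- .endpoint_mean(active, ma$t_a_end)
  F_pe_end <- .endpoint_mean(passive, mp$t_p_end)
  F_mt_start <- .endpoint_mean(active, ma$t_a_start)
  F_pe_start <- .endpoint_mean(passive, mp$t_p_start)
  da <- active$data
  l_start <- da$length_mm[which.min(abs(da$time_s - ma$t_a_start))] / L_mto
  l_end <- da$length_mm[which.min(abs(da$time_s - ma$t_a_end))] / L_mto

  lt_start <- active_length_tension(l_start, B)
  if (lt_start <= 0) stop("degenerate point: length-tension value <= 0 at the ramp start")
  F_iso <- (F_mt_start - F_pe_start) / lt_start

  rise <- active_force_rise_slope(active, passive, eval_time = ma$t_a_end)
  v_lab <- ma$V_mt / L_mto - rise$slope / (K_t * F_iso)
  v_m <- -v_lab  # shortening-positive convention

  lt_end <- active_length_tension(l_end, B)
  denom <- F_iso * a * lt_end
  if (!is.finite(denom) || denom <= 0) {
    stop("degenerate point: isometric normalization is not positive")
  }
  fv <- (F_mt_end - F_pe_end) / denom
  list(v_m_norm = v_m, fv = fv, F_iso_est_max = F_iso,
       slope = rise$slope, V_mt = ma$V_mt)
}

#' Extract all force-velocity points of an experiment
#'
#' @param traces List of paired-phase force-velocity episode traces.
#' @inheritParams extract_fv_point
#' @return Data frame with one row per episode (`V_mt`, `v_m_norm`, `fv`,
#'   `F_iso_est_max`, `dFCE_dt`).
#' @export
extract_fv_points <- function(traces, B, K_t, L_mto, a = 1) {
  do.call(rbind, lapply(traces, function(tr) {
    p <- extract_fv_point(tr, tr, B = B, K_t = K_t, L_mto = L_mto, a = a)
    data.frame(V_mt = p$V_mt, v_m_norm = p$v_m_norm, fv = p$fv,
               F_iso_est_max = p$F_iso_est_max, dFCE_dt = p$slope)
  }))
}

#' Evaluation time for the series-stiffness slope
#'
#' The force-rise slope used in the stiffness regression is evaluated at
#' the start of the active ramp, where the contractile element has not yet
#' accelerated and the neglected contractile-velocity term of the
#' stiffness relation vanishes.  (The end of the ramp is still used for
#' the force-velocity correction, where the instantaneous slope at the
#' measurement time is what matters.)
#'
#' @param trace A force-velocity `episode_trace`.
#' @return Time (s) at which to evaluate the slope.
#' @export
stiffness_eval_time <- function(trace) {
  trace$meta$t_a_start
}

#' Estimate the normalized series-elastic stiffness
#'
#' Ordinary least-squares regression of the active force-rise slope
#' against the lab-frame ramp velocity across episodes; the contractile
#' velocity term is neglected, which biases the estimate slightly low (the
#' documented approximation of the bench analysis).  The regression slope
#' (N per mm) is converted to the dimensionless stiffness by
#' `L_mto / F_mto`.  The intercept is not constrained to zero and is
#' returned as a diagnostic.
#'
#' @param points Data frame with columns `V_mt` (mm/s) and `dFCE_dt` (N/s),
#'   one row per episode; at least two distinct velocities.
#' @param F_mto Peak isometric force (N).
#' @param L_mto Optimal length (mm).
#' @return List with `K_t` (dimensionless), `slope` (N/mm), `intercept`
#'   (N/s), `r_squared` and `n`.
#' @export
estimate_series_stiffness <- function(points, F_mto, L_mto) {
  if (length(unique(points$V_mt)) < 2L) {
    stop("rank-deficient stiffness regression: need at least 2 distinct velocities")
  }
  fit <- stats::lm(dFCE_dt ~ V_mt, data = points)
  slope <- unname(stats::coef(fit)["V_mt"])
  tss <- sum((points$dFCE_dt - mean(points$dFCE_dt))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  list(K_t = slope * L_mto / F_mto,
       slope = slope,
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = r2,
       n = nrow(points))
}
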