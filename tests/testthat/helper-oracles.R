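# Shared oracles and a session cache for the synthetic experiments, which
# several test files reuse.

# Effective force-velocity relation of a model that simulates through the
# inverse-FV double exponential: the force ratio r at which the inverted
# velocity equals v, found by root bracketing (independent of the
# simulator and of the hyperbolic FV fit).
r_effective <- function(v, E) {
  vapply(v, function(vv) {
    stats::uniroot(function(r) inverse_force_velocity(r, E) - vv,
                   c(-2, 6), tol = 1e-12)$root
  }, numeric(1))
}

# Composed measurable steady-state force-frequency response of a model:
# activation fixed point pushed through the series-elastic equilibrium.
composed_ff_force <- function(params, f_stim) {
  vapply(f_stim, function(fr) {
    isometric_steady_state(params, params$L_0 / params$L_mto,
                           force_frequency_response(fr, params$A))$f_ce
  }, numeric(1))
}

# Nearest constraint-feasible cubic to a coefficient vector: equality
# constraints cubic(1) = 1 and cubic'(1) = 0 imposed by projection.
feasible_cubic <- function(b) {
  A <- rbind(c(1, 1, 1, 1), c(3, 2, 1, 0))
  c_ <- c(1, 0)
  b + crossprod(A, solve(A %*% t(A), c_ - A %*% b))
}

# Build a minimal synthetic episode_trace by hand (for extractor unit
# tests that need full control of the force channel).
manual_trace <- function(time, force, length = NULL, stim_hz = 0, meta = list()) {
  fs <- 1 / median(diff(time))
  if (is.null(length)) length <- rep(16.02, length(time))
  structure(list(
    data = data.frame(time_s = time, length_mm = length, force_N = force,
                      stim_hz = stim_hz),
    meta = utils::modifyList(list(fs = fs), meta)
  ), class = "episode_trace")
}

# --- session cache for the expensive synthetic experiments ----------------
.synth_cache <- new.env(parent = emptyenv())

truth_params <- function() {
  if (is.null(.synth_cache$truth)) .synth_cache$truth <- hill_parameters_i1i3()
  .synth_cache$truth
}

# One full set of synthetic protocols from the ground-truth model.
# noise_sd = 0 gives the noiseless study conditions; the noisy variant uses
# 10 mN measurement noise with fixed seeds.
synthetic_experiments <- function(noise_sd = 0) {
  key <- paste0("synth_", noise_sd)
  if (is.null(.synth_cache[[key]])) {
    p <- truth_params()
    s <- function(k) if (noise_sd > 0) k else NULL
    .synth_cache[[key]] <- list(
      ff = synthesize_experiment(p, ff_protocol(L_0 = p$L_0), noise_sd, s(101)),
      lt = synthesize_experiment(p, lt_protocol(L_0 = p$L_0), noise_sd, s(202)),
      fv = synthesize_experiment(p, fv_protocol(L_0 = p$L_0), noise_sd, s(303))
    )
  }
  .synth_cache[[key]]
}

# The kinetic pipeline run on those experiments (activation fitted
# separately where a test needs it).
pipeline_fit <- function(noise_sd = 0) {
  key <- paste0("fit_", noise_sd)
  if (is.null(.synth_cache[[key]])) {
    ex <- synthetic_experiments(noise_sd)
    .synth_cache[[key]] <- characterize_muscle(ex$ff, ex$lt, ex$fv,
                                               fit_activation = FALSE)
  }
  .synth_cache[[key]]
}
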