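# Synthetic rig experiments.  The three servomotor protocols (isometric
# force-frequency trains, slow length-tension ramps, paired passive/active
# isokinetic ramps) are generated as length trajectories plus stimulation
# schedules, pushed through the forward simulator with a known ground-truth
# model, and optionally corrupted with measurement noise.  Episodes are
# simulated independently from rest: the long inter-episode rests of the
# bench protocol exist to let the real muscle recover, which a memoryless
# model achieves by a state reset at no integration cost.

.default_fs <- 500  # Hz; desk-scale decimation of the 5 kHz rig rate

#' Force-frequency protocol definition
#'
#' Isometric stimulation trains at the rest length: one episode per
#' frequency, each holding the muscle at `L_0` and stimulating for
#' `stim_duration` seconds.
#'
#' @param frequencies Stimulation train frequencies (Hz).
#' @param stim_duration Train duration (s).
#' @param pre_stim Quiet time before stimulation onset (s); must exceed the
#'   20 s baseline window of the extractor.
#' @param post_stim Quiet time after the train (s), long enough to observe
#'   the relaxation tail.
#' @param L_0 Rest length (mm).
#' @param fs Sampling rate of the synthesized traces (Hz).
#' @return List of protocol episode definitions.
#' @export
ff_protocol <- function(frequencies = seq(2, 38, by = 6),
                        stim_duration = 5, pre_stim = 25, post_stim = 20,
                        L_0 = 16.02, fs = .default_fs) {
  stopifnot(stim_duration > 0, pre_stim >= 20, post_stim > 0, fs > 0)
  lapply(seq_along(frequencies), function(i) {
    f <- frequencies[i]
    dur <- pre_stim + stim_duration + post_stim
    list(
      kind = "force_frequency",
      length = data.frame(time_s = c(0, dur), length_mm = c(L_0, L_0)),
      stim = data.frame(time_s = c(0, pre_stim, pre_stim + stim_duration),
                        hz = c(0, f, 0)),
      duration = dur, fs = fs,
      meta = list(protocol = "force_frequency", episode = i,
                  stim_hz = f, stim_onset = pre_stim,
                  stim_offset = pre_stim + stim_duration, fs = fs)
    )
  })
}

#' Length-tension protocol definition
#'
#' Slow 20 s ramps between length offsets relative to the rest length, a
#' long rest, then a saturating stimulation train at the new length.  The
#' first two episodes are conditioning (repeated shortening to `-1` mm) and
#' are tagged `conditioning = TRUE`; only the remaining episodes are meant
#' for fitting.
#'
#' @param offsets_mm Length offsets from `L_0` at which each episode ends
#'   (mm); the default reproduces the bench sequence
#'   0, -1, -1, 0, 1, ..., 8.
#' @param ramp_duration Length-change ramp duration (s).
#' @param stim_delay Time from the end of the ramp to stimulation onset (s).
#' @param stim_duration Stimulation train duration (s).
#' @param stim_hz Train frequency (Hz), saturating.
#' @param post_stim Quiet tail after the train (s).
#' @inheritParams ff_protocol
#' @return List of protocol episode definitions.
#' @export
lt_protocol <- function(offsets_mm = c(0, -1, -1, 0, 1, 2, 3, 4, 5, 6, 7, 8),
                        ramp_duration = 20, stim_delay = 110,
                        stim_duration = 5, stim_hz = 26, post_stim = 15,
                        L_0 = 16.02, fs = .default_fs) {
  stopifnot(length(offsets_mm) >= 1, ramp_duration > 0, stim_delay >= 10,
            stim_duration > 0, stim_hz >= 26)
  prev <- c(0, offsets_mm[-length(offsets_mm)])
  lapply(seq_along(offsets_mm), function(i) {
    dur <- ramp_duration + stim_delay + stim_duration + post_stim
    onset <- ramp_duration + stim_delay
    list(
      kind = "length_tension",
      length = data.frame(
        time_s = c(0, ramp_duration, dur),
        length_mm = L_0 + c(prev[i], offsets_mm[i], offsets_mm[i])
      ),
      stim = data.frame(time_s = c(0, onset, onset + stim_duration),
                        hz = c(0, stim_hz, 0)),
      duration = dur, fs = fs,
      meta = list(protocol = "length_tension", episode = i,
                  offset_mm = offsets_mm[i], stim_hz = stim_hz,
                  stim_onset = onset, stim_offset = onset + stim_duration,
                  ramp_start = 0, ramp_end = ramp_duration,
                  conditioning = i <= 2L, fs = fs)
    )
  })
}

#' Force-velocity protocol definition
#'
#' Paired passive/active isokinetic ramps over `L_0 - excursion` to
#' `L_0 + excursion`.  Each episode first ramps the unstimulated muscle
#' (passive phase), returns it to the start length, then after 80 s from
#' the passive start stimulates at a saturating frequency and repeats the
#' ramp during stimulation (active phase, ramp starting 5 s into the
#' train).  Shortening ramps carry negative `V_mt`.
#'
#' @param speeds_mm_s Signed ramp velocities (mm/s, lengthening positive);
#'   the default tests both directions at 0.25-8 mm/s.
#' @param excursion Half-range of the ramp around `L_0` (mm).
#' @param stim_hz Saturating stimulation frequency (Hz).
#' @inheritParams ff_protocol
#' @return List of protocol episode definitions.
#' @export
fv_protocol <- function(speeds_mm_s = c(-(c(0.25, 0.5, 1, 2, 4, 8)),
                                        c(0.25, 0.5, 1, 2, 4, 8)),
                        excursion = 0.5, stim_hz = 26,
                        L_0 = 16.02, fs = .default_fs) {
  stopifnot(length(speeds_mm_s) >= 1, all(speeds_mm_s != 0), excursion > 0)
  lapply(seq_along(speeds_mm_s), function(i) {
    v <- speeds_mm_s[i]
    from <- L_0 - sign(v) * excursion
    to <- L_0 + sign(v) * excursion
    ramp <- 2 * excursion / abs(v)
    t_p_start <- 5
    t_p_end <- t_p_start + ramp
    t_return_end <- t_p_end + 5 + ramp
    stim_start <- t_p_start + 80
    if (t_return_end > stim_start - 5) {
      stop("infeasible force-velocity episode: passive phase overruns the active phase")
    }
    t_a_start <- stim_start + 5
    t_a_end <- t_a_start + ramp
    if (t_a_end > stim_start + 10) {
      stop("infeasible force-velocity episode: ramp slower than the stimulation train")
    }
    dur <- stim_start + 10 + 10
    list(
      kind = "force_velocity",
      length = data.frame(
        time_s = c(0, t_p_start, t_p_end, t_p_end + 5, t_return_end,
                   t_a_start, t_a_end, dur),
        length_mm = c(from, from, to, to, from, from, to, to)
      ),
      stim = data.frame(time_s = c(0, stim_start, stim_start + 10),
                        hz = c(0, stim_hz, 0)),
      duration = dur, fs = fs,
      meta = list(protocol = "force_velocity", episode = i,
                  V_mt = v, stim_hz = stim_hz,
                  stim_onset = stim_start, stim_offset = stim_start + 10,
                  t_p_start = t_p_start, t_p_end = t_p_end,
                  t_a_start = t_a_start, t_a_end = t_a_end, fs = fs)
    )
  })
}

#' Generate a protocol by name
#'
#' Dispatcher over [ff_protocol()], [lt_protocol()] and [fv_protocol()].
#'
#' @param kind One of `"force_frequency"`, `"length_tension"`,
#'   `"force_velocity"`.
#' @param ... Passed to the protocol constructor.
#' @return List of protocol episode definitions.
#' @export
generate_protocol <- function(kind = c("force_frequency", "length_tension",
                                       "force_velocity"), ...) {
  kind <- match.arg(kind)
  switch(kind,
         force_frequency = ff_protocol(...),
         length_tension = lt_protocol(...),
         force_velocity = fv_protocol(...))
}

#' Synthesize one episode trace from a ground-truth model
#'
#' Runs the forward simulator over a protocol episode and packages the
#' result as an episode trace (uniformly sampled time, imposed length,
#' measured force, stimulation frequency, plus the protocol metadata the
#' feature extractors require).  Optional additive Gaussian measurement
#' noise on the force channel; a seed is mandatory whenever noise is
#' requested so traces are reproducible.  An optional exponential
#' stress-relaxation transient after each length ramp (amplitude in N,
#' decaying with `transient$tau_s`) exists only to probe extractor
#' robustness and is off by default.
#'
#' @param params Ground-truth [hill_parameters()].
#' @param episode One element of a protocol list.
#' @param noise_sd Force noise standard deviation (N).
#' @param seed RNG seed; required when `noise_sd > 0`.
#' @param transient Optional list with `amplitude` (N, absolute value at
#'   the end of each ramp) and `tau_s` (decay constant, s).
#' @return An `episode_trace` object: list with `data` (data frame
#'   `time_s`, `length_mm`, `force_N`, `stim_hz`) and `meta`.
#' @export
synthesize_episode <- function(params, episode, noise_sd = 0, seed = NULL,
                               transient = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_sd > 0 && is.null(seed)) stop("a seed is required when noise_sd > 0")
  drv <- drive_signal(episode$stim$time_s, episode$stim$hz, mode = "frequency")
  sim <- simulate_episode(params, drv, episode$length,
                          t_end = episode$duration, dt_out = 1 / episode$fs)
  l_fun <- stats::approxfun(episode$length$time_s, episode$length$length_mm,
                            method = "linear", rule = 2)
  s_fun <- stats::approxfun(episode$stim$time_s, episode$stim$hz,
                            method = "constant", rule = 2, f = 0)
  force <- sim$force_N
  if (!is.null(transient)) {
    bp <- episode$length
    ramp_ends <- bp$time_s[-1][abs(diff(bp$length_mm)) > 1e-12]
    dirs <- sign(diff(bp$length_mm))[abs(diff(bp$length_mm)) > 1e-12]
    for (k in seq_along(ramp_ends)) {
      idx <- sim$time_s >= ramp_ends[k]
      force[idx] <- force[idx] + dirs[k] * transient$amplitude *
        exp(-(sim$time_s[idx] - ramp_ends[k]) / transient$tau_s)
    }
  }
  if (noise_sd > 0) {
    set.seed(seed)
    force <- force + stats::rnorm(length(force), sd = noise_sd)
  }
  structure(list(
    data = data.frame(time_s = sim$time_s,
                      length_mm = l_fun(sim$time_s),
                      force_N = force,
                      stim_hz = s_fun(sim$time_s)),
    meta = episode$meta
  ), class = "episode_trace")
}

#' Synthesize a full experiment (list of episodes)
#'
#' Convenience wrapper running [synthesize_episode()] over every episode of
#' a protocol with per-episode seeds derived deterministically from `seed`.
#'
#' @inheritParams synthesize_episode
#' @param protocol A protocol list from [generate_protocol()] and friends.
#' @return List of `episode_trace` objects.
#' @export
synthesize_experiment <- function(params, protocol, noise_sd = 0, seed = NULL,
                                  transient = NULL) {
  lapply(seq_along(protocol), function(i) {
    ep_seed <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
    synthesize_episode(params, protocol[[i]], noise_sd = noise_sd,
                       seed = ep_seed, transient = transient)
  })
}

#' @export
print.episode_trace <- function(x, ...) {
  m <- x$meta
  cat(sprintf("episode trace: %s episode %s, %d samples at %g Hz\n",
              m$protocol, m$episode, nrow(x$data), m$fs))
  invisible(x)
}

#' Synthesize an EMG-like drive with known envelope
#'
#' An amplitude-modulated carrier emulating a rectifiable electromyogram:
#' the envelope is a sum of smooth bursts (raised-cosine edges), the
#' carrier is a band-limited oscillation (a tone, standing in for the
#' narrow-band interference pattern of a real recording), and additive
#' Gaussian noise models the measurement floor.  A broadband white-noise
#' carrier is deliberately not used: peak-interpolation envelope
#' estimators are negatively biased on broadband carriers (window maxima
#' sit well below the global peak), which would confound envelope-recovery
#' tests.  The true envelope is returned alongside the raw signal so
#' recovery can be tested against a known ground truth.
#'
#' @param duration Signal duration (s).
#' @param fs Sampling rate (Hz).
#' @param bursts Data frame with columns `start`, `end` (s) and
#'   `amplitude`; overlapping bursts sum.
#' @param edge Raised-cosine edge duration of each burst (s).
#' @param carrier_hz Carrier frequency (Hz); must be well below `fs / 2`.
#' @param noise_sd Additive measurement-noise standard deviation (signal
#'   units).
#' @param seed RNG seed (mandatory; the noise floor is random).
#' @return List with `time`, `signal` and `envelope` (the ground-truth
#'   modulation).
#' @export
synthesize_emg_drive <- function(duration = 10, fs = 1000,
                                 bursts = data.frame(start = 2, end = 7,
                                                     amplitude = 1),
                                 edge = 0.25, carrier_hz = 80,
                                 noise_sd = 0.02, seed) {
  stopifnot(duration > 0, fs > 0, nrow(bursts) >= 1,
            all(bursts$end > bursts$start), carrier_hz < fs / 2)
  time <- seq(0, duration, by = 1 / fs)
  env <- numeric(length(time))
  for (k in seq_len(nrow(bursts))) {
    b <- bursts[k, ]
    ramp_up <- pmin(pmax((time - b$start) / edge, 0), 1)
    ramp_dn <- pmin(pmax((b$end - time) / edge, 0), 1)
    shape <- (1 - cos(pi * ramp_up)) / 2 * (1 - cos(pi * ramp_dn)) / 2
    env <- env + b$amplitude * shape
  }
  set.seed(seed)
  carrier <- sin(2 * pi * carrier_hz * time)
  noise <- if (noise_sd > 0) stats::rnorm(length(time), sd = noise_sd) else 0
  list(time = time, signal = env * carrier + noise, envelope = env)
}

#' Write / read an episode trace
#'
#' The on-disk format is a CSV with columns
#' `time_s,length_mm,force_N,stim_hz` plus a metadata sidecar JSON
#' (protocol kind, stimulation and ramp times, ramp velocity, sampling
#' rate).  The reader validates the trace invariants (uniform sampling,
#' stimulation onset before offset, passive ramp before active ramp) and
#' reports the offending CSV line on failure.
#'
#' @param trace An `episode_trace` object.
#' @param csv_path Path of the CSV file; the sidecar is written next to it
#'   with extension `.json` unless `json_path` is given.
#' @param json_path Optional explicit sidecar path.
#' @return `read_episode_trace` returns an `episode_trace`.
#' @export
write_episode_trace <- function(trace, csv_path, json_path = NULL) {
  if (!inherits(trace, "episode_trace")) stop("trace must be an episode_trace")
  if (is.null(json_path)) json_path <- sub("\\.csv$", ".json", csv_path)
  utils::write.csv(trace$data, csv_path, row.names = FALSE)
  jsonlite::write_json(trace$meta, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}

#' @rdname write_episode_trace
#' @export
read_episode_trace <- function(csv_path, json_path = NULL) {
  if (is.null(json_path)) json_path <- sub("\\.csv$", ".json", csv_path)
  data <- utils::read.csv(csv_path)
  need <- c("time_s", "length_mm", "force_N", "stim_hz")
  if (!all(need %in% names(data))) {
    stop("episode CSV must have columns ", paste(need, collapse = ","))
  }
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  dt <- diff(data$time_s)
  if (length(dt) > 0) {
    bad <- which(abs(dt - stats::median(dt)) > stats::median(dt) + 1e-12)
    if (length(bad) > 0) {
      stop(sprintf("non-uniform sampling at CSV line %d (data row %d)",
                   bad[1] + 2L, bad[1] + 1L))
    }
  }
  if (!is.null(meta$stim_onset) && !is.null(meta$stim_offset) &&
      meta$stim_onset >= meta$stim_offset) {
    stop("metadata invalid: stim_onset must precede stim_offset")
  }
  if (identical(meta$protocol, "force_velocity") &&
      meta$t_p_end > meta$t_a_start) {
    stop("metadata invalid: passive ramp must precede the active ramp")
  }
  structure(list(data = data, meta = meta), class = "episode_trace")
}
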