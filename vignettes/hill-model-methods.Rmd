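---
title: "A Hill-type model of the Aplysia I1/I3 retractor complex: methods and design"
author: "aplysiahill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Hill-type model of the Aplysia I1/I3 retractor complex: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The I1/I3 complex is the main retractor of the odontophore (the grasper) in
the feeding apparatus of the sea slug *Aplysia californica*. This package
implements a lumped-parameter Hill-type model of that muscle and the full
characterization pipeline that identifies it from servomotor rig
experiments.

The muscle is a contractile element (CE) in series with a linear elastic
element (SEE), both in parallel with a passive elastic element (PE). With
forces normalized by the peak active isometric force $F_{mto}$ and lengths
and velocities by the optimal length $L_{mto}$, the total force is

$$ F_{mt} = F_{mto}\,\big( \tilde f_{PE}(\tilde l_{mt}) + \tilde
f_{CE} \big), \qquad \tilde f_{CE} = a(t)\; LT(\tilde l_m)\; FV(\tilde
v_m) = \tilde f_{SEE} = K_t(\tilde l_{mt} - \tilde l_m), $$

where $\tilde l_{mt}$ is the imposed (total) length, $\tilde l_m$ the CE
length, and $K_t$ the normalized series stiffness (slack length fixed at
zero — the "tendon" is internal connective tissue, not a physical tendon).
The constitutive curves are

* **force–frequency**: a sigmoid $u_f(f_{stim}) = A_1/(A_1 + A_2
  e^{-A_3 (f_{stim}-A_4)})$ mapping nerve stimulation frequency to steady
  normalized drive (`force_frequency_response()`);
* **active length–tension**: a cubic, concave over the measured range with
  its stationary point pinned to $(1, 1)$, in total-length coordinates
  (coefficients `B`) and, after series-elasticity correction, in CE
  coordinates (coefficients `Y`) (`active_length_tension()`);
* **passive length–tension**: $C_1 + C_2 e^{C_3 \tilde l_{mt} - C_4}$
  above a threshold length (default $0.87$), zero below it
  (`passive_length_tension()`);
* **force–velocity**: paired hyperbolas, $<1$ while shortening
  ($\tilde v_m \ge 0$ in the shortening-positive convention), $>1$ while
  lengthening (`force_velocity()`), plus the fitted inverse — a double
  exponential giving CE velocity from the force ratio
  (`inverse_force_velocity()`), which is what the simulator actually uses;
* **activation dynamics**: a first-order equation
  $\dot a' = \big(u_f - [\beta + (1-\beta) u_f]\, a'\big)/\tau$ with output
  $a = \mathrm{clamp}(g (a' - a_0), 0, 1)$. The effective time constant
  grades from $\tau$ (0.60 s at full drive) to $\tau/\beta$ (4.0 s in
  relaxation) — this muscle is smooth-muscle-like and over an order of
  magnitude slower than typical vertebrate striated muscle.

The shipped parameter set (`hill_parameters_i1i3()`) is the
closest-to-median individual of each experiment type: $F_{mto} = 1.61$ N,
$L_{mto} = 18.03$ mm, rest length $L_0 = 16.02$ mm, $K_t = 11.95$.

```{r}
library(aplysiahill)
hill_parameters_i1i3()
```

## Forward simulation

`simulate_episode()` integrates the two-state system — activation $a'(t)$
and CE length $\tilde l_m(t)$ — with an adaptive solver (`deSolve::lsoda`,
maximum step 50 ms, relative tolerance $10^{-6}$, absolute $10^{-8}$).
The imposed length is linearly interpolated; the stimulation schedule is a
held (zero-order) signal. The CE velocity comes from inverting the
force–velocity relation at the force the SEE carries:
$r = \tilde f_{SEE} / (a\, LT(\tilde l_m))$, then
$\tilde v_m = \mathrm{IFV}(r)$.

Numerical guards, and why they look the way they do:

* the denominator factors are floored ($a$ at $10^{-6}$, $LT$ at
  $10^{-3}$) and $r$ is clamped below at 0 — the SEE cannot push;
* $r$ is **not** clamped at the lengthening asymptote $1 + D_3$ of the
  hyperbolic fit. The inverse map is the fitted double exponential, which
  is finite and monotone past that asymptote; fast lengthening transiently
  drives $r$ above it and the inversion must follow, otherwise the CE
  velocity saturates near $0.09\,L_{mto}/s$ and the SEE winds up
  unphysically during fast ramps. Only a generous overflow cap
  ($20\,L_{mto}/s$) limits the returned lengthening velocity;
* when the activation is effectively zero the CE is slack: no velocity the
  fitted inverse can express would let it follow a fast passive ramp, and
  an $\epsilon$-floored ratio produces a chattering sliding mode that
  stalls the integrator. The slack branch instead lets $\tilde l_m$ track
  $\tilde l_{mt}$ directly (with a fast first-order pull-in of residual
  stretch), which keeps passive episodes exactly force-free in the series
  element — the behavior the model equations imply at $a = 0$.

Initial conditions are not stated by the characterization itself and are a
design choice: $a'(0) = a_0$ (so $a(0) = 0$) and an unstretched SEE.
Where a simulation explicitly represents a long-rested muscle (the
activation fit, the acceptance script) the activation state starts at the
zero-drive fixed point $a' = 0$ instead.

A consequence of simulating through the fitted inverse: the isometric
operating point sits where $\mathrm{IFV}(r) = 0$, i.e. at $r \approx
0.983$ for the shipped coefficients rather than exactly 1, because the
fitted inverse gives a slightly negative velocity at force ratio 1.
`isometric_steady_state()` — the algebraic oracle used in the tests —
solves the equilibrium at that zero crossing, so oracle and simulator
agree to solver accuracy.

## Feature extraction

Every averaging window is a pure function of declared episode metadata;
nothing is searched outside the declared stimulation interval.

* **Force–frequency** (`extract_ff_point()`): baseline = mean force 5–20 s
  before stimulation onset; active force = mean of the baseline-subtracted
  force in a 2 s window centered on the in-stimulation peak, truncated at
  the train bounds. Normalization (`normalize_ff_series()`) is per muscle
  over that muscle's trials.
* **Length–tension** (`extract_lt_points()`): passive = mean force 2–10 s
  before onset (the more specific of the two windows the protocol
  description offers; bounds configurable), active = 1 s peak-centered
  mean minus passive. Second pass normalizes by the muscle's own peak
  active force, so the peak point maps to $(1,1)$ exactly. The two
  conditioning episodes at the start of the protocol are tagged and
  dropped.
* **Force–velocity** (`extract_fv_point()`): endpoint forces use a 1 ms
  window (the closed sample window of $\lceil f_s \cdot 0.001\rceil$
  samples); the isometric normalizer is corrected to optimal length
  through the active LT fit; the CE velocity is the ramp velocity minus
  the SEE strain rate inferred from the force-rise slope at the ramp end.
  The passive trace is matched to the active ramp **by length**, not by
  time, before subtraction.
* **Series stiffness** (`estimate_series_stiffness()`): ordinary least
  squares of the force-rise slope on the lab-frame ramp velocity across
  episodes, scaled by $L_{mto}/F_{mto}$; the intercept is reported as a
  diagnostic, not constrained. The slope is a fourth-order polynomial
  derivative (`active_force_rise_slope()`), evaluated at the **start** of
  the active ramp (`stiffness_eval_time()`): there the CE has not yet
  accelerated and the neglected CE-velocity term of the stiffness relation
  vanishes. Evaluating at the ramp end instead (the time used for the
  velocity correction, where the instantaneous slope is what matters)
  biases the stiffness 20–35% low in forward simulation, because by then
  the CE carries a large share of the ramp velocity.

## Fitting

The active LT cubic is a linearly-constrained linear least-squares
problem — equalities $\sum B_i = 1$ and $3B_1 + 2B_2 + B_3 = 0$ (stationary
point through $(1,1)$), inequalities $6 B_1 l + 2 B_2 \le 0$ at the data
extremes (concavity) — solved exactly by enumerating the active sets of the
two inequalities (`fit_active_lt_constrained()`); the KKT residuals are
returned as diagnostics. The nonlinear families use deterministic
multi-start Levenberg–Marquardt. Two of the published parameterizations
carry exact redundancies — the four-coefficient sigmoid has two effective
shape parameters, and $E_1, E_3$ of the double exponential only enter via
$E_1 e^{-E_2 E_3}$ — so the fitters work in the identifiable reduced forms
and report the conventional layouts; for these families curve agreement,
not coefficient agreement, is the contract. The activation parameters are
fitted by a bounded Nelder–Mead search (logistic reparameterization;
$\tau \in (0,10]$ s, $\beta \in (0,1]$, $a_0 \in [0,1)$, $g \in (0,20]$;
deterministic start $(1, 0.5, 0.5, 2)$ with simplex restarts) over forward
simulations of the saturating isometric episodes; $\beta$ is identifiable
only if the episodes include the post-stimulation decay.

`characterize_muscle()` chains the stages in the order the bench analysis
needs them: LT extraction → stiffness → series-elasticity-corrected LT
refit → FV and its inverse → force–frequency → activation.

## Cohort median selection

With few animals, averaging parameters can produce a model no real muscle
exhibits; instead the individual closest to the cohort median is selected
per curve family (`select_representative()`). Fitted curves are evaluated
on a shared grid (`build_grid()`: 0.001 spacing for lengths, 0.0005
$L_{mto}$/s for velocities; the force–frequency family uses the shared
measured frequencies directly), the pointwise median is taken (even cohort
sizes use the midpoint of the central pair — the cohort includes an even
case, so the convention must be fixed), the family is refitted to the
median, and the individual with the lowest sum of squared error to that
median fit wins; ties break to the lowest index.

## The synthetic experiment generator

No recordings were deposited with the characterization this package
implements, so the generator (`generate_protocol()`,
`synthesize_episode()`) reproduces the rig protocols from a known
ground-truth model and makes every pipeline stage testable by parameter
recovery:

* **force–frequency**: isometric trains at 2–38 Hz in 6 Hz steps, 5 s
  each;
* **length–tension**: 20 s ramps through offsets $0, -1, -1, 0, 1, \dots,
  8$ mm around the rest length, stimulation ($\ge$ 26 Hz, 5 s) 110 s after
  each ramp; the first two episodes are conditioning;
* **force–velocity**: paired passive/active 1 mm ramps at
  $\pm\{0.25, 0.5, 1, 2, 4, 8\}$ mm/s, the active ramp starting 5 s into a
  10 s train, 80 s after the passive phase begins.

Two desk-scale compressions keep a full protocol under a minute of
compute: traces are sampled at 500 Hz rather than the rig's 5 kHz (all
windows are defined in seconds or in samples-per-second, so nothing else
changes), and the 180 s inter-episode rests are realized as state resets —
the model is memoryless, so a rested start is exactly what a long rest
produces. Measurement noise is additive Gaussian on the force channel
(seed mandatory). An optional stress-relaxation transient (bounded by the
$\sim$350 mN transients seen on the rig) exists only for robustness
probes and is off by default, because the model deliberately excludes
passive viscoelasticity.

The EMG generator (`synthesize_emg_drive()`) produces a burst-modulated
band-limited carrier (a tone) plus an additive noise floor, returning the
true envelope for oracle tests. A broadband white-noise carrier is
deliberately avoided: peak-interpolation envelope estimators are
intrinsically biased low on broadband carriers (window maxima sit well
below the one global peak), and real EMG interference is much closer to
narrow-band.

**What recovery on these data does and does not show.** The generator
shares the model family with the fitter, has no stress relaxation,
fatigue, electrode drift, or history-dependent force depression, and its
noise is white. Passing recovery therefore validates the pipeline's
correctness — windows, corrections, constraints, estimators — not the
model's adequacy for real tissue.

Three composition effects of the published model matter when judging
recovery, and the tests account for them:

* at low stimulation frequency the activation threshold $a_0$ zeroes the
  force entirely (steady activation reaches 0 below $\sim$10 Hz), so the
  measurable force–frequency relation is the *composed* steady-state
  response, not the raw input sigmoid; recovery is judged against the
  composed curve;
* the measurable active LT relation in total-length coordinates is the
  composed curve of `Y` through the series-elastic equilibrium; again the
  oracle is the composed curve;
* the assembled model's force–velocity behavior *is* the inverse of its
  double-exponential `E` (the shipped `E` is not consistent with any of
  the per-animal hyperbola fits), so force–velocity recovery and the
  in-silico loop closure are judged against that effective relation,
  computed by root finding.

A related propagation effect: fitting the activation parameters against
the pipeline-recovered kinetics (rather than the true ones) lets the
activation stage absorb small upstream curve biases ($\tau$ drifts
$+15\%$, $\beta$ $+50\%$ while the force fit *improves*). This is a real
property of the sequential identification, worth remembering when
interpreting activation constants fitted downstream of fitted curves.

## Validation utilities

`emg_envelope()` rectifies, normalizes, and linearly interpolates across
peaks separated by at least `min_separation` samples (kept in samples, as
the 5 kHz-rate convention of 1000 samples = 0.2 s implies), inserting
knots wherever the interpolant would dip below the signal so the envelope
is a true upper bound. `fit_emg_scale()` finds the scalar mapping the
normalized envelope to a stimulation-frequency drive by golden-section
search on the force MSE; any residual lead/lag is estimated by
cross-correlation and *reported*, never silently applied.
`one_sample_t_test()` and `summarize_cohort()` implement the cohort
comparisons against the I2 protractor reference values (the only published
I2 quantities shipped: $F_{mto} = 0.15$ N, $K_t = 5$, $\tau = 2.45$ s,
$\tau/\beta = 3.48$ s).

## Problem sizes and determinism

The test suite and the acceptance script synthesize full protocols at
500 Hz (7 force–frequency, 12 length–tension, 12 force–velocity episodes;
about 1.8 million samples per full run), run the complete pipeline
noiselessly and with 10 mN force noise, and fit activation parameters on
the three saturating trains. Every fit is deterministic given its inputs;
the only randomness is the seeded measurement noise.

## Known limitations

* No history dependence: force depression after shortening and transient
  passive viscoelasticity are deliberately outside the model, so it
  under-predicts the steady-state force drop after shortening.
* The inverse-FV double exponential cannot reproduce the hyperbolic FV
  pair to better than $\approx$2.5% velocity error over
  $[-0.25, 0.5]\,L_{mto}$/s — a family-capability limit that also makes
  the assembled model slightly inconsistent at the isometric point
  ($\mathrm{IFV}(1) = -0.0018$).
* The activation clamp $0 < a \le 1$ makes the model fully silent below
  $\sim$10 Hz stimulation, although the real muscle produces small forces
  there.
* Spatial innervation (the anterior-jaw region driven separately), fatigue
  and neuromodulation of the neuromuscular transform are not modeled.
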