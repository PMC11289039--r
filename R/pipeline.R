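#' Characterize one muscle from its three experiment types
#'
#' Runs the full single-muscle identification pipeline in the order the
#' bench analysis uses it:
#' \enumerate{
#'   \item length-tension extraction: per-muscle peak force `F_mto_e` and
#'     optimal length `L_mto_e`, passive exponential `C` with threshold,
#'     and the constrained active cubic `B` in total-length coordinates;
#'   \item series stiffness `K_t` from the force-rise slopes of the
#'     isokinetic episodes regressed on ramp velocity;
#'   \item series-elasticity correction of the active length-tension
#'     abscissae and constrained refit to obtain `Y`;
#'   \item force-velocity extraction with the `B` and `K_t` just
#'     estimated, hyperbolic fit `D` and inverse double-exponential `E`;
#'   \item force-frequency extraction and sigmoid fit `A`;
#'   \item activation parameters `(tau, beta, a0, g)` optimized against
#'     the saturating isometric episodes (optional, the slow step).
#' }
#'
#' @param ff_traces,lt_traces,fv_traces Lists of `episode_trace`s from the
#'   force-frequency, length-tension and force-velocity protocols of one
#'   muscle.
#' @param fit_activation Whether to run the activation-parameter
#'   optimization (forward simulations; the slow step).
#' @param activation_min_hz Only isometric episodes at or above this
#'   stimulation frequency are used for the activation fit.
#' @param seed_params Parameter set supplying the activation starting
#'   model structure and any fields not identified here; defaults to the
#'   bundled I1/I3 model.
#' @param ... Passed to [fit_activation_parameters()].
#' @return List with `params` (a [hill_parameters()] object assembled from
#'   the fitted components), the per-stage `fits`, and the extracted
#'   `points`.
#' @export
characterize_muscle <- function(ff_traces, lt_traces, fv_traces,
                                fit_activation = TRUE,
                                activation_min_hz = 26,
                                seed_params = hill_parameters_i1i3(), ...) {
  # stage 1: length-tension
  lt_points <- extract_lt_points(lt_traces)
  F_mto_e <- attr(lt_points, "F_mto_e")
  L_mto_e <- attr(lt_points, "L_mto_e")
  fit_B <- fit_active_lt_constrained(lt_points$l_mt_norm, lt_points$LT_e)
  fit_C <- fit_passive_lt(lt_points$l_mt_norm, lt_points$f_pe_e)

  # stage 2: series stiffness from the isokinetic force-rise slopes,
  # evaluated at the ramp start where the contractile velocity vanishes
  stiff_pts <- do.call(rbind, lapply(fv_traces, function(tr) {
    rise <- active_force_rise_slope(tr, tr,
                                    eval_time = stiffness_eval_time(tr))
    data.frame(V_mt = tr$meta$V_mt, dFCE_dt = rise$slope)
  }))
  kt_fit <- estimate_series_stiffness(stiff_pts, F_mto = F_mto_e,
                                      L_mto = L_mto_e)

  # stage 3: contractile-element length-tension
  l_m <- shift_to_contractile_length(lt_points$l_mt_norm, lt_points$LT_e,
                                     kt_fit$K_t)
  fit_Y <- fit_active_lt_constrained(l_m, lt_points$LT_e)

  # stage 4: force-velocity and its inverse
  fv_points <- extract_fv_points(fv_traces, B = fit_B$coefficients,
                                 K_t = kt_fit$K_t, L_mto = L_mto_e)
  fit_D <- fit_fv_piecewise(fv_points$v_m_norm, fv_points$fv)
  fit_E <- fit_inverse_fv(fv_points$fv, fv_points$v_m_norm)

  # stage 5: force-frequency
  ff_points <- normalize_ff_series(
    do.call(rbind, lapply(ff_traces, function(tr) {
      as.data.frame(extract_ff_point(tr))
    }))
  )
  fit_A <- fit_force_frequency(ff_points$f_stim, ff_points$u_f_e)

  params <- hill_parameters(
    F_mto = F_mto_e, L_mto = L_mto_e,
    L_0 = seed_params$L_0, L_st = 0, K_t = kt_fit$K_t,
    A = fit_A$coefficients, B = fit_B$coefficients,
    Y = fit_Y$coefficients, C = fit_C$coefficients,
    l_pe_threshold = fit_C$diagnostics$threshold,
    D = fit_D$coefficients, E = fit_E$coefficients,
    tau = seed_params$tau, beta = seed_params$beta,
    a0 = seed_params$a0, g = seed_params$g
  )

  fit_act <- NULL
  if (fit_activation) {
    sat <- Filter(function(tr) tr$meta$stim_hz >= activation_min_hz, ff_traces)
    if (length(sat) == 0L) stop("no saturating episodes for the activation fit")
    fit_act <- fit_activation_parameters(params, sat, ...)
    params$tau <- unname(fit_act$coefficients["tau"])
    params$beta <- unname(fit_act$coefficients["beta"])
    params$a0 <- unname(fit_act$coefficients["a0"])
    params$g <- unname(fit_act$coefficients["g"])
  }

  list(
    params = validate_hill_parameters(params),
    fits = list(A = fit_A, B = fit_B, C = fit_C, Y = fit_Y,
                D = fit_D, E = fit_E, K_t = kt_fit, activation = fit_act),
    points = list(ff = ff_points, lt = lt_points, fv = fv_points,
                  stiffness = stiff_pts)
  )
}
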