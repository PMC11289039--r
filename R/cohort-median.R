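# Median-individual identification.  Each individual's fitted curve is
# evaluated on a shared grid, the pointwise median is taken, the family's
# curve is refitted to the median, and the individual whose fitted curve is
# closest (lowest sum of squared error on the grid) to that median fit is
# selected as the representative.

.family_predict <- function(family, fit, x) {
  cf <- if (inherits(fit, "fit_result")) fit$coefficients else fit
  switch(family,
         ff = force_frequency_response(x, cf),
         lt_active = active_length_tension(x, cf),
         lt_passive = {
           thr <- if (inherits(fit, "fit_result") &&
                      !is.null(fit$diagnostics$threshold)) {
             fit$diagnostics$threshold
           } else 0.87
           passive_length_tension(x, cf, thr)
         },
         fv = force_velocity(x, cf),
         ifv = inverse_force_velocity(x, cf),
         stop("unknown curve family: ", family))
}

.family_fit <- function(family, x, y) {
  switch(family,
         ff = fit_force_frequency(x, y),
         lt_active = fit_active_lt_constrained(x, y),
         lt_passive = fit_passive_lt(x, y),
         fv = fit_fv_piecewise(x, y),
         ifv = fit_inverse_fv(y, x),  # (fv, v) argument order
         stop("unknown curve family: ", family))
}

#' Build the shared interpolation grid for a curve family
#'
#' Lengths use a spacing of 0.001 (in units of the optimal length),
#' velocities a spacing of 0.0005 optimal lengths per second.  The
#' force-frequency family needs no interpolation because every animal is
#' measured at the same frequencies: the measured frequency set is returned
#' unchanged.
#'
#' @param family One of `"ff"`, `"lt_active"`, `"lt_passive"`, `"fv"`,
#'   `"ifv"`.
#' @param data_min,data_max Range of the independent variable across all
#'   individuals (ignored for `"ff"`).
#' @param frequencies Measured frequency set, required for `"ff"`.
#' @return Numeric grid.
#' @export
build_grid <- function(family, data_min = NULL, data_max = NULL,
                       frequencies = NULL) {
  if (family == "ff") {
    if (is.null(frequencies)) stop("the force-frequency grid is the measured frequency set")
    return(sort(unique(frequencies)))
  }
  if (is.null(data_min) || is.null(data_max) || data_min >= data_max) {
    stop("need data_min < data_max for the interpolation grid")
  }
  spacing <- switch(family,
                    lt_active = , lt_passive = 0.001,
                    fv = , ifv = 0.0005,
                    stop("unknown curve family: ", family))
  seq(data_min, data_max, by = spacing)
}

#' Pointwise median of a set of curves on a shared grid
#'
#' @param curves Matrix with one row per individual and one column per grid
#'   point (a single curve may be given as a vector).
#' @return The per-grid-point median; even cohort sizes use the midpoint of
#'   the two central values.
#' @export
pointwise_median <- function(curves) {
  if (is.vector(curves)) curves <- matrix(curves, nrow = 1)
  if (nrow(curves) < 1L) stop("need at least one curve")
  apply(curves, 2, stats::median)
}

#' Select the representative (closest-to-median) individual
#'
#' Evaluates each individual's fitted curve on the grid, fits the family's
#' curve to the pointwise median, and returns the individual whose curve
#' has the lowest sum of squared error to the median fit on the grid.
#' Ties are broken by the lowest index.
#'
#' @param fits List of per-individual fits (`fit_result` objects or bare
#'   coefficient vectors).
#' @param grid Shared grid from [build_grid()].
#' @param family Curve family, see [build_grid()].
#' @param median_curve Optional precomputed median curve on the grid;
#'   computed from the fits when omitted.
#' @return List with `index` (winning individual), `sse` (per-individual
#'   SSE table), `median_fit` (a `fit_result` for the median curve) and
#'   `median_curve`.
#' @export
select_representative <- function(fits, grid, family, median_curve = NULL) {
  if (length(fits) < 1L) stop("need at least one individual")
  curves <- t(vapply(fits, function(f) .family_predict(family, f, grid),
                     numeric(length(grid))))
  if (is.null(median_curve)) median_curve <- pointwise_median(curves)
  median_fit <- .family_fit(family, grid, median_curve)
  med_pred <- .family_predict(family, median_fit, grid)
  sse <- apply(curves, 1, function(cv) sum((cv - med_pred)^2))
  list(index = which.min(sse), sse = sse,
       median_fit = median_fit, median_curve = median_curve)
}
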