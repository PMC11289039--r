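#' Hill-type muscle model parameters
#'
#' Bundle of all constants defining one Hill-type muscle model of the
#' I1/I3 (or a comparable) muscle: scaling constants, the coefficient
#' vectors of the five constitutive curves, and the activation-dynamics
#' parameters.  Forces are normalized by the peak active isometric force
#' `F_mto` and lengths/velocities by the optimal length `L_mto`, so all
#' curve coefficients live in normalized coordinates.
#'
#' @param F_mto Peak active isometric force (N).
#' @param L_mto Optimal muscle length, where the peak active force occurs (mm).
#' @param L_0 Rest length of the muscle (mm).
#' @param L_st Slack length of the series elastic element (mm); unmeasurable
#'   in this muscle and fixed at 0.
#' @param K_t Normalized series-elastic stiffness (units of `F_mto` per
#'   `L_mto`).
#' @param A Length-4 force-frequency sigmoid coefficients; `A[3]` has units
#'   1/Hz and `A[4]` Hz.
#' @param B Length-4 active length-tension cubic coefficients in the
#'   normalized total muscle length.
#' @param Y Length-4 active length-tension cubic coefficients in the
#'   normalized contractile-element length (series-elasticity corrected).
#' @param C Length-4 passive length-tension exponential coefficients.
#' @param l_pe_threshold Normalized length below which passive force is zero.
#' @param D Length-4 piecewise-hyperbola force-velocity coefficients;
#'   `D[2] > 0` and `D[4] > 0`.
#' @param E Length-5 inverse force-velocity double-exponential coefficients.
#' @param tau Activation time constant at full neural drive (s).
#' @param beta Ratio of activation to relaxation time constant, in (0, 1];
#'   the relaxation time constant is `tau/beta`.
#' @param a0 Activation offset (threshold) applied to the pre-scaling
#'   activation state.
#' @param g Activation gain.
#'
#' @return An object of class `hill_parameters` (a validated list).
#' @seealso [read_hill_parameters()], [hill_parameters_i1i3()]
#' @export
hill_parameters <- function(F_mto, L_mto, L_0, L_st = 0, K_t,
                            A, B, Y, C, l_pe_threshold = 0.87,
                            D, E, tau, beta, a0, g) {
  p <- list(
    F_mto = as.numeric(F_mto), L_mto = as.numeric(L_mto),
    L_0 = as.numeric(L_0), L_st = as.numeric(L_st), K_t = as.numeric(K_t),
    A = as.numeric(A), B = as.numeric(B), Y = as.numeric(Y),
    C = as.numeric(C), l_pe_threshold = as.numeric(l_pe_threshold),
    D = as.numeric(D), E = as.numeric(E),
    tau = as.numeric(tau), beta = as.numeric(beta),
    a0 = as.numeric(a0), g = as.numeric(g)
  )
  class(p) <- "hill_parameters"
  validate_hill_parameters(p)
}

#' Validate a set of Hill model parameters
#'
#' Checks lengths, finiteness and the sign constraints that the model
#' relies on (positive scales, positive hyperbola pole offsets, activation
#' parameters in range).  Called by [hill_parameters()]; exported so that
#' parameter files read from disk can be checked explicitly.
#'
#' @param p A `hill_parameters` object or a bare list with the same fields.
#' @return The validated object, invisibly classed as `hill_parameters`.
#' @export
validate_hill_parameters <- function(p) {
  need <- c("F_mto", "L_mto", "L_0", "L_st", "K_t", "A", "B", "Y", "C",
            "l_pe_threshold", "D", "E", "tau", "beta", "a0", "g")
  missing <- setdiff(need, names(p))
  if (length(missing) > 0L) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  }
  len <- c(A = 4L, B = 4L, Y = 4L, C = 4L, D = 4L, E = 5L)
  for (nm in names(len)) {
    if (length(p[[nm]]) != len[[nm]]) {
      stop(sprintf("coefficient vector %s must have length %d", nm, len[[nm]]))
    }
  }
  scalars <- c("F_mto", "L_mto", "L_0", "L_st", "K_t", "l_pe_threshold",
               "tau", "beta", "a0", "g")
  for (nm in c(scalars, "A", "B", "Y", "C", "D", "E")) {
    if (!all(is.finite(p[[nm]]))) {
      stop("non-finite value in parameter field ", nm)
    }
  }
  stopifnot(
    "F_mto must be > 0" = p$F_mto > 0,
    "L_mto must be > 0" = p$L_mto > 0,
    "K_t must be > 0" = p$K_t > 0,
    "tau must be > 0" = p$tau > 0,
    "beta must be in (0, 1]" = p$beta > 0 && p$beta <= 1,
    "g must be > 0" = p$g > 0,
    "D[2] must be > 0" = p$D[2] > 0,
    "D[4] must be > 0" = p$D[4] > 0
  )
  class(p) <- "hill_parameters"
  invisible(p)
}

#' @export
print.hill_parameters <- function(x, ...) {
  cat("Hill-type muscle model parameters\n")
  cat(sprintf("  scales:      F_mto = %.3g N, L_mto = %.4g mm, L_0 = %.4g mm, L_st = %g mm\n",
              x$F_mto, x$L_mto, x$L_0, x$L_st))
  cat(sprintf("  series:      K_t = %.4g (F_mto/L_mto)\n", x$K_t))
  cat(sprintf("  activation:  tau = %.3g s, beta = %.3g (tau/beta = %.3g s), a0 = %.3g, g = %.3g\n",
              x$tau, x$beta, x$tau / x$beta, x$a0, x$g))
  fmt <- function(v) paste0("[", paste(formatC(v, format = "g"), collapse = ", "), "]")
  cat("  A (force-frequency):     ", fmt(x$A), "\n")
  cat("  B (active LT, l_mt):     ", fmt(x$B), "\n")
  cat("  Y (active LT, l_m):      ", fmt(x$Y), "\n")
  cat("  C (passive LT), thresh:  ", fmt(x$C), sprintf(" below %.3g -> 0\n", x$l_pe_threshold))
  cat("  D (force-velocity):      ", fmt(x$D), "\n")
  cat("  E (inverse FV):          ", fmt(x$E), "\n")
  invisible(x)
}

#' Read / write model parameters as JSON
#'
#' The on-disk format is a flat JSON object whose keys name the fields of
#' [hill_parameters()] exactly.  Two parameter files ship with the package
#' (see [hill_parameters_i1i3()] and [hill_parameters_i2()]).
#'
#' @param path Path to a JSON parameter file.
#' @return For `read_hill_parameters`, a validated `hill_parameters` object.
#' @export
read_hill_parameters <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- raw[intersect(names(raw), names(formals(hill_parameters)))]
  do.call(hill_parameters, raw)
}

#' @rdname read_hill_parameters
#' @param p A `hill_parameters` object.
#' @export
write_hill_parameters <- function(p, path) {
  validate_hill_parameters(p)
  x <- unclass(p)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Bundled I1/I3 "best median" model
#'
#' The complete fitted model of the I1/I3 retractor complex assembled from
#' the representative (closest-to-median) individuals of each
#' characterization experiment, as shipped in
#' `inst/extdata/i1i3_best_median.json`.
#'
#' @return A `hill_parameters` object.
#' @export
hill_parameters_i1i3 <- function() {
  read_hill_parameters(system.file("extdata", "i1i3_best_median.json",
                                   package = "aplysiahill", mustWork = TRUE))
}

#' Bundled I2 reference parameter set
#'
#' Reference values for the I2 protractor muscle used for between-muscle
#' comparisons: peak isometric force 0.15 N, normalized series stiffness 5,
#' activation time constant 2.45 s and relaxation time constant 3.48 s.
#' The curve coefficient vectors in this file are placeholders copied from
#' the I1/I3 model (the I2 curve fits are not redistributed here); only the
#' four scalar reference values above should be quoted as I2 properties.
#'
#' @return A `hill_parameters` object.
#' @export
hill_parameters_i2 <- function() {
  read_hill_parameters(system.file("extdata", "i2_reference.json",
                                   package = "aplysiahill", mustWork = TRUE))
}
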