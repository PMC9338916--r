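#' Adaptive Runge-Kutta reference solution
#'
#' Integrates the full nonlinear Michaelis-Menten system with an embedded
#' Dormand-Prince 4(5) pair (`deSolve`'s `"ode45"` method) at the given
#' tolerances. This is the accuracy oracle for the inductive
#' linearization solver and the simulation engine for noisy observations.
#'
#' @param theta A [pk_params()] object.
#' @param dose Dose amount (mg) in the depot at t = 0.
#' @param times Requested output times (h), non-negative and
#'   non-decreasing.
#' @param atol Absolute tolerance (mg); default `1e-6`.
#' @param rtol Relative tolerance; default `1e-3`.
#' @param full If `TRUE`, return a data frame with the full state
#'   (`time_h`, `depot_mg`, `central_mg`, `conc_mg_L`) instead of the
#'   concentration vector.
#' @return Concentrations (mg/L) at `times`, or a data frame if
#'   `full = TRUE`.
#' @export
reference_solve <- function(theta, dose, times, atol = 1e-6, rtol = 1e-3,
                            full = FALSE) {
  theta <- as_pk_params(theta)
  stopifnot(is.numeric(times), all(is.finite(times)), all(times >= 0),
            !is.unsorted(times), dose > 0, atol > 0, rtol > 0)
  tt <- sort(unique(c(0, times)))
  rhs <- function(t, y, p) list(mm_rhs(p, y, t))
  out <- deSolve::ode(y = c(depot = dose, central = 0), times = tt,
                      func = rhs, parms = theta, method = "ode45",
                      atol = atol, rtol = rtol)
  if (nrow(out) != length(tt) || any(!is.finite(out))) {
    stop("reference Runge-Kutta integration failed", call. = FALSE)
  }
  if (full) {
    return(data.frame(time_h = out[, "time"], depot_mg = out[, "depot"],
                      central_mg = out[, "central"],
                      conc_mg_L = out[, "central"] / theta[["V"]]))
  }
  conc <- out[, "central"] / theta[["V"]]
  conc[match(times, tt)]
}
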