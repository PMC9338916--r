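#' Michaelis-Menten model parameters
#'
#' Container for the four constants of the one-compartment extravascular
#' model with saturable (Michaelis-Menten) elimination. Defaults are the
#' nominal values used throughout the package examples.
#'
#' @param ka First-order absorption rate constant (/h).
#' @param V Apparent volume of distribution (L).
#' @param Vmax Maximum elimination velocity (mg/h).
#' @param Km Michaelis-Menten constant (mg/L), the concentration at which
#'   elimination runs at half its maximal rate.
#'
#' @return A named numeric vector of class `pk_params` with elements
#'   `ka`, `V`, `Vmax`, `Km`.
#' @examples
#' theta <- pk_params()
#' theta[["Km"]]
#' @export
pk_params <- function(ka = 1, V = 1, Vmax = 0.2, Km = 0.5) {
  theta <- c(ka = as.numeric(ka), V = as.numeric(V),
             Vmax = as.numeric(Vmax), Km = as.numeric(Km))
  if (any(!is.finite(theta)) || any(theta <= 0)) {
    stop("all parameters (ka, V, Vmax, Km) must be strictly positive and finite",
         call. = FALSE)
  }
  structure(theta, class = "pk_params")
}

#' Coerce a numeric vector to `pk_params`
#'
#' Accepts a `pk_params` object, a named numeric vector containing
#' `ka`, `V`, `Vmax`, `Km`, or an unnamed length-4 vector in that order.
#'
#' @param x Object to coerce.
#' @return A `pk_params` object.
#' @export
as_pk_params <- function(x) {
  if (inherits(x, "pk_params")) return(x)
  x <- unlist(x)
  if (!is.numeric(x) || length(x) != 4L) {
    stop("expected four numeric parameter values (ka, V, Vmax, Km)", call. = FALSE)
  }
  if (!is.null(names(x)) && all(c("ka", "V", "Vmax", "Km") %in% names(x))) {
    pk_params(x[["ka"]], x[["V"]], x[["Vmax"]], x[["Km"]])
  } else {
    pk_params(x[[1L]], x[[2L]], x[[3L]], x[[4L]])
  }
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Michaelis-Menten PK parameters:\n")
  cat(sprintf("  ka   = %g /h\n  V    = %g L\n  Vmax = %g mg/h\n  Km   = %g mg/L\n",
              x[["ka"]], x[["V"]], x[["Vmax"]], x[["Km"]]))
  invisible(x)
}

#' Nominal single-dose sampling design
#'
#' The 13-sample design used in the package's worked examples: a single
#' 3 mg oral dose at time 0 with rich sampling out to 30 h.
#'
#' @return A list with elements `times` (h) and `dose` (mg).
#' @export
nominal_design <- function() {
  list(times = c(0.1, 0.25, 0.5, 0.75, 1, 2, 4, 6, 8, 12, 16, 24, 30),
       dose = 3)
}

#' Right-hand side of the nonlinear Michaelis-Menten system
#'
#' The model is written in amounts: `y1` is the depot amount (mg) and
#' `y2` the central-compartment amount (mg), with observed concentration
#' `C = y2 / V` (mg/L). The dose enters through the initial state
#' `(D, 0)`, not the right-hand side.
#'
#' \deqn{dy_1/dt = -k_a y_1, \quad
#'       dy_2/dt = k_a y_1 - \frac{V_{max} C}{K_m + C}}
#'
#' @param theta A [pk_params()] object.
#' @param state Numeric length-2 state `(y1, y2)` in mg.
#' @param t Time (h); the system is autonomous so `t` is unused, kept for
#'   a standard ODE right-hand-side signature.
#' @return Numeric length-2 derivative (mg/h).
#' @export
mm_rhs <- function(theta, state, t = 0) {
  theta <- as_pk_params(theta)
  if (length(state) != 2L || any(!is.finite(state))) {
    stop("state must be a finite length-2 vector (depot mg, central mg)", call. = FALSE)
  }
  conc <- state[2L] / theta[["V"]]
  absorb <- theta[["ka"]] * state[1L]
  c(-absorb, absorb - theta[["Vmax"]] * conc / (theta[["Km"]] + conc))
}

#' Rate matrix of the linearized Michaelis-Menten system
#'
#' Builds the 2x2 rate matrix of the linear time-varying system obtained
#' by plugging the previous iterate's concentration into the saturable
#' elimination term:
#' \deqn{K = \begin{bmatrix} -k_a & 0 \\
#'       k_a & -\frac{1}{V}\frac{V_{max}}{K_m + C^{prev}} \end{bmatrix}}
#' With `c_prev = 0` (the cold-start plug-in) the elimination entry is the
#' constant `-Vmax/(V Km)` and the system is an ordinary first-order
#' absorption/elimination cascade.
#'
#' @param theta A [pk_params()] object.
#' @param c_prev Plug-in concentration (mg/L), `>= 0`.
#' @return A 2x2 lower-triangular rate matrix (/h).
#' @export
build_K <- function(theta, c_prev) {
  theta <- as_pk_params(theta)
  if (!is.numeric(c_prev) || length(c_prev) != 1L || !is.finite(c_prev) || c_prev < 0) {
    stop("c_prev must be a single finite non-negative concentration", call. = FALSE)
  }
  ka <- theta[["ka"]]
  k20 <- theta[["Vmax"]] / (theta[["V"]] * (theta[["Km"]] + c_prev))
  matrix(c(-ka, ka, 0, -k20), nrow = 2L, ncol = 2L)
}

# Vectorized internal form of build_K: one 2x2 slice per grid interval.
# Tiny negative plug-in concentrations (numerical floor) are clamped to 0.
k_cube <- function(theta, c_left) {
  c_left <- pmax(c_left, 0)
  n <- length(c_left)
  Ks <- array(0, dim = c(2L, 2L, n))
  Ks[1L, 1L, ] <- -theta[["ka"]]
  Ks[2L, 1L, ] <- theta[["ka"]]
  Ks[2L, 2L, ] <- -theta[["Vmax"]] / (theta[["V"]] * (theta[["Km"]] + c_left))
  Ks
}

#' Bateman closed-form concentration profile
#'
#' Exact solution of the linear first-order absorption / first-order
#' elimination cascade, used as the analytic oracle for the constant-K
#' first iterate of the inductive linearization (where the effective
#' elimination rate constant is `k10 = Vmax / (V * Km)`):
#' \deqn{C(t) = \frac{k_a D}{V (k_a - k_{10})}
#'       \left(e^{-k_{10} t} - e^{-k_a t}\right)}
#'
#' @param theta A [pk_params()] object supplying `ka` and `V`.
#' @param dose Dose amount D (mg).
#' @param t Time(s) (h), `>= 0`.
#' @param k10 First-order elimination rate constant (/h); defaults to the
#'   low-concentration limit `Vmax / (V * Km)` of the saturable model.
#' @return Concentration(s) (mg/L).
#' @export
bateman <- function(theta, dose, t, k10 = NULL) {
  theta <- as_pk_params(theta)
  if (is.null(k10)) k10 <- theta[["Vmax"]] / (theta[["V"]] * theta[["Km"]])
  stopifnot(is.numeric(t), all(t >= 0), dose > 0, k10 > 0)
  ka <- theta[["ka"]]
  if (abs(ka - k10) < 1e-12 * max(ka, k10)) {
    stop("bateman() is degenerate at ka == k10 (confluent case not supported)",
         call. = FALSE)
  }
  ka * dose / (theta[["V"]] * (ka - k10)) * (exp(-k10 * t) - exp(-ka * t))
}
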