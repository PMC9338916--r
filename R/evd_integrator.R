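#' Single matrix-exponential propagation step
#'
#' Computes `exp(K * dt) %*% state` by eigendecomposition of the rate
#' matrix `K`. When `K` is (near-)defective -- eigenvector matrix singular
#' or with condition number above `cond_max` -- the step falls back to a
#' scaling-and-squaring matrix exponential, so the result is always
#' defined.
#'
#' @param K Square, finite rate matrix (/h).
#' @param dt Step length (h), `>= 0`.
#' @param state Numeric state vector, one element per row of `K`.
#' @param cond_max Eigenvector condition-number threshold above which the
#'   scaling-and-squaring fallback is used. Default `1e8`.
#' @return The propagated state vector.
#' @export
step_expm <- function(K, dt, state, cond_max = 1e8) {
  if (!is.matrix(K) || nrow(K) != ncol(K) || any(!is.finite(K))) {
    stop("K must be a finite square matrix", call. = FALSE)
  }
  stopifnot(is.numeric(dt), length(dt) == 1L, dt >= 0,
            length(state) == nrow(K), all(is.finite(state)))
  as.numeric(step_expm_cpp(K, dt, as.numeric(state), cond_max))
}

#' Propagate a piecewise-constant linear system over a step grid
#'
#' Applies [step_expm()] sequentially: one rate matrix per grid interval,
#' each held constant across its interval. This is the integrator for the
#' linear time-varying systems produced by inductive linearization, where
#' the grid is fine enough that per-interval time invariance is an
#' acceptable approximation.
#'
#' @param Ks Rate matrices, either a `m x m x n_intervals` array or a list
#'   of `m x m` matrices, one per interval.
#' @param grid A `step_grid` from [fixed_grid()] or [adaptive_grid()], or
#'   a numeric vector of node times.
#' @param y0 Initial state at the first node.
#' @param cond_max Passed to the per-step propagator; see [step_expm()].
#' @return A `m x n_nodes` matrix of states, first column `y0`.
#' @export
propagate <- function(Ks, grid, y0, cond_max = 1e8) {
  times <- if (inherits(grid, "step_grid")) grid$times else as.numeric(grid)
  if (is.list(Ks)) {
    m <- length(y0)
    Ks <- array(unlist(Ks), dim = c(m, m, length(Ks)))
  }
  n_int <- length(times) - 1L
  if (dim(Ks)[3L] != n_int) {
    stop("need exactly one rate matrix per grid interval", call. = FALSE)
  }
  stopifnot(all(is.finite(y0)))
  traj <- propagate_cpp(Ks, diff(times), as.numeric(y0), cond_max)
  if (!all(is.finite(traj))) {
    stop("propagation produced non-finite states", call. = FALSE)
  }
  traj
}

# Internal step-grid constructor: sorts, merges nodes closer than `tol`
# (avoiding zero-length steps from output-time unions), and snaps the
# surviving node of each merged cluster onto the requested output time so
# later lookups are exact.
new_step_grid <- function(nodes, output_times = numeric(), tol = 1e-12) {
  nodes <- sort(as.numeric(nodes))
  keep <- c(TRUE, diff(nodes) > tol)
  nodes <- nodes[keep]
  output_times <- sort(unique(as.numeric(output_times)))
  for (ot in output_times) {
    j <- which.min(abs(nodes - ot))
    if (abs(nodes[j] - ot) <= tol) nodes[j] <- ot
  }
  nodes <- unique(nodes)
  structure(list(times = nodes, is_output = nodes %in% output_times),
            class = "step_grid")
}

#' @export
print.step_grid <- function(x, ...) {
  cat(sprintf("step grid: %d nodes on [%g, %g], %d output times, max step %g h\n",
              length(x$times), x$times[1L], x$times[length(x$times)],
              sum(x$is_output), max(diff(x$times))))
  invisible(x)
}

#' Build a fixed-step integration grid
#'
#' Nodes are the union of the uniform grid `{0, ss, 2 ss, ...}`, the
#' horizon `T`, and every requested output time, sorted and de-duplicated
#' (nodes closer than `1e-12` h are merged).
#'
#' @param ss Step size (h), `> 0`.
#' @param T Integration horizon (h), `> 0`.
#' @param output_times Times (h) that must appear as grid nodes; all in
#'   `[0, T]`.
#' @return A `step_grid` object with fields `times` and `is_output`.
#' @export
fixed_grid <- function(ss, T, output_times = numeric()) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0) {
    stop("integration horizon T must be a single positive time", call. = FALSE)
  }
  stopifnot(is.numeric(ss), length(ss) == 1L, ss > 0)
  output_times <- as.numeric(output_times)
  if (length(output_times) &&
      (min(output_times) < 0 || max(output_times) > T + 1e-12)) {
    stop("output times must lie in [0, T]", call. = FALSE)
  }
  new_step_grid(c(seq(0, T, by = ss), T, output_times), output_times)
}

#' Adaptive step-size configuration
#'
#' Settings for the slope-based adaptive grid: the local step size is
#' `alpha / |dy*/dt|`, clipped to `[ss_min, ss_max]`, where `dy*/dt` is
#' the finite-difference slope of the first-iterate (constant-K) observed
#' trajectory. The step is therefore smallest where the response changes
#' fastest. The clip is required because the raw rule is unbounded where
#' the slope vanishes (e.g. at the concentration peak).
#'
#' @param alpha Step-scale factor; default 0.01 (in the model's h and
#'   mg/L units, treated as a raw numeric recipe).
#' @param ss_min Smallest allowed step (h).
#' @param ss_max Largest allowed step (h).
#' @return A list of class `step_spec` with `type = "adaptive"`.
#' @export
step_adaptive <- function(alpha = 0.01, ss_min = 1e-4, ss_max = 1) {
  stopifnot(alpha > 0, ss_min > 0, ss_min <= ss_max)
  structure(list(type = "adaptive", alpha = alpha,
                 ss_min = ss_min, ss_max = ss_max), class = "step_spec")
}

#' Fixed step-size configuration
#'
#' @param ss Step size (h), `> 0`.
#' @return A list of class `step_spec` with `type = "fixed"`.
#' @export
step_fixed <- function(ss = 0.01) {
  stopifnot(ss > 0)
  structure(list(type = "fixed", ss = ss), class = "step_spec")
}

#' Build an adaptive integration grid from a bootstrap trajectory
#'
#' Implements the inverse-slope step-size rule: starting at 0, each step
#' is `clip(alpha / |slope(t)|, ss_min, ss_max)` with the slope taken
#' from the bootstrap trajectory by central finite differences and linear
#' interpolation. The resulting nodes are merged with the requested
#' output times. For multiple observed variables, supply the
#' minimum-step (largest-|slope|) trajectory.
#'
#' @param bootstrap A list or data frame with numeric `time` and `value`
#'   for the observed variable of the first (constant-K) iterate,
#'   covering `[0, T]`.
#' @param config A [step_adaptive()] specification.
#' @param T Integration horizon (h).
#' @param output_times Times (h) that must appear as grid nodes.
#' @return A `step_grid` object.
#' @export
adaptive_grid <- function(bootstrap, config, T, output_times = numeric()) {
  stopifnot(inherits(config, "step_spec"), identical(config$type, "adaptive"))
  tb <- as.numeric(bootstrap$time)
  vb <- as.numeric(bootstrap$value)
  if (length(tb) < 3L || max(tb) < T - 1e-9) {
    stop("bootstrap trajectory must cover [0, T] with at least 3 points",
         call. = FALSE)
  }
  aslope <- abs(central_slope(tb, vb))
  if (all(aslope < .Machine$double.eps) && !is.finite(config$ss_max)) {
    stop("all-zero bootstrap slopes require a finite ss_max", call. = FALSE)
  }
  slope_at <- stats::approxfun(tb, aslope, rule = 2)
  nodes <- numeric(ceiling(T / config$ss_min) + 2L)
  nodes[1L] <- 0
  n <- 1L
  t <- 0
  while (t < T - 1e-12) {
    ss <- min(max(config$alpha / max(slope_at(t), 1e-300), config$ss_min),
              config$ss_max)
    t <- min(t + ss, T)
    n <- n + 1L
    nodes[n] <- t
  }
  new_step_grid(c(nodes[seq_len(n)], output_times), output_times)
}

# Central finite-difference slope on a (possibly non-uniform) time grid;
# one-sided at the ends.
central_slope <- function(t, v) {
  n <- length(t)
  s <- numeric(n)
  s[1L] <- (v[2L] - v[1L]) / (t[2L] - t[1L])
  s[n] <- (v[n] - v[n - 1L]) / (t[n] - t[n - 1L])
  if (n > 2L) {
    mid <- 2:(n - 1L)
    s[mid] <- (v[mid + 1L] - v[mid - 1L]) / (t[mid + 1L] - t[mid - 1L])
  }
  s
}
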