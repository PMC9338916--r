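#' Observed concentration-time dataset
#'
#' @param times Sampling times (h), strictly increasing and positive.
#' @param conc Observed concentrations (mg/L), strictly positive (the
#'   residual error model is lognormal).
#' @param dose Dose amount (mg) administered at t = 0.
#' @return A list of class `pk_dataset` with fields `times`, `conc`,
#'   `dose`.
#' @export
pk_dataset <- function(times, conc, dose) {
  times <- as.numeric(times); conc <- as.numeric(conc)
  if (length(times) != length(conc)) {
    stop("times and conc must have equal length", call. = FALSE)
  }
  if (any(times <= 0) || is.unsorted(times, strictly = TRUE)) {
    stop("sampling times must be strictly increasing and positive", call. = FALSE)
  }
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("observed concentrations must be finite and positive", call. = FALSE)
  }
  if (length(times) < 4L) {
    stop("need at least as many observations as parameters (4)", call. = FALSE)
  }
  stopifnot(is.numeric(dose), length(dose) == 1L, dose > 0)
  structure(list(times = times, conc = conc, dose = dose), class = "pk_dataset")
}

#' Read / write a dataset CSV
#'
#' The file has columns `time_h` and `conc_mg_L`; the dose is not stored
#' in the file and must be supplied (it comes from the run configuration).
#'
#' @param path CSV file path.
#' @param dose Dose amount (mg).
#' @return For `read_dataset`, a [pk_dataset()]; for `write_dataset`, the
#'   path invisibly.
#' @export
read_dataset <- function(path, dose) {
  df <- read.csv(path)
  if (!all(c("time_h", "conc_mg_L") %in% names(df))) {
    stop("dataset CSV must have columns time_h and conc_mg_L", call. = FALSE)
  }
  df <- df[order(df$time_h), , drop = FALSE]   # row order in the file is free
  pk_dataset(df$time_h, df$conc_mg_L, dose)
}

#' @rdname read_dataset
#' @param dataset A [pk_dataset()].
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "pk_dataset"))
  write.csv(data.frame(time_h = dataset$times, conc_mg_L = dataset$conc),
            path, row.names = FALSE)
  invisible(path)
}

#' Ordinary least squares objective function value
#'
#' `OFV = sum((observed - predicted)^2)`, in (mg/L)^2.
#'
#' @param observed,predicted Equal-length concentration series (mg/L).
#' @return Non-negative scalar.
#' @export
ofv <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted series must have equal length", call. = FALSE)
  }
  sum((observed - predicted)^2)
}

#' Estimation configuration
#'
#' Selects the solver back-end used for each objective evaluation and
#' the optimizer settings of the Levenberg-Marquardt search.
#'
#' @param solver `"reference"` (adaptive Runge-Kutta) or `"indlin"`.
#' @param indlin An [indlin_config()] used when `solver = "indlin"`.
#' @param smart_update If `TRUE`, each inductive-linearization call is
#'   warm-started from the converged prediction series of the previous
#'   objective evaluation instead of zeros (the first evaluation is
#'   always a cold start). Only meaningful for the indlin back-end.
#' @param theta0 Initial parameter vector for the search; defaults to
#'   the nominal [pk_params()].
#' @param max_fev Maximum number of objective (residual) evaluations.
#' @param ftol,ptol Levenberg-Marquardt relative termination tolerances
#'   on the sum of squares and the parameter step.
#' @param atol,rtol Tolerances of the reference solver back-end.
#' @return A list of class `estimation_config`.
#' @export
estimation_config <- function(solver = c("reference", "indlin"),
                              indlin = indlin_config(),
                              smart_update = FALSE,
                              theta0 = pk_params(),
                              max_fev = 400L, ftol = 1e-8, ptol = 1e-8,
                              atol = 1e-6, rtol = 1e-3) {
  solver <- match.arg(solver)
  stopifnot(inherits(indlin, "indlin_config"), max_fev >= 1)
  structure(list(solver = solver, indlin = indlin,
                 smart_update = isTRUE(smart_update),
                 theta0 = as_pk_params(theta0),
                 max_fev = as.integer(max_fev), ftol = ftol, ptol = ptol,
                 atol = atol, rtol = rtol),
            class = "estimation_config")
}

# Mutable per-fit cache: most recent converged prediction series (the
# smart-update warm start) plus evaluation / iteration counters.
# Finite-difference Jacobian probes share the same cache.
new_predict_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$pred <- NULL
  e$total_iterations <- 0L
  e$n_calls <- 0L
  e
}

#' Model-predicted concentrations at sampling times
#'
#' Dispatches to the configured solver back-end. With the indlin back-end
#' and `smart_update = TRUE`, the linearization is initialized from the
#' cached prediction series of the previous call (interpolated onto the
#' current grid); the cache is then refreshed with the new converged
#' series. A cold cache reproduces the plain zero-start solve.
#'
#' @param theta A [pk_params()] object.
#' @param times Sampling times (h).
#' @param dose Dose amount (mg).
#' @param config An [estimation_config()].
#' @param cache Optional cache from `new_predict_cache()`; used both for
#'   the smart-update series and to count solver iterations.
#' @return Predicted concentrations (mg/L) at `times`.
#' @export
predict_mm <- function(theta, times, dose, config = estimation_config(),
                       cache = NULL) {
  theta <- as_pk_params(theta)
  if (config$solver == "reference") {
    if (!is.null(cache)) cache$n_calls <- cache$n_calls + 1L
    return(reference_solve(theta, dose, times,
                           atol = config$atol, rtol = config$rtol))
  }
  warm <- if (config$smart_update && !is.null(cache)) cache$pred else NULL
  sol <- inductive_linearize(theta, dose, times, config$indlin,
                             warm_start = warm)
  if (!is.null(cache)) {
    cache$n_calls <- cache$n_calls + 1L
    cache$total_iterations <- cache$total_iterations + sol$iterations
    cache$pred <- list(time = sol$grid$times, conc = sol$conc)
  }
  predict_conc(sol, times)
}

#' Fit the Michaelis-Menten model by least squares
#'
#' Minimizes the ordinary least squares objective over
#' `theta = (ka, V, Vmax, Km)` with a Levenberg-Marquardt search
#' (`minpack.lm::nls.lm`, finite-difference Jacobian) on the natural
#' parameter scale. Objective evaluations at non-positive or non-finite
#' parameters return residuals of magnitude `1e6` (soft rejection), so
#' the unbounded search is steered back without crashing. The fit is
#' deterministic given the dataset and configuration.
#'
#' @param dataset A [pk_dataset()].
#' @param config An [estimation_config()].
#' @return A list of class `mm_fit`: `theta_hat`, `ofv` ((mg/L)^2),
#'   `converged`, `n_evals` (objective evaluations), `indlin_iterations`
#'   (total linearization iterations across evaluations, 0 for the
#'   reference back-end), `mean_indlin_iterations`, `runtime_s`, and
#'   `optimizer` diagnostics (`info`, `message`, `niter`).
#' @export
fit_mm <- function(dataset, config = estimation_config()) {
  stopifnot(inherits(dataset, "pk_dataset"), inherits(config, "estimation_config"))
  k <- length(dataset$conc)
  cache <- new_predict_cache()
  resfn <- function(p) {
    if (any(!is.finite(p)) || any(p <= 0)) return(rep(1e6, k))
    g <- tryCatch(
      predict_mm(as_pk_params(p), dataset$times, dataset$dose, config, cache),
      error = function(e) NULL)
    if (is.null(g)) return(rep(1e6, k))
    dataset$conc - g
  }
  ctrl <- minpack.lm::nls.lm.control(maxfev = config$max_fev, maxiter = 200L,
                                     ftol = config$ftol, ptol = config$ptol)
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(minpack.lm::nls.lm(par = unclass(config$theta0), fn = resfn,
                                     control = ctrl),
                  error = function(e) e)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (inherits(out, "error")) {
    return(structure(list(theta_hat = NULL, ofv = NA_real_, converged = FALSE,
                          n_evals = cache$n_calls,
                          indlin_iterations = cache$total_iterations,
                          mean_indlin_iterations = NA_real_,
                          runtime_s = elapsed,
                          optimizer = list(info = -1L,
                                           message = conditionMessage(out),
                                           niter = NA_integer_)),
                     class = "mm_fit"))
  }
  structure(list(theta_hat = as_pk_params(out$par),
                 ofv = out$deviance,
                 converged = out$info %in% 1:4,
                 n_evals = cache$n_calls,
                 indlin_iterations = cache$total_iterations,
                 mean_indlin_iterations =
                   if (cache$n_calls > 0L && config$solver == "indlin")
                     cache$total_iterations / cache$n_calls else NA_real_,
                 runtime_s = elapsed,
                 optimizer = list(info = out$info, message = out$message,
                                  niter = out$niter)),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  if (is.null(x$theta_hat)) {
    cat("Michaelis-Menten fit: FAILED (", x$optimizer$message, ")\n")
    return(invisible(x))
  }
  cat(sprintf("Michaelis-Menten least-squares fit (%s)\n",
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  ka = %.4g /h, V = %.4g L, Vmax = %.4g mg/h, Km = %.4g mg/L\n",
              x$theta_hat[["ka"]], x$theta_hat[["V"]],
              x$theta_hat[["Vmax"]], x$theta_hat[["Km"]]))
  cat(sprintf("  OFV = %.6g (mg/L)^2 after %d objective evaluations\n",
              x$ofv, x$n_evals))
  invisible(x)
}
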