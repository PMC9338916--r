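#' Between-subject and residual variability specification
#'
#' @param omega2 Lognormal between-subject variance per parameter; a
#'   single value applied to all four parameters or a named length-4
#'   vector (`ka`, `V`, `Vmax`, `Km`). Default 0.1 each.
#' @param sigma Residual log-scale standard deviation of the exponential
#'   error model (CV of about `sigma` for small `sigma`). Default 0.1.
#' @return A list of class `variability_spec`.
#' @export
variability_spec <- function(omega2 = 0.1, sigma = 0.1) {
  if (length(omega2) == 1L) {
    omega2 <- setNames(rep(as.numeric(omega2), 4L), c("ka", "V", "Vmax", "Km"))
  }
  stopifnot(length(omega2) == 4L, all(omega2 >= 0), sigma >= 0)
  if (is.null(names(omega2))) names(omega2) <- c("ka", "V", "Vmax", "Km")
  structure(list(omega2 = omega2[c("ka", "V", "Vmax", "Km")],
                 sigma = as.numeric(sigma)),
            class = "variability_spec")
}

#' Draw an individual's parameters with between-subject variability
#'
#' `theta_i = theta_bar * exp(eta)`, `eta ~ N(0, omega2)` independently
#' per parameter, drawn from the current RNG state.
#'
#' @param theta_bar Population mean parameters ([pk_params()]).
#' @param spec A [variability_spec()].
#' @return A [pk_params()] object for the individual.
#' @export
draw_individual <- function(theta_bar, spec = variability_spec()) {
  theta_bar <- as_pk_params(theta_bar)
  stopifnot(inherits(spec, "variability_spec"))
  eta <- rnorm(4L, mean = 0, sd = sqrt(spec$omega2))
  as_pk_params(unclass(theta_bar) * exp(eta))
}

#' Simulate a noisy observed dataset
#'
#' Observations are `y_i = g(theta_i, t_i) * exp(eps_i)` with
#' `eps_i ~ N(0, sigma^2)`; the noise-free predictions `g` come from the
#' adaptive Runge-Kutta reference solver.
#'
#' @param theta_i Individual parameters ([pk_params()]).
#' @param design A list with `times` (h) and `dose` (mg); see
#'   [nominal_design()].
#' @param sigma Residual log-scale SD; `0` gives noise-free data.
#' @param atol,rtol Reference-solver tolerances.
#' @return A [pk_dataset()].
#' @export
simulate_observations <- function(theta_i, design = nominal_design(),
                                  sigma = 0.1, atol = 1e-6, rtol = 1e-3) {
  g <- reference_solve(theta_i, design$dose, design$times,
                       atol = atol, rtol = rtol)
  # the adaptive solver can return tiny negatives (|error| <= atol) on a
  # fast-eliminating individual's tail; the lognormal error model needs
  # g > 0, and at these magnitudes the OLS weight is negligible either way
  g <- pmax(g, 1e-12)
  y <- g * exp(rnorm(length(g), mean = 0, sd = sigma))
  pk_dataset(design$times, y, design$dose)
}

#' Percent relative difference of estimates from truth
#'
#' `100 * (theta_hat - theta_true) / theta_true`, per parameter.
#'
#' @param theta_hat,theta_true Parameter vectors ([pk_params()]).
#' @return Named numeric length-4 vector (percent).
#' @export
reldiff <- function(theta_hat, theta_true) {
  theta_hat <- as_pk_params(theta_hat)
  theta_true <- as_pk_params(theta_true)
  100 * (unclass(theta_hat) - unclass(theta_true)) / unclass(theta_true)
}

# Independent, reproducible per-replicate seed stream: changing the
# variant list or total replicate count never alters earlier replicates.
sse_child_seed <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 1e6) * 2039 + 7919 * as.numeric(i)) %%
               2147483647)
}

#' Run a stochastic simulation-estimation study
#'
#' For each replicate: draw an individual's parameters with
#' between-subject variability, simulate one noisy dataset with the
#' reference solver, then fit that same dataset with every configured
#' solver variant (a paired comparison). Fully reproducible from `seed`;
#' per-replicate failures are recorded, not fatal.
#'
#' @param n_reps Number of replicates, `>= 1`.
#' @param variants Named list of [estimation_config()] objects.
#' @param spec A [variability_spec()].
#' @param design Sampling design list (`times`, `dose`).
#' @param theta_bar Population mean parameters used both to draw
#'   individuals and as the search's initial values (via each variant's
#'   `theta0`).
#' @param seed Integer parent seed.
#' @param progress_every Log a progress line to stderr every this many
#'   replicates; `0` disables.
#' @return A list of class `sse_result`: `replicates` (one row per
#'   replicate x variant, with true and estimated parameters, OFV,
#'   runtime, convergence flag and per-parameter RelDiff) and `summary`
#'   (from [summarize_sse()]).
#' @export
run_sse <- function(n_reps, variants, spec = variability_spec(),
                    design = nominal_design(), theta_bar = pk_params(),
                    seed = 1L, progress_every = 0L) {
  stopifnot(n_reps >= 1, is.list(variants), length(variants) >= 1)
  if (is.null(names(variants)) || any(names(variants) == "")) {
    stop("variants must be a named list of estimation_config objects",
         call. = FALSE)
  }
  theta_bar <- as_pk_params(theta_bar)
  pnames <- c("ka", "V", "Vmax", "Km")
  rows <- vector("list", n_reps * length(variants))
  r <- 0L
  for (i in seq_len(n_reps)) {
    set.seed(sse_child_seed(seed, i))
    theta_i <- draw_individual(theta_bar, spec)
    dataset <- simulate_observations(theta_i, design, spec$sigma)
    for (v in names(variants)) {
      fit <- tryCatch(suppressWarnings(fit_mm(dataset, variants[[v]])),
                      error = function(e) NULL)
      failed <- is.null(fit) || is.null(fit$theta_hat) || !is.finite(fit$ofv)
      rd <- if (failed) rep(NA_real_, 4L) else reldiff(fit$theta_hat, theta_i)
      th <- if (failed) rep(NA_real_, 4L) else unclass(fit$theta_hat)
      row <- data.frame(replicate = i, variant = v)
      row[paste0("theta_true_", pnames)] <- as.list(unclass(theta_i))
      row[paste0("theta_hat_", pnames)] <- as.list(th)
      row$ofv <- if (failed) NA_real_ else fit$ofv
      row$runtime_s <- if (is.null(fit)) NA_real_ else fit$runtime_s
      row$converged <- if (failed) FALSE else fit$converged
      row$indlin_iterations <- if (failed) NA_real_ else fit$indlin_iterations
      row[paste0("reldiff_", pnames)] <- as.list(rd)
      r <- r + 1L
      rows[[r]] <- row
    }
    if (progress_every > 0L && i %% progress_every == 0L) {
      message(sprintf("SSE replicate %d / %d done", i, n_reps))
    }
  }
  replicates <- do.call(rbind, rows)
  rownames(replicates) <- NULL
  structure(list(replicates = replicates, summary = summarize_sse(replicates)),
            class = "sse_result")
}

#' Summarize a replicate table
#'
#' Per solver variant: replicate counts, mean and sample SD of OFV and
#' runtime, and mean / SD / quartiles of the percent relative difference
#' per parameter. Failed fits (missing OFV) are excluded, with the
#' exclusion count reported.
#'
#' @param replicates The replicate data frame from [run_sse()].
#' @return A list of class `sse_summary` with data frames `ofv`,
#'   `runtime`, `reldiff`, plus `n_replicates`.
#' @export
summarize_sse <- function(replicates) {
  if (!is.data.frame(replicates) || nrow(replicates) == 0L) {
    stop("replicate table must be a non-empty data frame", call. = FALSE)
  }
  pnames <- c("ka", "V", "Vmax", "Km")
  variants <- unique(replicates$variant)
  ofv_rows <- list(); rt_rows <- list(); rd_rows <- list()
  for (v in variants) {
    sub <- replicates[replicates$variant == v, , drop = FALSE]
    keep <- is.finite(sub$ofv)
    ok <- sub[keep, , drop = FALSE]
    sd0 <- function(x) if (length(x) > 1L) sd(x) else 0
    ofv_rows[[v]] <- data.frame(variant = v, n = nrow(ok),
                                n_excluded = sum(!keep),
                                mean = mean(ok$ofv), sd = sd0(ok$ofv))
    rt_rows[[v]] <- data.frame(variant = v, n = nrow(ok),
                               mean = mean(ok$runtime_s),
                               sd = sd0(ok$runtime_s))
    for (p in pnames) {
      x <- ok[[paste0("reldiff_", p)]]
      qs <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      rd_rows[[paste(v, p)]] <- data.frame(variant = v, parameter = p,
                                           mean = mean(x), sd = sd0(x),
                                           q25 = qs[1L], median = qs[2L],
                                           q75 = qs[3L])
    }
  }
  structure(list(ofv = do.call(rbind, c(ofv_rows, make.row.names = FALSE)),
                 runtime = do.call(rbind, c(rt_rows, make.row.names = FALSE)),
                 reldiff = do.call(rbind, c(rd_rows, make.row.names = FALSE)),
                 n_replicates = length(unique(replicates$replicate))),
            class = "sse_summary")
}

#' @export
print.sse_summary <- function(x, ...) {
  cat(sprintf("SSE summary over %d replicates\n", x$n_replicates))
  cat("Objective function value (mg/L)^2:\n")
  print(x$ofv, row.names = FALSE)
  cat("RelDiff (%) by parameter:\n")
  print(x$reldiff, row.names = FALSE, digits = 3)
  invisible(x)
}
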