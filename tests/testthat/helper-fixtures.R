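# Shared fixtures: nominal parameters, design, and oracle helpers.

nominal_theta <- function() pk_params(ka = 1, V = 1, Vmax = 0.2, Km = 0.5)

design13 <- function() nominal_design()

# Tight-tolerance Runge-Kutta solve, used as the accuracy oracle when a
# comparison tolerance is far below the reference solver's defaults.
tight_reference <- function(theta, dose, times) {
  reference_solve(theta, dose, times, atol = 1e-12, rtol = 1e-10)
}

# Linear-elimination parameterization: Km so large that the saturable
# term is effectively first order with k10 = Vmax / (V * Km) = 0.4 /h.
linear_theta <- function() pk_params(ka = 1, V = 1, Vmax = 4e5, Km = 1e6)

# Random stable test matrix: shifts a random matrix so all eigenvalues
# have negative real part.
random_stable_matrix <- function(m) {
  M <- matrix(stats::rnorm(m * m), m, m)
  M - (max(Re(eigen(M, only.values = TRUE)$values)) + stats::runif(1, 0.1, 1)) * diag(m)
}
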