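test_that("step_expm handles identity, cascade, and diagonal cases", {
  K <- matrix(c(-1, 1, 0, -0.4), 2, 2)
  expect_equal(step_expm(K, 0, c(3, 0)), c(3, 0))
  # one step across the constant-K cascade equals the closed form
  expect_equal(step_expm(K, 1, c(3, 0)),
               c(3 * exp(-1), 5 * (exp(-0.4) - exp(-1))), tolerance = 1e-12)
  expect_equal(step_expm(diag(c(-1, -0.4)), 2, c(1, 1)),
               c(exp(-2), exp(-0.8)), tolerance = 1e-12)
  expect_error(step_expm(matrix(NA_real_, 2, 2), 1, c(1, 1)), "finite")
  expect_error(step_expm(matrix(1, 2, 3), 1, c(1, 1)), "square")
})

test_that("step_expm agrees with a scaling-and-squaring oracle on random stable matrices", {
  skip_if_not_installed("Matrix")
  set.seed(101)
  for (i in 1:1000) {
    m <- if (i %% 5 == 0) 5L else 2L
    K <- random_stable_matrix(m)
    if (m == 2L && i %% 2 == 0) K[1, 2] <- 0  # exercise the triangular path
    dt <- stats::runif(1, 0.01, 2)
    y <- stats::rnorm(m)
    want <- as.numeric(Matrix::expm(K * dt) %*% y)
    expect_equal(step_expm(K, dt, y), want, tolerance = 1e-10)
  }
})

test_that("step_expm stays exact through the confluent (defective) limit", {
  skip_if_not_installed("Matrix")
  # equal eigenvalues: the cascade matrix is defective, EVD alone fails
  K <- matrix(c(-1, 1, 0, -1), 2, 2)
  expect_equal(step_expm(K, 1.3, c(2, 1)),
               as.numeric(Matrix::expm(K * 1.3) %*% c(2, 1)), tolerance = 1e-12)
  # nearly defective non-triangular matrix takes the fallback route
  K2 <- matrix(c(-1, 1, 1e-18, -1), 2, 2)
  expect_equal(step_expm(K2, 0.7, c(1, 2)),
               as.numeric(Matrix::expm(K2 * 0.7) %*% c(1, 2)), tolerance = 1e-10)
})

test_that("propagate applies per-interval exponentials sequentially", {
  K <- matrix(c(-1, 1, 0, -0.4), 2, 2)
  # one interval is exactly one step
  traj <- propagate(list(K), c(0, 1), c(3, 0))
  expect_equal(traj[, 2], step_expm(K, 1, c(3, 0)))
  # semigroup: fine constant-K grid equals one coarse step
  tt <- seq(0, 1, by = 0.05)
  Ks <- array(K, dim = c(2, 2, length(tt) - 1))
  fine <- propagate(Ks, tt, c(3, 0))
  expect_equal(fine[, length(tt)], step_expm(K, 1, c(3, 0)), tolerance = 1e-10)
  # wrong interval count is a contract error
  expect_error(propagate(list(K, K), c(0, 1), c(3, 0)), "per grid interval")
})

test_that("propagate preserves the closed-form depot decay at every node", {
  grid <- fixed_grid(0.01, 30, design13()$times)
  nint <- length(grid$times) - 1
  K <- build_K(nominal_theta(), 0)
  Ks <- array(K, dim = c(2, 2, nint))
  traj <- propagate(Ks, grid, c(3, 0))
  expect_equal(traj[1, ], 3 * exp(-grid$times), tolerance = 1e-10)
})

test_that("propagate converges with at least first order on a time-varying system", {
  # genuinely LTV elimination rate sampled at interval midpoints
  k22 <- function(t) -(0.4 + 0.2 * sin(t))
  solve_ss <- function(ss) {
    tt <- seq(0, 10, by = ss)
    mid <- (tt[-1] + tt[-length(tt)]) / 2
    Ks <- array(0, dim = c(2, 2, length(mid)))
    Ks[1, 1, ] <- -1; Ks[2, 1, ] <- 1; Ks[2, 2, ] <- k22(mid)
    propagate(Ks, tt, c(3, 0))[, length(tt)]
  }
  truth <- solve_ss(0.002)
  errs <- vapply(c(0.2, 0.1, 0.05), function(ss) max(abs(solve_ss(ss) - truth)),
                 numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_gt(log2(errs[1] / errs[3]), 2)  # observed order >= 1 over two halvings
})

test_that("fixed_grid builds sorted, de-duplicated grids containing output times", {
  d <- design13()
  g <- fixed_grid(0.1, 30, d$times)
  expect_true(all(d$times %in% g$times))
  expect_lte(max(diff(g$times)), 0.1 + 1e-12)
  expect_identical(g$times[1], 0)
  expect_equal(max(g$times), 30)
  g2 <- fixed_grid(100, 30, c(1, 2))
  expect_equal(g2$times, c(0, 1, 2, 30))
  g3 <- fixed_grid(100, 30, c(1, 1, 1))
  expect_equal(sum(g3$times == 1), 1L)
  expect_error(fixed_grid(0.1, -1, numeric()), "positive")
  expect_error(fixed_grid(0.1, 30, 31), "\\[0, T\\]")
})

test_that("adaptive_grid implements the clipped inverse-slope rule", {
  # constant |slope| = 2 with alpha = 0.01 gives uniform 0.005 h steps
  boot <- list(time = seq(0, 1, by = 0.01), value = 2 * seq(0, 1, by = 0.01))
  g <- adaptive_grid(boot, step_adaptive(alpha = 0.01, ss_min = 1e-4, ss_max = 1), 1)
  expect_equal(unique(round(diff(g$times), 12)), 0.005)
  # vanishing slope is clipped at ss_max
  flat <- list(time = seq(0, 10, by = 0.01), value = rep(1, 1001))
  gf <- adaptive_grid(flat, step_adaptive(alpha = 0.01, ss_max = 0.5), 10)
  expect_equal(unique(round(diff(gf$times), 12)), 0.5)
})

test_that("adaptive_grid keeps output times and steps small where the profile is steep", {
  d <- design13(); th <- nominal_theta()
  cfg <- indlin_config(step = step_adaptive(0.01))
  sol <- inductive_linearize(th, 3, d$times, cfg)
  g <- sol$grid
  expect_true(all(d$times %in% g$times))
  expect_lte(max(diff(g$times)), 1 + 1e-9)
  # |dC/dt| ~ 3 near t = 0, near zero in the tail: early steps much smaller
  early <- diff(g$times)[1]
  late <- max(diff(g$times)[g$times[-length(g$times)] > 25])
  expect_lt(early, 0.01)
  expect_gt(late, 10 * early)
})
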