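test_that("successive_error is a guarded max relative difference", {
  expect_equal(successive_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(successive_error(c(1, 2), c(0.9, 2)), 0.1)
  # nodes where the current iterate is ~0 are excluded by the guard
  expect_equal(successive_error(c(0, 1), c(5, 1)), 0)
  expect_identical(successive_error(c(0, 0), c(1, 2)), Inf)
  expect_error(successive_error(1:3, 1:2), "equal length")
})

test_that("cold-start first iterate is the Bateman profile of the constant-K system", {
  d <- design13(); th <- nominal_theta()
  sol1 <- inductive_linearize(th, 3, d$times,
                              indlin_config(n_max = 1, use_stopping = FALSE,
                                            step = step_fixed(0.01)))
  expect_equal(predict_conc(sol1, d$times), bateman(th, 3, d$times),
               tolerance = 1e-6)
})

test_that("the fixed-point loop contracts and satisfies the stopping rule", {
  d <- design13(); th <- nominal_theta()
  sol <- inductive_linearize(th, 3, d$times,
                             indlin_config(epsilon = 1e-6, n_max = 60,
                                           step = step_fixed(0.01)))
  expect_true(sol$converged)
  expect_lt(sol$final_error, 1e-6)
  expect_lte(sol$iterations, 60)
  # geometric contraction: successive error strictly decreasing after the
  # (trivially 1) first comparison against the zero plug-in
  expect_true(all(diff(sol$errors[-1]) < 0))
  expect_equal(sol$errors[1], 1)
})

test_that("a linear parameterization reaches its fixed point after one iteration", {
  d <- design13()
  # huge Km with nominal Vmax: the plug-in concentration moves K(2,2) by
  # O(C/Km), so the fixed point is reached essentially immediately
  sol <- inductive_linearize(pk_params(Km = 1e6), 3, d$times,
                             indlin_config(n_max = 2, use_stopping = FALSE,
                                           step = step_fixed(0.05)))
  expect_lt(sol$errors[2], 1e-10)
})

test_that("warm starting from the fixed point converges immediately and never changes the answer", {
  d <- design13(); th <- nominal_theta()
  cfg <- indlin_config(epsilon = 1e-8, n_max = 40, step = step_fixed(0.02))
  cold <- inductive_linearize(th, 3, d$times, cfg)
  warm <- inductive_linearize(th, 3, d$times, cfg,
                              warm_start = list(time = cold$grid$times,
                                                conc = cold$conc))
  expect_equal(warm$iterations, 1L)
  expect_true(warm$converged)
  expect_equal(warm$conc, cold$conc, tolerance = 10 * cfg$epsilon)
  # a warm start from a different parameter vector's solution also lands
  # on the same fixed point
  other <- inductive_linearize(pk_params(1.2, 0.9, 0.25, 0.4), 3, d$times, cfg)
  warm2 <- inductive_linearize(th, 3, d$times, cfg,
                               warm_start = list(time = other$grid$times,
                                                 conc = other$conc))
  expect_equal(warm2$conc, cold$conc, tolerance = 10 * cfg$epsilon)
})

test_that("converged solution matches the tight adaptive-RK oracle", {
  d <- design13(); th <- nominal_theta()
  sol <- inductive_linearize(th, 3, d$times,
                             indlin_config(epsilon = 1e-9, n_max = 60,
                                           step = step_fixed(0.01)))
  expect_equal(predict_conc(sol, d$times), tight_reference(th, 3, d$times),
               tolerance = 1e-4)
})

test_that("hitting the iteration cap warns and reports non-convergence", {
  d <- design13()
  expect_warning(
    sol <- inductive_linearize(nominal_theta(), 3, d$times,
                               indlin_config(epsilon = 1e-6, n_max = 3,
                                             step = step_fixed(0.05))),
    "stopping rule")
  expect_false(sol$converged)
  expect_identical(sol$iterations, 3L)
})

test_that("predict_conc does exact node lookup only", {
  d <- design13()
  sol <- inductive_linearize(nominal_theta(), 3, d$times,
                             indlin_config(step = step_fixed(0.05)))
  expect_equal(predict_conc(sol, 0), 0)
  expect_length(predict_conc(sol, d$times), 13L)
  expect_equal(predict_conc(sol, 30), sol$conc[length(sol$conc)])
  expect_error(predict_conc(sol, 0.123456), "not a grid node")
})

test_that("solutions round-trip through the trajectory CSV schema", {
  d <- design13()
  sol <- inductive_linearize(nominal_theta(), 3, d$times,
                             indlin_config(step = step_fixed(0.5)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(sol, path)
  df <- read.csv(path)
  expect_named(df, c("time_h", "depot_mg", "central_mg", "conc_mg_L"))
  expect_equal(df$conc_mg_L, sol$conc)
})
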