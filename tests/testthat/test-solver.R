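test_that("zero observations give the zero solution", {
  M <- matrix(0, 1, 20)
  fit <- srm_solve(M, lambda = 1, p = 1, q = 1)
  expect_equal(fit$L, M)
  expect_equal(fit$E, M)
  expect_equal(fit$objective_trace[fit$iterations], 0)
  expect_equal(fit$rank_estimate, 0L)
})

test_that("clean low-order signals are recovered exactly with large lambda", {
  y <- generate_outputs(sample_poles(4, 11), 80)
  fit <- srm_solve(y, lambda = 1e4, p = 1, q = 1, spec = square_spec(80),
                   control = srm_control(eps1 = 1e-7, eps2 = 1e-9,
                                         max_iter = 2000))
  expect_lt(rel_error(y, fit$L), 1e-6)
  expect_lt(sqrt(sum(fit$E^2)), 1e-4)
  expect_equal(fit$rank_estimate, 4L)
  expect_true(fit$converged)
})

test_that("the stopping rule uses strict inequalities on all five ratios", {
  cc <- hsrm:::check_convergence
  # identical consecutive feasible states
  expect_true(cc(0, 0, 0, 0, 0, normM = 1, eps1 = 1e-4, eps2 = 1e-7))
  # a residual ratio exactly at eps1 must not converge
  expect_false(cc(1e-4, 0, 0, 0, 0, normM = 1, eps1 = 1e-4, eps2 = 1e-7))
  expect_false(cc(0, 0, 1e-7, 0, 0, normM = 1, eps1 = 1e-4, eps2 = 1e-7))
  # zero-norm observations fall back to absolute residuals
  expect_true(cc(1e-5, 0, 0, 0, 0, normM = 0, eps1 = 1e-4, eps2 = 1e-7))
  # early iterations with large residuals do not converge
  expect_false(cc(0.5, 0.5, 0.5, 0.5, 0.5, normM = 1, eps1 = 1e-4,
                  eps2 = 1e-7))
})

test_that("q = 2 reduces to a ridge-like quadratic data fit", {
  # elementwise oracle: argmin lambda/mu w^2 e^2 + (e - z)^2/2
  Z <- matrix(c(-2, 0, 1, 3), 2, 2)
  W <- matrix(c(1, 0.5, 0, 2), 2, 2)
  out <- hsrm:::e_update_q2(Z, lambda = 0.7, mu = 2, W = W)
  direct <- vapply(seq_along(Z), function(i) {
    f <- function(e) 0.7 / 2 * (W[i] * e)^2 + 0.5 * (e - Z[i])^2
    stats::optimize(f, c(-10, 10))$minimum
  }, numeric(1))
  expect_equal(as.vector(out), direct, tolerance = 1e-5)
  # on clean data the q = 2 solver reproduces the signal
  y <- generate_outputs(sample_poles(2, 12), 60)
  fit <- srm_solve(y, lambda = 1e4, p = 1, q = 2, spec = square_spec(60),
                   control = srm_control(eps1 = 1e-7, eps2 = 1e-9,
                                         max_iter = 2000))
  expect_lt(rel_error(y, fit$L), 1e-4)
})

test_that("objective and residual decrease after the initial transient", {
  inst <- synthetic_instance(6, 100, rho = 0.2, amplitude = 1, seed = 42)
  fit <- srm_solve(inst$y_tilde, lambda = 0.1, p = 0.5, q = 0.5,
                   spec = square_spec(100),
                   control = srm_control(eps1 = 0, eps2 = 0, max_iter = 220))
  expect_lte(fit$objective_trace[200], fit$objective_trace[10])
  expect_lte(fit$residual_trace[200], fit$residual_trace[10])
})

test_that("scalable solver agrees with the full solver when K covers the rank", {
  ctl_full <- srm_control(mu_growth = 1.05, max_iter = 3000)
  ctl_sc <- srm_control(mu_growth = 1.05, max_iter = 3000, K = 8)
  y <- generate_outputs(sample_poles(4, 13), 80)
  f1 <- srm_solve(y, lambda = 10, p = 1, q = 1, spec = square_spec(80),
                  control = ctl_full)
  f2 <- srm_solve_scalable(y, lambda = 10, p = 1, q = 1,
                           spec = square_spec(80), control = ctl_sc)
  expect_lt(sqrt(sum((f1$L - f2$L)^2)) / sqrt(sum(f1$L^2)), 1e-3)
  # the orthonormality constraint holds at the returned state
  expect_lt(sqrt(sum((crossprod(f2$Q) - diag(8))^2)), 1e-8)
})

test_that("scalable solver with K = 1 recovers a rank-1 Hankel trajectory", {
  y1 <- matrix(0.8^(1:60), 1)
  fit <- srm_solve_scalable(y1, lambda = 1e3, p = 1, q = 1,
                            control = srm_control(K = 1))
  expect_lt(rel_error(y1, fit$L), 1e-4)
  expect_error(srm_solve_scalable(y1, lambda = 1, p = 1, q = 1,
                                  control = srm_control()),
               "K")
})

test_that("estimate_rank thresholds relative to the top singular value", {
  expect_equal(estimate_rank(matrix(0, 3, 3)), 0L)
  expect_equal(estimate_rank(diag(c(1, 1e-6))), 1L)
  expect_equal(estimate_rank(diag(c(1, 1e-6)), rel_tol = 1e-7), 2L)
  y <- generate_outputs(sample_poles(6, 14), 100)
  expect_equal(estimate_rank(hankel_map(y, square_spec(100))), 6L)
})

test_that("solver input validation catches malformed problems", {
  M <- matrix(rnorm(20), 1)
  expect_error(srm_solve(M, lambda = -1), "lambda")
  expect_error(srm_solve(M, lambda = 1, p = 1.5), "p must lie")
  expect_error(srm_solve(M, lambda = 1, q = 1.5), "q must lie")
  expect_error(srm_solve(M, lambda = 1, W = matrix(1, 2, 2)), "same shape")
})

test_that("masked-entry lambda tuning selects a competitive value", {
  inst <- synthetic_instance(4, 80, rho = 0.2, amplitude = 1, seed = 21)
  grid <- 10^seq(-2, 0, length.out = 5)
  tuned <- tune_lambda_masked(inst$y_tilde, grid, p = 1, q = 1,
                              spec = square_spec(80), seed = 22)
  expect_true(tuned$lambda %in% grid)
  expect_equal(tuned$score, max(tuned$scores))
  # single-element grid returns that element
  one <- tune_lambda_masked(inst$y_tilde, 0.1, p = 1, q = 1,
                            spec = square_spec(80), seed = 22)
  expect_equal(one$lambda, 0.1)
  expect_error(tune_lambda_masked(inst$y_tilde, numeric(0)), "nonempty")
})
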