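test_that("nullspace basis is orthonormal and annihilates the matrix", {
  H <- matrix(c(1, 0, 0, 0), 2, 2)
  B <- nullspace_basis(H)
  expect_equal(dim(B), c(2L, 1L))
  expect_lt(max(abs(H %*% B)), 1e-10)
  expect_equal(abs(B[2, 1]), 1)
  set.seed(31)
  X <- matrix(rnorm(12), 3, 4) %*% diag(4)[, c(1, 2, 1, 2)]  # rank 2
  Bx <- nullspace_basis(X)
  expect_lt(max(abs(X %*% Bx)), 1e-10)
  expect_equal(crossprod(Bx), diag(ncol(Bx)), tolerance = 1e-12)
  expect_error(nullspace_basis(diag(3)), "trivial nullspace")
})

test_that("realization recovers a known system from noiseless data", {
  sys <- generate_io_system(4, 2, 1, 120, seed = 3)
  mod <- realize_lti(sys$Y, sys$U, order = 4, r = 10)
  expect_lt(rel_error(sys$Y, simulate_lti(mod, sys$U)), 1e-6)
  # eigenvalues are similarity invariants
  ev_hat <- sort(Mod(eigen(mod$A, only.values = TRUE)$values))
  ev_true <- sort(Mod(eigen(sys$model$A, only.values = TRUE)$values))
  expect_equal(ev_hat, ev_true, tolerance = 1e-6)
})

test_that("pure feedthrough systems are recovered at order zero", {
  sys <- generate_io_system(0, 3, 2, 50, seed = 4)
  mod <- realize_lti(sys$Y, sys$U, order = 0)
  expect_equal(mod$order, 0L)
  expect_lt(max(abs(mod$D - sys$model$D)), 1e-10)
})

test_that("simulation follows the exact forward recursion", {
  # A = 0: output column 1 carries the initial state, rest zero
  mod <- ss_model(A = matrix(0, 2, 2), B = matrix(0, 2, 0),
                  C = diag(2), D = matrix(0, 2, 0), x0 = c(3, -1))
  Y <- simulate_lti(mod, T_len = 4)
  expect_equal(Y, cbind(c(3, -1), 0, 0, 0) * matrix(1, 2, 4) *
                 cbind(1, 0, 0, 0)[rep(1, 2), ])
  # scalar geometric decay
  mod2 <- ss_model(A = matrix(0.5), B = matrix(0, 1, 0), C = matrix(1),
                   D = matrix(0, 1, 0), x0 = 1)
  expect_equal(as.vector(simulate_lti(mod2, T_len = 4)),
               c(1, 0.5, 0.25, 0.125))
  # prefix consistency
  sys <- generate_io_system(3, 1, 2, 40, seed = 5)
  Y1 <- simulate_lti(sys$model, sys$U[, 1:25, drop = FALSE])
  expect_equal(simulate_lti(sys$model, sys$U)[, 1:25], Y1)
})

test_that("noiseless end-to-end prediction is near perfect", {
  sys <- generate_io_system(4, 2, 1, 150, seed = 41)
  tr <- 1:90; te <- 91:150
  pred <- predict_behavior(sys$Y[, tr, drop = FALSE],
                           sys$U[, tr, drop = FALSE],
                           sys$U[, te, drop = FALSE],
                           lambda = 10, p = 1, q = 1)
  expect_gt(pearson_cor(sys$Y[, te], pred$Y_hat), 0.99)
  expect_equal(pred$order, 4L)
})

test_that("constant outputs with no inputs predict a constant", {
  Y <- matrix(2, 1, 40)
  pred <- predict_behavior(Y, lambda = 10, p = 1, q = 1, n_test = 10)
  expect_equal(as.vector(pred$Y_hat), rep(2, 10), tolerance = 1e-4)
})

test_that("prediction under sparse corruption beats a static regression", {
  # baseline: least-squares fit of outputs on inputs, no dynamics
  wins <- 0L
  for (s in 1:5) {
    sys <- generate_io_system(4, 2, 1, 150, seed = 500 + s)
    tr <- 1:90; te <- 91:150
    noisy <- add_sparse_noise(sys$Y[, tr, drop = FALSE], 0.2, 1,
                              seed = 900 + s)
    pred <- predict_behavior(noisy$y_tilde, sys$U[, tr, drop = FALSE],
                             sys$U[, te, drop = FALSE],
                             lambda = 10^seq(-2, 0, length.out = 5),
                             p = 0.5, q = 0.5, r = 10)
    beta <- t(lm.fit(t(sys$U[, tr, drop = FALSE]),
                     t(noisy$y_tilde))$coefficients)
    y_static <- beta %*% sys$U[, te, drop = FALSE]
    cor_dyn <- pearson_cor(sys$Y[, te], pred$Y_hat)
    cor_static <- pearson_cor(sys$Y[, te], y_static)
    if (cor_dyn > cor_static) wins <- wins + 1L
  }
  expect_gt(wins, 2L)
})

test_that("hold-out lambda tuning picks the best validated candidate", {
  sys <- generate_io_system(3, 1, 1, 120, seed = 51)
  grid <- c(0.01, 0.1, 1)
  tuned <- tune_lambda(sys$Y, sys$U, grid, p = 1, q = 1, r = 10)
  expect_true(tuned$lambda %in% grid)
  expect_equal(tuned$score, max(tuned$scores))
  one <- tune_lambda(sys$Y, sys$U, 0.5, p = 1, q = 1, r = 10)
  expect_equal(one$lambda, 0.5)
  expect_error(tune_lambda(sys$Y, sys$U, numeric(0)), "nonempty")
  expect_error(tune_lambda(matrix(1, 1, 120), sys$U, grid, r = 10),
               "zero variance")
})
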