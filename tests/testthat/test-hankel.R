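test_that("hankel_map matches the definition on small examples", {
  sp <- hankel_spec(1, 1, 2, 2)
  expect_equal(hankel_map(matrix(1:3, 1), sp),
               matrix(c(1, 2, 2, 3), 2, 2))
  # block case: shape (m*j) x (n_blk*k)
  sp2 <- hankel_spec(2, 1, 3, 4)
  A <- matrix(rnorm(2 * 6), 2)
  H <- hankel_map(A, sp2)
  expect_equal(dim(H), c(6L, 4L))
  # constant skew-diagonal blocks
  expect_equal(H[1:2, 2], H[3:4, 1])
  expect_equal(H[3:4, 3], H[5:6, 2])
  expect_error(hankel_map(matrix(1:4, 1), sp), "trajectory must be")
})

test_that("hankel_adjoint sums blocks along skew diagonals", {
  sp <- hankel_spec(1, 1, 2, 2)
  B <- matrix(c(1, 3, 2, 4), 2, 2)  # [[a, b], [c, d]] = [[1, 2], [3, 4]]
  expect_equal(hankel_adjoint(B, sp), matrix(c(1, 5, 4), 1))
  expect_equal(hankel_adjoint(matrix(0, 2, 2), sp), matrix(0, 1, 3))
  expect_error(hankel_adjoint(matrix(0, 3, 2), sp), "matrix must be")
})

test_that("map and adjoint satisfy the adjoint identity, with and without gamma", {
  set.seed(1)
  specs <- list(hankel_spec(1, 1, 3, 5),
                hankel_spec(2, 1, 4, 3),
                hankel_spec(3, 2, 2, 4))
  for (sp in specs) {
    for (rep in 1:5) {
      A <- matrix(rnorm(sp$m * sp$n_blk * hankel_T(sp)), sp$m)
      B <- matrix(rnorm(sp$m * sp$j * sp$n_blk * sp$k), sp$m * sp$j)
      expect_lt(abs(sum(hankel_map(A, sp) * B) -
                      sum(A * hankel_adjoint(B, sp))), 1e-10)
    }
  }
  # with a nontrivial gamma (orthonormal columns)
  sp <- hankel_spec(1, 1, 4, 6)
  gam <- qr.Q(qr(matrix(rnorm(6 * 3), 6)))
  spg <- hankel_spec(1, 1, 4, 6, gamma = gam)
  A <- matrix(rnorm(9), 1)
  B <- matrix(rnorm(4 * 3), 4)
  expect_lt(abs(sum(hankel_map(A, spg) * B) -
                  sum(A * hankel_adjoint(B, spg))), 1e-10)
})

test_that("adjoint norm is bounded by min(j, k)", {
  set.seed(2)
  sp <- hankel_spec(1, 1, 3, 4)
  expect_equal(adjoint_norm_bound(sp), 3)
  expect_equal(adjoint_norm_bound(hankel_spec(1, 1, 1, 1)), 1)
  for (rep in 1:20) {
    B <- matrix(rnorm(3 * 4), 3)
    expect_lte(sum(hankel_adjoint(B, sp)^2), 3 * sum(B^2) + 1e-12)
  }
})

test_that("norm bound dominates the operator norm of adjoint-compose-map", {
  # power-iteration oracle on small random specs
  set.seed(3)
  for (sp in list(hankel_spec(1, 1, 3, 4), hankel_spec(2, 1, 3, 3),
                  hankel_spec(1, 1, 5, 2))) {
    v <- matrix(rnorm(sp$m * hankel_T(sp)), sp$m)
    for (it in 1:200) {
      v <- hankel_adjoint(hankel_map(v, sp), sp)
      v <- v / sqrt(sum(v^2))
    }
    sigma <- sum(v * hankel_adjoint(hankel_map(v, sp), sp))
    expect_lte(sigma, adjoint_norm_bound(sp) + 1e-8)
  }
})

test_that("Q0 is positive semi-definite", {
  sp <- hankel_spec(1, 1, 4, 4)
  expect_equal(apply_q0(matrix(0, 1, 7), sp), matrix(0, 1, 7))
  set.seed(4)
  for (rep in 1:10) {
    P <- matrix(rnorm(7), 1)
    expect_gte(sum(P * apply_q0(P, sp)), -1e-10 * sum(P^2))
  }
  # dense assembly and eigendecomposition on small specs
  for (sp in list(hankel_spec(1, 1, 3, 4), hankel_spec(2, 1, 2, 3))) {
    Q <- assemble_q0(sp)
    expect_lt(max(abs(Q - t(Q))), 1e-12)
    expect_gte(min(eigen(Q, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("adjoint-compose-map multiplies by skew-diagonal multiplicities", {
  sp <- hankel_spec(1, 1, 3, 4)
  y <- matrix(rnorm(6), 1)
  mult <- c(1, 2, 3, 3, 2, 1)
  expect_equal(hankel_adjoint(hankel_map(y, sp), sp), y * rep(mult, each = 1),
               tolerance = 1e-12)
})

test_that("gamma validation rejects expansive multipliers", {
  expect_error(hankel_spec(1, 1, 2, 3, gamma = 2 * diag(3)),
               "singular value")
  expect_silent(hankel_spec(1, 1, 2, 3, gamma = diag(3)))
})

test_that("trajectory text round trip preserves values and missing entries", {
  M <- matrix(c(1.5, NA, 3, 4, 5, 6), 2, 3)
  rownames(M) <- c("ch_a", "ch_b")
  path <- tempfile(fileext = ".csv")
  write_trajectory(M, path)
  M2 <- read_trajectory(path)
  expect_equal(unname(M2), unname(M))
  expect_equal(rownames(M2), rownames(M))
  unlink(path)
})
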