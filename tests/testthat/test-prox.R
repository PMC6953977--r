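test_that("soft thresholding matches its closed form", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(0, 5), 0)
  expect_equal(soft_threshold(c(-3, -1, 0, 1, 3), 1.5),
               c(-1.5, 0, 0, 0, 1.5))
  expect_error(soft_threshold(1, -1), "nonnegative")
})

test_that("q-shrinkage at q = 1 equals soft thresholding bit for bit", {
  z <- seq(-4, 4, by = 0.01)
  for (alpha in c(0.3, 1, 2.5)) {
    expect_identical(q_shrink(z, alpha, 1), soft_threshold(z, alpha))
  }
})

test_that("q-shrinkage matches dense grid minimization of the scalar objective", {
  b <- seq(-5, 5, by = 1e-6)
  for (q in c(0.1, 0.5, 0.9)) {
    for (alpha in c(0.5, 1, 2)) {
      for (z in c(-3, -1.2, 0.4, 1.7, 3)) {
        h <- alpha * abs(b)^q + 0.5 * (b - z)^2
        expect_equal(q_shrink(z, alpha, q), b[which.min(h)],
                     tolerance = 1e-5,
                     label = sprintf("q=%g alpha=%g z=%g", q, alpha, z))
      }
    }
  }
})

test_that("q-shrinkage zeroes inputs below the threshold c2", {
  q <- 0.5; alpha <- 1
  c1 <- (alpha * q * (1 - q))^(1 / (2 - q))
  c2 <- c1 + alpha * q * c1^(q - 1)
  z <- seq(-c2, c2, length.out = 41)
  expect_true(all(q_shrink(z, alpha, q) == 0))
})

test_that("q-shrinkage is odd, monotone, and never beaten by 0 or z", {
  z <- seq(-6, 6, by = 0.05)
  for (q in c(0.2, 0.5, 0.8, 1)) {
    out <- q_shrink(z, 1, q)
    expect_equal(q_shrink(-z, 1, q), -out)
    expect_true(all(diff(out) >= -1e-12))
    h <- function(b) abs(b)^q + 0.5 * (b - z)^2
    expect_true(all(h(out) <= h(0 * z) + 1e-12))
    expect_true(all(h(out) <= h(z) + 1e-12))
  }
  expect_error(q_shrink(1, 1, 1.5), "q must lie")
  expect_error(q_shrink(1, 1, 0), "q must lie")
})

test_that("weighted q-shrinkage applies per-entry thresholds", {
  set.seed(5)
  Z <- matrix(rnorm(20, sd = 3), 4, 5)
  W1 <- matrix(1, 4, 5)
  expect_equal(weighted_q_shrink(Z, 0.7, W1, 0.5), q_shrink(Z, 0.7, 0.5))
  # zero weight means no penalty: entry passes through
  W0 <- W1; W0[2, 3] <- 0
  out <- weighted_q_shrink(Z, 0.7, W0, 0.5)
  expect_equal(out[2, 3], Z[2, 3])
  # 0/1 mask at q = 1: soft threshold on observed entries only
  Wm <- matrix(rbinom(20, 1, 0.5), 4, 5)
  out1 <- weighted_q_shrink(Z, 0.7, Wm, 1)
  expect_equal(out1[Wm == 1], soft_threshold(Z[Wm == 1], 0.7))
  expect_equal(out1[Wm == 0], Z[Wm == 0])
  expect_error(weighted_q_shrink(Z, 1, matrix(1, 2, 2), 1), "same shape")
})

test_that("singular-value p-shrinkage shrinks spectra and solves its objective", {
  Z <- diag(c(3, 1))
  expect_equal(sv_p_shrink(Z, 1, 1), diag(c(2, 0)), ignore_attr = TRUE)
  set.seed(6)
  Z2 <- matrix(rnorm(16), 4, 4)
  expect_equal(sv_p_shrink(Z2, 0, 0.5), Z2, ignore_attr = TRUE)
  # never increases singular values; rank never grows
  for (p in c(0.3, 0.7, 1)) {
    B <- sv_p_shrink(Z2, 0.8, p)
    dB <- svd(B, nu = 0, nv = 0)$d
    dZ <- svd(Z2, nu = 0, nv = 0)$d
    expect_true(all(dB <= dZ + 1e-10))
    expect_lte(sum(dB > 1e-10), sum(dZ > 1e-10))
  }
  # randomized optimality over perturbed singular-value vectors
  p <- 0.5; alpha <- 1
  sZ <- svd(Z2)
  B <- sv_p_shrink(Z2, alpha, p)
  dB <- attr(B, "sv")
  obj <- function(d) alpha * sum(d[d > 0]^p) + 0.5 * sum((d - sZ$d)^2)
  base <- obj(dB)
  for (rep in 1:10000) {
    cand <- pmax(dB + rnorm(4, sd = 0.2), 0)
    expect_gte(obj(cand), base - 1e-10)
  }
})

test_that("procrustes projects onto column-orthonormal matrices", {
  A <- diag(c(2, 3))
  expect_equal(procrustes(A), diag(2))
  set.seed(7)
  Q <- qr.Q(qr(matrix(rnorm(18), 6, 3)))
  expect_lt(sqrt(sum((procrustes(Q) - Q)^2)), 1e-10)
  A2 <- matrix(rnorm(18), 6, 3)
  P <- procrustes(A2)
  expect_lt(max(abs(crossprod(P) - diag(3))), 1e-10)
  # maximality of <P, A> over random orthonormal matrices
  base <- sum(P * A2)
  for (rep in 1:10000) {
    B <- qr.Q(qr(matrix(rnorm(18), 6, 3)))
    expect_gte(base, sum(B * A2) - 1e-10)
  }
  expect_error(procrustes(matrix(0, 2, 3)), "at least as many rows")
})
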