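#' Orthonormal nullspace basis
#'
#' Columns form an orthonormal basis of the (right) nullspace of `X`, from the
#' SVD with numerical rank determined at tolerance `max(dim) * eps * sigma_max`.
#'
#' @param X Nonzero numeric matrix.
#' @return Matrix whose columns are orthonormal and satisfy `X %*% basis = 0`.
#' @export
nullspace_basis <- function(X) {
  X <- as.matrix(X)
  if (all(X == 0)) return(diag(ncol(X)))
  s <- svd(X, nu = 0, nv = ncol(X))
  tol <- max(dim(X)) * .Machine$double.eps * s$d[1]
  rank <- sum(s$d > tol)
  if (rank >= ncol(X))
    stop("matrix has a trivial nullspace; increase the number of Hankel ",
         "block columns (k) or reduce the input dimension")
  s$v[, (rank + 1L):ncol(X), drop = FALSE]
}

#' Linear time-invariant state-space model
#'
#' Container for the discrete-time model `x[t+1] = A x[t] + B u[t]`,
#' `y[t] = C x[t] + D u[t]` with initial state `x0`. Order-0 (pure
#' feedthrough) models carry empty `A`, `B`, `C`.
#'
#' @param A,B,C,D State transition (`n x n`), input map (`n x d`), output map
#'   (`m x n`) and feedthrough (`m x d`) matrices.
#' @param x0 Initial state (length `n`).
#' @return An object of class `"ss_model"`.
#' @export
ss_model <- function(A, B, C, D, x0) {
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C); D <- as.matrix(D)
  n <- nrow(A)
  if (ncol(A) != n) stop("A must be square")
  if (n > 0 && nrow(C) < 1) stop("C must have at least one row")
  if (nrow(B) != n) stop("B must have n rows")
  if (n > 0 && ncol(C) != n) stop("C must have n columns")
  structure(list(A = A, B = B, C = C, D = D, x0 = as.numeric(x0),
                 order = n), class = "ss_model")
}

#' @export
print.ss_model <- function(x, ...) {
  m <- if (x$order > 0) nrow(x$C) else nrow(x$D)
  d <- ncol(x$D)
  rho <- if (x$order > 0) max(Mod(eigen(x$A, only.values = TRUE)$values)) else 0
  cat(sprintf("LTI state-space model: order %d, %d output(s), %d input(s)\n",
              x$order, m, d))
  cat(sprintf("  spectral radius of A: %.4f\n", rho))
  invisible(x)
}

#' Simulate a state-space model
#'
#' Exact forward recursion from the stored initial state.
#'
#' @param model An [ss_model()].
#' @param U Inputs `d x T`, or `NULL`/zero-column for an autonomous run.
#' @param T_len Number of steps; defaults to `ncol(U)`.
#' @return Output matrix `m x T_len`.
#' @export
simulate_lti <- function(model, U = NULL, T_len = NULL) {
  d <- ncol(model$D)
  if (is.null(T_len)) {
    if (is.null(U)) stop("T_len must be given when U is NULL")
    T_len <- ncol(U)
  }
  if (is.null(U)) U <- matrix(0, d, T_len)
  U <- as.matrix(U)
  if (d > 0 && nrow(U) != d) stop("U must have d = ", d, " rows")
  m <- if (model$order > 0) nrow(model$C) else nrow(model$D)
  Y <- matrix(0, m, T_len)
  x <- model$x0
  for (t in seq_len(T_len)) {
    u <- if (d > 0) U[, t] else numeric(0)
    y <- numeric(m)
    if (model$order > 0) y <- y + as.vector(model$C %*% x)
    if (d > 0) y <- y + as.vector(model$D %*% u)
    Y[, t] <- y
    if (model$order > 0) {
      x <- as.vector(model$A %*% x)
      if (d > 0) x <- x + as.vector(model$B %*% u)
    }
  }
  Y
}

#' Deterministic subspace realization from a clean trajectory
#'
#' Realizes a state-space model of the requested order from outputs `Y`
#' (typically the clean trajectory recovered by [srm_solve()]) and inputs
#' `U`. The order-n extended observability matrix is taken from the rank-n
#' SVD of `H(Y) U_perp`; `C` is its first block row and `A` solves the
#' shift-invariance least-squares system. `B`, `D` and the initial state
#' solve the linear system given by writing the output equation over the
#' training horizon.
#'
#' @param Y Outputs `m x T`.
#' @param U Inputs `d x T` or `NULL` (autonomous: only `A`, `C`, `x0` are
#'   estimated and `B`, `D` are zero-width).
#' @param order Target system order `n >= 0`.
#' @param r Hankel depth; must exceed `order`.
#' @param ridge Ridge factor applied when the shift system is
#'   ill-conditioned.
#' @param stabilize When `TRUE` (default) and the shift-invariance estimate
#'   of `A` has spectral radius above 1, rescale it to radius 0.999 before
#'   fitting `B`, `D` and the initial state, which then absorb the change in
#'   the least-squares sense. Behavioral trajectories are bounded, so an
#'   unstable realization can only be an artifact of noise; simulating it
#'   over a long horizon diverges.
#' @return An [ss_model()].
#' @export
realize_lti <- function(Y, U = NULL, order, r = NULL, ridge = 1e-8,
                        stabilize = TRUE) {
  Y <- as.matrix(Y)
  m <- nrow(Y); T_len <- ncol(Y)
  d <- if (is.null(U)) 0L else nrow(as.matrix(U))
  if (order < 0) stop("order must be >= 0")
  if (order == 0L) return(realize_feedthrough(Y, U, m, d))
  if (is.null(r)) {
    r <- max(order + 1L, T_len %/% 3L)
    r <- min(r, (T_len - 1L) %/% 2L)
  }
  if (r <= order) stop("depth r must exceed the target order")
  spec_y <- hankel_spec(m, 1L, r + 1L, T_len - r)
  HY <- hankel_map(Y, spec_y)
  if (!is.null(U)) {
    U <- as.matrix(U)
    spec_u <- hankel_spec(d, 1L, r + 1L, T_len - r)
    Uperp <- nullspace_basis(hankel_map(U, spec_u))
    HY <- HY %*% Uperp
  }
  s <- svd(HY)
  n <- min(order, sum(s$d > 0))
  G <- s$u[, seq_len(n), drop = FALSE] %*% diag(sqrt(s$d[seq_len(n)]), n)
  C <- G[seq_len(m), , drop = FALSE]
  G_up <- G[seq_len(m * r), , drop = FALSE]
  G_down <- G[(m + 1L):(m * (r + 1L)), , drop = FALSE]
  gtg <- crossprod(G_up)
  cond <- kappa(gtg, exact = FALSE)
  if (!is.finite(cond) || cond > 1e12) {
    warning("ill-conditioned shift-invariance system; using a ridge solve")
    gtg <- gtg + ridge * mean(diag(gtg)) * diag(n)
  }
  A <- solve(gtg, crossprod(G_up, G_down))
  if (stabilize) {
    rho <- max(Mod(eigen(A, only.values = TRUE)$values))
    if (rho > 1) A <- A * (0.999 / rho)
  }
  bdx <- solve_bdx0(Y, U, A, C, n, m, d)
  ss_model(A = A, B = bdx$B, C = C, D = bdx$D, x0 = bdx$x0)
}

realize_feedthrough <- function(Y, U, m, d) {
  if (d == 0L) stop("order 0 with no inputs leaves nothing to estimate")
  U <- as.matrix(U)
  D <- t(lstsq(t(U), t(Y)))
  ss_model(A = matrix(0, 0, 0), B = matrix(0, 0, d),
           C = matrix(0, m, 0), D = D, x0 = numeric(0))
}

# minimum-norm least squares via the SVD pseudoinverse (robust to the rank
# deficiency that arises when the realized order exceeds the true order)
lstsq <- function(X, y) {
  s <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * s$d[1]
  pos <- s$d > tol
  s$v[, pos, drop = FALSE] %*%
    ((crossprod(s$u[, pos, drop = FALSE], as.matrix(y))) / s$d[pos])
}

# least squares for x0, B and D:
# y_t = C A^t x0 + sum_{s<t} C A^{t-1-s} B u_s + D u_t, linear in the unknowns
solve_bdx0 <- function(Y, U, A, C, n, m, d) {
  T_len <- ncol(Y)
  CA <- vector("list", T_len)          # CA[[t+1]] = C A^t
  CA[[1]] <- C
  for (t in seq_len(T_len - 1L)) CA[[t + 1L]] <- CA[[t]] %*% A
  n_theta <- n + n * d + m * d
  X <- matrix(0, m * T_len, n_theta)
  for (t in 0:(T_len - 1L)) {
    rows <- t * m + seq_len(m)
    X[rows, seq_len(n)] <- CA[[t + 1L]]
    if (d > 0) {
      acc <- matrix(0, m, n * d)
      if (t > 0) {
        for (s in 0:(t - 1L)) {
          acc <- acc + kronecker(t(U[, s + 1L]), CA[[t - s]])
        }
      }
      X[rows, n + seq_len(n * d)] <- acc
      X[rows, n + n * d + seq_len(m * d)] <- kronecker(t(U[, t + 1L]), diag(m))
    }
  }
  theta <- lstsq(X, as.vector(Y))
  x0 <- theta[seq_len(n)]
  B <- if (d > 0) matrix(theta[n + seq_len(n * d)], n, d) else matrix(0, n, 0)
  D <- if (d > 0) matrix(theta[n + n * d + seq_len(m * d)], m, d)
       else matrix(0, m, 0)
  list(x0 = x0, B = B, D = D)
}

#' Continuous behavior prediction through a learned LTI system
#'
#' End-to-end prediction pipeline: solve the structured rank minimization
#' problem on the training outputs (with the Hankel map right-multiplied by
#' the orthonormal nullspace basis of the input Hankel matrix when inputs are
#' present), estimate the system order from the low-rank surrogate, realize a
#' state-space model from the recovered clean trajectory, then simulate over
#' the full horizon and return the test-segment outputs.
#'
#' @param Y_train Training outputs `m x T_train`.
#' @param U_train Training inputs `d x T_train`, or `NULL` (autonomous).
#' @param U_test Test inputs `d x T_test`; `NULL` for autonomous prediction.
#' @param n_test Number of test steps (required when `U_test` is `NULL`).
#' @param lambda Either a single positive value or a grid to be tuned with
#'   [tune_lambda()].
#' @param p,q Norm exponents, as in [srm_solve()].
#' @param r Hankel depth; default as in [default_hankel_spec()].
#' @param max_order Cap on the realized order (guards against over-estimated
#'   rank on short trajectories).
#' @param rank_tol Relative threshold for [estimate_rank()].
#' @param control A [srm_control()].
#' @return List with `Y_hat` (test-segment predictions `m x n_test`),
#'   `model`, `order`, `lambda` and the solver `fit`.
#' @export
predict_behavior <- function(Y_train, U_train = NULL, U_test = NULL,
                             n_test = NULL, lambda, p = 1, q = 1, r = NULL,
                             max_order = NULL, rank_tol = 1e-3,
                             control = srm_control()) {
  Y_train <- as.matrix(Y_train)
  m <- nrow(Y_train); T_train <- ncol(Y_train)
  if (!is.null(U_train)) {
    U_train <- as.matrix(U_train)
    if (ncol(U_train) != T_train) stop("U_train must align with Y_train")
    if (is.null(U_test)) stop("U_test is required when U_train is given")
    U_test <- as.matrix(U_test)
    n_test <- ncol(U_test)
  }
  if (is.null(n_test)) stop("n_test must be given for autonomous prediction")
  if (length(lambda) > 1L) {
    tuned <- tune_lambda(Y_train, U_train, lambda, p = p, q = q, r = r,
                         control = control)
    lambda <- tuned$lambda
  }
  if (is.null(r)) {
    r <- max(2L, T_train %/% 3L)
    r <- min(r, (T_train - 1L) %/% 2L)
    if (!is.null(U_train)) {
      # the input Hankel matrix d(r+1) x (T-r) needs a nullspace of dimension
      # at least the system order: cap r so T - r - d(r+1) stays comfortable
      d <- nrow(U_train)
      r <- min(r, max(2L, (T_train - d - 10L) %/% (d + 1L)))
    }
  }
  gamma <- NULL
  if (!is.null(U_train)) {
    d <- nrow(U_train)
    spec_u <- hankel_spec(d, 1L, r + 1L, T_train - r)
    gamma <- nullspace_basis(hankel_map(U_train, spec_u))
  }
  spec <- hankel_spec(m, 1L, r + 1L, T_train - r, gamma = gamma)
  fit <- srm_solve(Y_train, lambda = lambda, p = p, q = q, spec = spec,
                   control = control)
  order <- max(1L, estimate_rank(fit$N, rank_tol))
  if (is.null(max_order)) max_order <- r - 1L
  order <- min(order, max_order)
  model <- realize_lti(fit$L, U_train, order = order, r = r)
  U_full <- if (is.null(U_train)) NULL else cbind(U_train, U_test)
  Y_full <- simulate_lti(model, U_full, T_len = T_train + n_test)
  list(Y_hat = Y_full[, T_train + seq_len(n_test), drop = FALSE],
       model = model, order = order, lambda = lambda, fit = fit)
}
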