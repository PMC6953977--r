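#' Solver controls for the structured rank minimization ADMM
#'
#' @param mu0 Initial penalty parameter; `NULL` uses `5 / ||M||_2` (inverse
#'   spectral norm of the observed trajectory, scaled so the first
#'   singular-value shrinkage retains the dominant dynamics).
#' @param mu_growth Multiplicative penalty growth per iteration.
#' @param mu_max Penalty cap.
#' @param eps1 Feasibility tolerance (residuals relative to `||M||_F`).
#' @param eps2 Iterate-change tolerance (relative to `||M||_F`).
#' @param max_iter Maximum number of iterations.
#' @param K Factor rank for the scalable solver.
#' @param init Initialization of the clean trajectory: `"scaled"` (1.1 times
#'   the observations), `"zeros"`, or `"gaussian"` (standard normal entries).
#' @param seed Seed for the Gaussian initialization.
#' @return A list of class `"srm_control"`.
#' @export
srm_control <- function(mu0 = NULL, mu_growth = 1.1, mu_max = 1e10,
                        eps1 = 1e-4, eps2 = 1e-7, max_iter = 1000L,
                        K = NULL, init = c("scaled", "zeros", "gaussian"),
                        seed = 0L) {
  init <- match.arg(init)
  if (!is.null(mu0) && mu0 <= 0) stop("mu0 must be positive")
  if (mu_growth < 1) stop("mu_growth must be >= 1")
  if (eps1 < 0 || eps2 < 0) stop("tolerances must be nonnegative")
  structure(list(mu0 = mu0, mu_growth = mu_growth, mu_max = mu_max,
                 eps1 = eps1, eps2 = eps2, max_iter = as.integer(max_iter),
                 K = K, init = init, seed = as.integer(seed)),
            class = "srm_control")
}

init_L <- function(M, control) {
  switch(control$init,
         scaled = 1.1 * M,
         zeros = matrix(0, nrow(M), ncol(M)),
         gaussian = {
           set.seed(control$seed)
           matrix(stats::rnorm(length(M)), nrow(M), ncol(M))
         })
}

# Eq.-25-style stopping rule: both feasibility residuals and all three iterate
# changes, relative to ||M||_F, strictly below their tolerances
check_convergence <- function(r1, r2, dN, dL, dE, normM, eps1, eps2) {
  s <- if (normM > 0) normM else 1
  max(r1, r2) / s < eps1 && max(dN, dL, dE) / s < eps2
}

# closed-form E update for the q = 2 (Frobenius fitting) case:
# argmin lambda/mu * ||W o E||_F^2 + 1/2 ||E - Z||_F^2
e_update_q2 <- function(Z, lambda, mu, W) Z / (1 + 2 * lambda * W^2 / mu)

#' Robust structured rank minimization by ADMM
#'
#' Decomposes an observed trajectory `M` into `L + E` where the block-Hankel
#' matrix of `L` has small Schatten p-norm (a rank surrogate) and `E` is
#' sparse in the lq sense, by minimizing
#' `||H(L)||_Sp^p + lambda * ||W o E||_q^q` subject to `M = L + E` with an
#' augmented-Lagrangian alternating scheme. Each iteration applies, in order,
#' the weighted q-shrinkage to update `E`, singular-value p-shrinkage to
#' update the low-rank surrogate `N` of `H(L)`, a closed-form proximal update
#' of `L`, and the dual updates. `q = 2` replaces the shrinkage by the
#' closed-form quadratic update (Frobenius data fit).
#'
#' @param M Observed trajectory, channels by time (`D x T`).
#' @param lambda Positive regularization weight on the sparse term.
#' @param p Schatten exponent in (0, 1].
#' @param q Sparsity exponent in (0, 1], or 2 for a Frobenius fit.
#' @param W Nonnegative weight/mask matrix, same shape as `M`; default all
#'   ones (fully observed).
#' @param spec A [hankel_spec()]; default [default_hankel_spec()] on `M`'s
#'   shape.
#' @param control A [srm_control()].
#' @param L_init Optional explicit initialization of the clean trajectory
#'   (overrides `control$init`); used by the completion pipeline to start
#'   from an interpolation of the missing entries instead of zeros.
#' @return An object of class `"srm_fit"`: the recovered clean trajectory
#'   `L`, sparse component `E`, low-rank surrogate `N` with `rank_estimate`,
#'   per-iteration `objective_trace` and `residual_trace`, `iterations` and
#'   the `converged` flag.
#' @seealso [srm_solve_scalable()] for the factorized large-scale variant.
#' @export
srm_solve <- function(M, lambda, p = 1, q = 1, W = NULL, spec = NULL,
                      control = srm_control(), L_init = NULL) {
  M <- as.matrix(M)
  prob <- srm_check_problem(M, lambda, p, q, W, spec)
  W <- prob$W; spec <- prob$spec
  Lb <- adjoint_norm_bound(spec)
  normM <- sqrt(sum(M^2))
  mu <- control$mu0
  if (is.null(mu)) {
    s1 <- if (normM > 0) svd(M, nu = 0, nv = 0)$d[1] else 1
    mu <- 5 / s1  # first p-shrinkage keeps the dominant dynamics
  }

  L <- if (is.null(L_init)) init_L(M, control) else as.matrix(L_init)
  if (!all(dim(L) == dim(M))) stop("L_init must have the same shape as M")
  E <- matrix(0, nrow(M), ncol(M))
  N <- matrix(0, spec$m * spec$j, hankel_qdim(spec))
  Lam1 <- matrix(0, nrow(M), ncol(M))
  Lam2 <- matrix(0, nrow(N), ncol(N))
  obj_trace <- res_trace <- numeric(control$max_iter)
  converged <- FALSE
  iter <- 0L
  for (i in seq_len(control$max_iter)) {
    iter <- i
    E_new <- {
      Z <- M - L + Lam1 / mu
      if (q == 2) e_update_q2(Z, lambda, mu, W)
      else weighted_q_shrink(Z, lambda / mu, W, q)
    }
    HL <- hankel_map(L, spec)
    N_new <- sv_p_shrink(HL - Lam2 / mu, 1 / mu, p)
    sv <- attr(N_new, "sv")
    L_new <- ((M - E_new + Lam1 / mu) +
                hankel_adjoint(N_new + Lam2 / mu, spec) +
                Lb * L - hankel_adjoint(HL, spec)) / (1 + Lb)
    HL_new <- hankel_map(L_new, spec)
    if (!all(is.finite(L_new)) || !all(is.finite(E_new)))
      stop("non-finite iterate at iteration ", i,
           "; consider a smaller mu_growth or larger lambda")
    Lam1 <- Lam1 + mu * (M - L_new - E_new)
    Lam2 <- Lam2 + mu * (N_new - HL_new)
    r1 <- sqrt(sum((M - L_new - E_new)^2))
    r2 <- sqrt(sum((N_new - HL_new)^2))
    dN <- sqrt(sum((N_new - N)^2))
    dL <- sqrt(sum((L_new - L)^2))
    dE <- sqrt(sum((E_new - E)^2))
    obj_trace[i] <- sum(sv^p) + lambda * sum(abs(W * E_new)^q)
    res_trace[i] <- r1
    L <- L_new; E <- E_new; N <- N_new
    if (check_convergence(r1, r2, dN, dL, dE, normM,
                          control$eps1, control$eps2)) {
      converged <- TRUE
      break
    }
    mu <- min(control$mu_max, control$mu_growth * mu)
  }
  new_srm_fit(L, E, N, obj_trace[seq_len(iter)], res_trace[seq_len(iter)],
              converged, iter, spec, p, q, lambda)
}

srm_check_problem <- function(M, lambda, p, q, W, spec) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be a positive scalar")
  if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
  if (!(q == 2 || (q > 0 && q <= 1)))
    stop("q must lie in (0, 1] or equal 2")
  if (is.null(spec)) spec <- default_hankel_spec(nrow(M), ncol(M))
  if (spec$m != nrow(M) || spec$n_blk * hankel_T(spec) != ncol(M))
    stop("spec does not match the shape of M")
  if (is.null(W)) W <- matrix(1, nrow(M), ncol(M))
  W <- as.matrix(W)
  if (!all(dim(W) == dim(M))) stop("W must have the same shape as M")
  if (any(W < 0)) stop("W must be nonnegative")
  if (any(!is.finite(M[W > 0])))
    stop("M must be finite at observed (positive-weight) entries")
  list(W = W, spec = spec)
}

new_srm_fit <- function(L, E, N, obj, res, converged, iter, spec, p, q,
                        lambda, Q = NULL, R = NULL) {
  structure(list(L = L, E = E, N = N,
                 rank_estimate = estimate_rank(N),
                 objective_trace = obj, residual_trace = res,
                 converged = converged, iterations = iter,
                 spec = spec, p = p, q = q, lambda = lambda,
                 Q = Q, R = R),
            class = "srm_fit")
}

#' @export
print.srm_fit <- function(x, ...) {
  cat(sprintf(
    "Structured rank minimization fit (p = %g, q = %g, lambda = %g)\n",
    x$p, x$q, x$lambda))
  cat(sprintf("  trajectory: %d x %d; Hankel: %d x %d\n",
              nrow(x$L), ncol(x$L), nrow(x$N), ncol(x$N)))
  cat(sprintf("  rank estimate: %d; iterations: %d (%s)\n",
              x$rank_estimate, x$iterations,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  final primal residual: %.3e\n",
              x$residual_trace[length(x$residual_trace)]))
  invisible(x)
}

#' Scalable structured rank minimization (orthonormal factorization)
#'
#' Same model as [srm_solve()] with the low-rank surrogate factorized as
#' `H(L) = Q R`, `Q` column-orthonormal with `K` columns. The Schatten norm is
#' unitarily invariant so the p-shrinkage acts on the small `K x N` factor
#' `R`, and `Q` is updated by the Procrustes projection; SVDs are on
#' `K`-sized matrices instead of the full Hankel matrix.
#'
#' @inheritParams srm_solve
#' @return An `"srm_fit"` whose `N` is the product `Q R` and which carries the
#'   factors in fields `Q` and `R`.
#' @export
srm_solve_scalable <- function(M, lambda, p = 1, q = 1, W = NULL, spec = NULL,
                               control = srm_control()) {
  M <- as.matrix(M)
  prob <- srm_check_problem(M, lambda, p, q, W, spec)
  W <- prob$W; spec <- prob$spec
  K <- control$K
  Mrows <- spec$m * spec$j
  qdim <- hankel_qdim(spec)
  if (is.null(K)) stop("control$K (factor rank) must be set")
  K <- as.integer(K)
  if (K < 1L || K > min(Mrows, qdim))
    stop("K must lie in [1, min(", Mrows, ", ", qdim, ")]")
  Lb <- adjoint_norm_bound(spec)
  normM <- sqrt(sum(M^2))
  mu <- control$mu0
  if (is.null(mu)) {
    s1 <- if (normM > 0) svd(M, nu = 0, nv = 0)$d[1] else 1
    mu <- 5 / s1  # first p-shrinkage keeps the dominant dynamics
  }

  L <- init_L(M, control)
  E <- matrix(0, nrow(M), ncol(M))
  Q <- svd(hankel_map(L, spec), nu = K, nv = 0)$u
  if (ncol(Q) < K)  # degenerate H(L[0]); pad with an orthonormal completion
    Q <- qr.Q(qr(cbind(Q, matrix(stats::rnorm(Mrows * (K - ncol(Q))),
                                 Mrows))))[, seq_len(K), drop = FALSE]
  R <- matrix(0, K, qdim)
  Lam1 <- matrix(0, nrow(M), ncol(M))
  Lam2 <- matrix(0, Mrows, qdim)
  obj_trace <- res_trace <- numeric(control$max_iter)
  converged <- FALSE
  iter <- 0L
  N <- Q %*% R
  for (i in seq_len(control$max_iter)) {
    iter <- i
    E_new <- {
      Z <- M - L + Lam1 / mu
      if (q == 2) e_update_q2(Z, lambda, mu, W)
      else weighted_q_shrink(Z, lambda / mu, W, q)
    }
    HL <- hankel_map(L, spec)
    G <- HL - Lam2 / mu
    R_new <- sv_p_shrink(crossprod(Q, G), 1 / mu, p)
    sv <- attr(R_new, "sv")
    Q_new <- procrustes(G %*% t(R_new))
    N_new <- Q_new %*% R_new
    L_new <- ((M - E_new + Lam1 / mu) +
                hankel_adjoint(N_new + Lam2 / mu, spec) +
                Lb * L - hankel_adjoint(HL, spec)) / (1 + Lb)
    HL_new <- hankel_map(L_new, spec)
    if (!all(is.finite(L_new)) || !all(is.finite(E_new)))
      stop("non-finite iterate at iteration ", i)
    Lam1 <- Lam1 + mu * (M - L_new - E_new)
    Lam2 <- Lam2 + mu * (N_new - HL_new)
    r1 <- sqrt(sum((M - L_new - E_new)^2))
    r2 <- sqrt(sum((N_new - HL_new)^2))
    dN <- sqrt(sum((N_new - N)^2))
    dL <- sqrt(sum((L_new - L)^2))
    dE <- sqrt(sum((E_new - E)^2))
    obj_trace[i] <- sum(sv^p) + lambda * sum(abs(W * E_new)^q)
    res_trace[i] <- r1
    L <- L_new; E <- E_new; N <- N_new; Q <- Q_new; R <- R_new
    if (check_convergence(r1, r2, dN, dL, dE, normM,
                          control$eps1, control$eps2)) {
      converged <- TRUE
      break
    }
    mu <- min(control$mu_max, control$mu_growth * mu)
  }
  new_srm_fit(L, E, N, obj_trace[seq_len(iter)], res_trace[seq_len(iter)],
              converged, iter, spec, p, q, lambda, Q = Q, R = R)
}

#' Numerical rank from singular values
#'
#' Counts the singular values exceeding `rel_tol` times the largest one. The
#' default tolerance of 1e-3 reflects that the solver's low-rank surrogate
#' carries small residual singular values which a machine-precision threshold
#' would over-count.
#'
#' @param N Numeric matrix.
#' @param rel_tol Relative threshold.
#' @return Integer rank estimate.
#' @export
estimate_rank <- function(N, rel_tol = 1e-3) {
  N <- as.matrix(N)
  if (any(!is.finite(N))) stop("N must be finite")
  d <- svd(N, nu = 0, nv = 0)$d
  if (length(d) == 0L || d[1] == 0) return(0L)
  sum(d > rel_tol * d[1])
}

#' Tune the sparsity weight by trailing hold-out validation
#'
#' Withholds the last `2 * r` training samples, runs the prediction pipeline
#' ([predict_behavior()]) on the remainder for every candidate `lambda`, and
#' scores the Pearson correlation between the predictions and the held-out
#' outputs. Returns the candidate with the highest validation correlation,
#' ties resolving to the smallest `lambda`.
#'
#' @param Y Training outputs, `m x T`.
#' @param U Training inputs, `d x T`, or `NULL` for an autonomous system.
#' @param lambda_grid Numeric vector of candidate values.
#' @param p,q Norm exponents, as in [srm_solve()].
#' @param r Hankel depth used by the pipeline (also sets the hold-out size).
#' @param control A [srm_control()].
#' @param ... Passed on to [predict_behavior()].
#' @return List with `lambda` (selected), `score`, and the full `scores`
#'   vector over the (sorted) grid.
#' @export
tune_lambda <- function(Y, U = NULL, lambda_grid, p = 1, q = 1, r = NULL,
                        control = srm_control(), ...) {
  if (length(lambda_grid) == 0L) stop("lambda_grid must be nonempty")
  lambda_grid <- sort(lambda_grid)
  Y <- as.matrix(Y)
  T_all <- ncol(Y)
  if (is.null(r)) {
    r <- max(1L, (T_all %/% 3L))
    r <- min(r, (T_all - 1L) %/% 2L)
  }
  n_hold <- 2L * r
  if (n_hold >= T_all - 2L)
    stop("not enough samples to hold out 2r = ", n_hold, " columns")
  fit_idx <- seq_len(T_all - n_hold)
  val_idx <- (T_all - n_hold + 1L):T_all
  Y_val <- Y[, val_idx, drop = FALSE]
  if (stats::sd(as.vector(Y_val)) == 0)
    stop("validation target has zero variance; cannot score correlation")
  scores <- vapply(lambda_grid, function(lam) {
    pred <- tryCatch(
      predict_behavior(Y[, fit_idx, drop = FALSE],
                       if (is.null(U)) NULL else U[, fit_idx, drop = FALSE],
                       if (is.null(U)) NULL else U[, val_idx, drop = FALSE],
                       n_test = length(val_idx),
                       p = p, q = q, lambda = lam, control = control, ...),
      error = function(e) NULL)
    if (is.null(pred)) return(-Inf)
    yh <- as.vector(pred$Y_hat)
    if (!all(is.finite(yh)) || stats::sd(yh) == 0) return(-Inf)
    pearson_cor(as.vector(Y_val), yh)
  }, numeric(1))
  if (all(!is.finite(scores)))
    stop("no lambda in the grid produced a usable validation prediction")
  best <- which.max(scores)  # first max = smallest lambda on ties
  list(lambda = lambda_grid[best], score = scores[best], scores = scores)
}
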