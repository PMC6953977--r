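#' Soft thresholding (shrinkage) operator
#'
#' Elementwise `sgn(x) * max(|x| - alpha, 0)`, the proximal operator of the
#' l1 norm.
#'
#' @param x Numeric scalar, vector or matrix.
#' @param alpha Nonnegative threshold.
#' @return Object of the same shape as `x`.
#' @export
soft_threshold <- function(x, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("alpha must be a nonnegative scalar")
  sign(x) * pmax(abs(x) - alpha, 0)
}

#' Generalized q-shrinkage operator
#'
#' Elementwise global minimizer of `h(b) = alpha*|b|^q + (b - z)^2 / 2` for
#' `q` in (0, 1]. For `q = 1` this is exactly [soft_threshold()]. For `q < 1`
#' the minimizer follows a three-case rule: zero whenever `|z| <= c2` with
#' `c1 = (alpha*q*(1-q))^(1/(2-q))`, `c2 = c1 + alpha*q*c1^(q-1)`; otherwise
#' the candidate root of `h'` in `[c1, |z|]` (found by Newton-Raphson started
#' at `|z|`, with a bisection fallback) is compared against 0 and the argmin
#' is returned, ties resolving to 0 for maximal sparsity.
#'
#' @param z Numeric scalar, vector or matrix.
#' @param alpha Positive threshold.
#' @param q Exponent in (0, 1].
#' @param max_iter,tol Newton-Raphson controls (stopping on `|h'| < tol`).
#' @return Object of the same shape as `z`.
#' @export
q_shrink <- function(z, alpha, q, max_iter = 100L, tol = 1e-12) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 1)
    stop("q must lie in (0, 1]")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("alpha must be a nonnegative scalar")
  if (q == 1) return(soft_threshold(z, alpha))
  if (alpha == 0) return(z)
  out <- z
  az <- abs(z)
  c1 <- (alpha * q * (1 - q))^(1 / (2 - q))
  c2 <- c1 + alpha * q * c1^(q - 1)
  out[az <= c2] <- 0
  act <- which(az > c2)
  if (length(act)) {
    zz <- az[act]
    b <- newton_root_magnitude(zz, alpha, q, c1, max_iter, tol)
    # pick the argmin of h among {0, root}; ties resolve to 0
    h_root <- alpha * b^q + 0.5 * (b - zz)^2
    h_zero <- 0.5 * zz^2
    b[h_root >= h_zero] <- 0
    out[act] <- sign(z[act]) * b
  }
  out
}

# vectorized Newton-Raphson for the positive root of
# g(b) = alpha*q*b^(q-1) + b - z on (c1, z], started at z; g is increasing and
# convex there, so the iteration descends monotonically onto the root
newton_root_magnitude <- function(z, alpha, q, c1, max_iter, tol) {
  b <- z
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- alpha * q * b^(q - 1) + b - z
    live <- abs(g) >= tol
    if (!any(live)) { converged <- TRUE; break }
    gp <- alpha * q * (q - 1) * b[live]^(q - 2) + 1
    step <- g[live] / gp
    bn <- b[live] - step
    # keep iterates inside the bracket (c1, z]
    bad <- !is.finite(bn) | bn <= c1 | bn > z[live]
    bn[bad] <- (b[live][bad] + c1) / 2
    b[live] <- bn
  }
  if (!converged) {
    g <- alpha * q * b^(q - 1) + b - z
    stuck <- which(abs(g) >= tol)
    if (length(stuck)) {
      warning("Newton-Raphson did not converge for ", length(stuck),
              " entries; falling back to bisection")
      for (i in stuck) b[i] <- bisect_root(z[i], alpha, q, c1)
    }
  }
  b
}

bisect_root <- function(z, alpha, q, c1, iters = 200L) {
  lo <- c1; hi <- z
  for (it in seq_len(iters)) {
    mid <- (lo + hi) / 2
    g <- alpha * q * mid^(q - 1) + mid - z
    if (g > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Entrywise weighted q-shrinkage
#'
#' Applies [q_shrink()] with per-entry threshold `alpha * W[i, j]`; entries
#' with zero weight carry no penalty and pass through unchanged.
#'
#' @param Z Numeric matrix.
#' @param alpha Positive base threshold.
#' @param W Nonnegative weight matrix of the same shape as `Z`.
#' @param q Exponent in (0, 1].
#' @return Matrix of the same shape as `Z`.
#' @export
weighted_q_shrink <- function(Z, alpha, W, q) {
  Z <- as.matrix(Z); W <- as.matrix(W)
  if (!all(dim(W) == dim(Z)))
    stop("W must have the same shape as Z")
  if (any(W < 0)) stop("weights must be nonnegative")
  out <- Z
  for (w in unique(as.vector(W))) {
    idx <- W == w
    out[idx] <- if (w == 0) Z[idx] else q_shrink(Z[idx], alpha * w, q)
  }
  out
}

#' Generalized singular-value p-shrinkage
#'
#' Applies [q_shrink()] with exponent `p` to the singular values of `Z`,
#' leaving the singular vectors untouched: the proximal operator of the
#' Schatten p-norm raised to the power p (for `p = 1`, singular-value soft
#' thresholding).
#'
#' @param Z Numeric matrix.
#' @param alpha Nonnegative threshold; 0 returns `Z` unchanged.
#' @param p Exponent in (0, 1].
#' @return Matrix of the same shape as `Z`, with the shrunken singular values
#'   attached as attribute `"sv"`.
#' @export
sv_p_shrink <- function(Z, alpha, p) {
  Z <- as.matrix(Z)
  if (any(!is.finite(Z))) stop("Z must be finite")
  if (alpha == 0) {
    attr(Z, "sv") <- svd(Z, nu = 0, nv = 0)$d
    return(Z)
  }
  s <- tryCatch(svd(Z), error = function(e)
    stop("SVD failed in sv_p_shrink: ", conditionMessage(e)))
  d <- q_shrink(s$d, alpha, p)
  B <- s$u %*% (d * t(s$v))
  attr(B, "sv") <- d
  B
}

#' Procrustes projection onto column-orthonormal matrices
#'
#' Returns `U %*% t(V)` from the thin SVD `A = U S V'`: the closest (in
#' Frobenius norm) matrix with orthonormal columns, equivalently the maximizer
#' of `<P, A>` over orthonormal `P`.
#'
#' @param A Matrix with at least as many rows as columns.
#' @return Column-orthonormal matrix of the same shape as `A`.
#' @export
procrustes <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) < ncol(A))
    stop("A must have at least as many rows as columns")
  s <- svd(A)
  s$u %*% t(s$v)
}
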