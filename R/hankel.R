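#' Block-Hankel geometry specification
#'
#' Describes the block-Hankel linear map used throughout the package: a
#' trajectory with `m x n_blk` blocks over `T = j + k - 1` time samples is
#' rearranged into an `(m*j) x (n_blk*k)` block-Hankel matrix (constant blocks
#' along skew diagonals) and optionally right-multiplied by a matrix `gamma`
#' with largest singular value at most 1.
#'
#' `gamma = NULL` means the identity (no right multiplication); this is the
#' autonomous, output-only case. For input-output problems `gamma` is taken as
#' an orthonormal basis of the nullspace of the input Hankel matrix (see
#' [nullspace_basis()]), which satisfies the singular-value condition by
#' construction.
#'
#' @param m Block height (channels per time sample).
#' @param n_blk Block width; 1 for the usual vector-valued trajectories.
#' @param j Number of block rows.
#' @param k Number of block columns.
#' @param gamma Optional `(n_blk*k) x q_dim` right multiplier, or `NULL` for
#'   the identity.
#' @return An object of class `"hankel_spec"`.
#' @examples
#' sp <- hankel_spec(m = 1, n_blk = 1, j = 2, k = 2)
#' hankel_map(matrix(1:3, 1), sp)
#' @export
hankel_spec <- function(m, n_blk = 1L, j, k, gamma = NULL) {
  m <- as.integer(m); n_blk <- as.integer(n_blk)
  j <- as.integer(j); k <- as.integer(k)
  if (m < 1L || n_blk < 1L || j < 1L || k < 1L)
    stop("all block-Hankel dimensions must be positive integers")
  if (!is.null(gamma)) {
    gamma <- as.matrix(gamma)
    if (nrow(gamma) != n_blk * k)
      stop("gamma must have n_blk*k = ", n_blk * k, " rows, got ", nrow(gamma))
    smax <- if (all(gamma == 0)) 0 else svd(gamma, nu = 0, nv = 0)$d[1]
    # slack for floating-point orthonormalization
    if (smax > 1 + 1e-8)
      stop("largest singular value of gamma must be <= 1 (got ",
           format(smax), ")")
  }
  structure(list(m = m, n_blk = n_blk, j = j, k = k, gamma = gamma),
            class = "hankel_spec")
}

#' @export
print.hankel_spec <- function(x, ...) {
  cat(sprintf("Block-Hankel spec: %d x %d blocks of size %d x %d (T = %d)\n",
              x$j, x$k, x$m, x$n_blk, hankel_T(x)))
  if (is.null(x$gamma)) {
    cat("gamma: identity\n")
  } else {
    cat(sprintf("gamma: %d x %d\n", nrow(x$gamma), ncol(x$gamma)))
  }
  invisible(x)
}

#' Number of time samples consumed by a Hankel spec
#' @param spec A [hankel_spec()].
#' @return Integer `j + k - 1`.
#' @export
hankel_T <- function(spec) spec$j + spec$k - 1L

# number of columns after the optional right multiplication
hankel_qdim <- function(spec) {
  if (is.null(spec$gamma)) spec$n_blk * spec$k else ncol(spec$gamma)
}

check_trajectory <- function(A, spec) {
  A <- as.matrix(A)
  if (nrow(A) != spec$m || ncol(A) != spec$n_blk * hankel_T(spec))
    stop("trajectory must be ", spec$m, " x ", spec$n_blk * hankel_T(spec),
         " for this spec, got ", nrow(A), " x ", ncol(A))
  A
}

#' Block-Hankel linear map
#'
#' Arranges the time blocks of a trajectory into the block-Hankel matrix whose
#' block `(a, b)` is time block `a + b`, then right-multiplies by
#' `spec$gamma` if present.
#'
#' @param A Trajectory matrix, `m x n_blk*(j+k-1)`.
#' @param spec A [hankel_spec()].
#' @return The `(m*j) x q_dim` (block-)Hankel matrix.
#' @export
hankel_map <- function(A, spec) {
  A <- check_trajectory(A, spec)
  m <- spec$m; nb <- spec$n_blk; j <- spec$j; k <- spec$k
  H <- matrix(0, m * j, nb * k)
  if (nb == 1L) {
    for (b in seq_len(k)) H[, b] <- A[, b:(b + j - 1L)]
  } else {
    for (b in seq_len(k)) {
      for (cc in seq_len(nb)) {
        H[, (b - 1L) * nb + cc] <- A[, ((b - 1L):(b + j - 2L)) * nb + cc]
      }
    }
  }
  if (!is.null(spec$gamma)) H <- H %*% spec$gamma
  H
}

#' Adjoint of the block-Hankel map
#'
#' Right-multiplies by `t(gamma)` (if present) and sums the blocks of the
#' resulting `(m*j) x (n_blk*k)` matrix along each skew diagonal of the block
#' grid, producing an `m x n_blk*(j+k-1)` trajectory.
#'
#' @param B Matrix of shape `(m*j) x q_dim` conforming to `spec`.
#' @param spec A [hankel_spec()].
#' @return Trajectory matrix `m x n_blk*(j+k-1)`.
#' @export
hankel_adjoint <- function(B, spec) {
  B <- as.matrix(B)
  m <- spec$m; nb <- spec$n_blk; j <- spec$j; k <- spec$k
  if (nrow(B) != m * j || ncol(B) != hankel_qdim(spec))
    stop("matrix must be ", m * j, " x ", hankel_qdim(spec),
         " for this spec, got ", nrow(B), " x ", ncol(B))
  if (!is.null(spec$gamma)) B <- B %*% t(spec$gamma)
  Tn <- hankel_T(spec)
  out <- matrix(0, m, nb * Tn)
  for (b in seq_len(k)) {
    cols <- ((b - 1L):(b + j - 2L)) * nb
    for (cc in seq_len(nb)) {
      idx <- cols + cc
      out[, idx] <- out[, idx] + matrix(B[, (b - 1L) * nb + cc], m, j)
    }
  }
  out
}

#' Spectral bound for the Hankel adjoint-map composition
#'
#' Returns `min(j, k)`, the constant `L` such that
#' `||H*(B)||_F^2 <= L ||B||_F^2`, used as the proximal constant in the
#' solver's trajectory update.
#'
#' @param spec A [hankel_spec()].
#' @return Scalar bound.
#' @export
adjoint_norm_bound <- function(spec) min(spec$j, spec$k)

#' Apply the proximal operator matrix Q0
#'
#' Computes `L*P - H*(H(P))` where `L = min(j,k)`; the induced quadratic form
#' is positive semi-definite, which makes the trajectory update of the ADMM
#' solver a closed-form expression.
#'
#' @param P Trajectory matrix conformable with `spec`.
#' @param spec A [hankel_spec()].
#' @return Trajectory matrix of the same shape as `P`.
#' @export
apply_q0 <- function(P, spec) {
  P <- check_trajectory(P, spec)
  adjoint_norm_bound(spec) * P - hankel_adjoint(hankel_map(P, spec), spec)
}

# multiplicity of each time block on the Hankel skew diagonals:
# number of (a, b), 0-based, with a + b = t
hankel_multiplicity <- function(spec) {
  Tn <- hankel_T(spec)
  t0 <- 0:(Tn - 1L)
  pmin(t0, spec$j - 1L, spec$k - 1L, Tn - 1L - t0) + 1L
}

# average the skew-diagonal copies of a pre-gamma Hankel matrix back into a
# trajectory; requires gamma = identity
dehankel_average <- function(B, spec) {
  if (!is.null(spec$gamma))
    stop("skew-diagonal averaging requires gamma = identity")
  mult <- rep(hankel_multiplicity(spec), each = spec$n_blk)
  sweep(hankel_adjoint(B, spec), 2, mult, "/")
}

#' Default Hankel split for a length-T trajectory
#'
#' Chooses the depth parameter `r` as `max(n_hint + 1, floor(T/3))` capped at
#' `floor((T-1)/2)`, and sets `j = r + 1`, `k = T - r`. The cap keeps the
#' matrix at least as wide as tall in the scalar case; `r` can be overridden.
#'
#' @param D Number of channels (block height).
#' @param T_len Number of time samples.
#' @param r Optional explicit depth (`j = r + 1`, `k = T - r`).
#' @param n_hint Lower bound hint for the system order.
#' @param gamma Optional right multiplier passed to [hankel_spec()].
#' @return A [hankel_spec()].
#' @export
default_hankel_spec <- function(D, T_len, r = NULL, n_hint = 0L, gamma = NULL) {
  T_len <- as.integer(T_len)
  if (is.null(r)) {
    r <- max(n_hint + 1L, T_len %/% 3L)
    r <- min(r, (T_len - 1L) %/% 2L)
  }
  r <- as.integer(r)
  if (r < 1L || r >= T_len)
    stop("depth r must satisfy 1 <= r < T")
  hankel_spec(m = D, n_blk = 1L, j = r + 1L, k = T_len - r, gamma = gamma)
}
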