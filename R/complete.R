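#' Binary observation mask
#'
#' Builds the `D x T` weight matrix that is 1 at observed positions and 0
#' elsewhere, from a two-column (row, col) index matrix of observed entries.
#'
#' @param D,T_len Matrix dimensions.
#' @param observed Two-column integer matrix (or data.frame) of observed
#'   (row, col) indices, 1-based.
#' @return `D x T_len` 0/1 matrix.
#' @export
build_mask <- function(D, T_len, observed) {
  W <- matrix(0, D, T_len)
  if (is.null(observed) || NROW(observed) == 0L) return(W)
  observed <- as.matrix(observed)
  if (ncol(observed) != 2L) stop("observed must have two columns (row, col)")
  if (any(observed[, 1] < 1 | observed[, 1] > D |
          observed[, 2] < 1 | observed[, 2] > T_len))
    stop("observed indices out of range")
  W[observed] <- 1
  W
}

#' Structured completion of a trajectory with missing entries
#'
#' Runs the structured rank minimization solver with a 0/1 observation mask
#' and reads the missing entries off the low-rank Hankel surrogate by
#' averaging the skew-diagonal copies of each trajectory entry. Observed
#' entries are kept as recovered (`L`, the observations minus the sparse
#' correction). Missing entries may be flagged either by `NA`s in `M` or by
#' zeros in `W`.
#'
#' @param M Trajectory `D x T`, `NA` at missing entries (or any value if `W`
#'   is given). When the system has inputs, stack outputs over inputs.
#' @param W Optional 0/1 mask (1 = observed); derived from `is.na(M)` when
#'   missing.
#' @param lambda Regularization weight.
#' @param p,q Norm exponents; the tracklet pipeline uses `q = 2`.
#' @param spec Optional [hankel_spec()] (gamma must be identity).
#' @param control A [srm_control()]. The completion default keeps the penalty
#'   constant (`mu_growth = 1`): annealing removes the singular-value
#'   shrinkage pressure before weakly covered entries (early/late samples,
#'   which appear in few skew diagonals) have converged.
#' @param refine Number of alternating-projection polish iterations per
#'   candidate rank (rank-r SVD truncation of the Hankel matrix alternated
#'   with restoring the observed entries, at the smallest rank consistent
#'   with the observations); 0 disables the polish.
#' @return List with `completed` (`D x T`), `rank` and the solver `fit`.
#' @export
complete_trajectory <- function(M, lambda, p = 1, q = 1, W = NULL,
                                spec = NULL,
                                control = srm_control(mu_growth = 1,
                                                      eps1 = 1e-7,
                                                      eps2 = 1e-9,
                                                      max_iter = 3000L),
                                refine = 200L) {
  M <- as.matrix(M)
  if (is.null(W)) W <- 1 * !is.na(M)
  W <- as.matrix(W)
  if (any(rowSums(W) == 0))
    stop("every channel needs at least one observed entry")
  M[W == 0] <- 0
  if (is.null(spec)) spec <- default_hankel_spec(nrow(M), ncol(M))
  if (!is.null(spec$gamma))
    stop("completion requires an identity gamma (autonomous Hankel map)")
  # start from an interpolation of the missing entries: a zero fill plants
  # spurious spikes in the Hankel matrix that the annealed iteration can
  # freeze around
  M_fill <- M
  for (i in seq_len(nrow(M))) {
    obs <- which(W[i, ] > 0)
    if (length(obs) < ncol(M))
      M_fill[i, -obs] <- stats::approx(obs, M[i, obs], xout = seq_len(ncol(M))[-obs],
                                       rule = 2)$y
  }
  fit <- srm_solve(M, lambda = lambda, p = p, q = q, W = W, spec = spec,
                   control = control, L_init = 1.1 * M_fill)
  filled <- dehankel_average(fit$N, spec)
  completed <- fit$L
  completed[W == 0] <- filled[W == 0]
  rank <- fit$rank_estimate
  if (refine > 0L && rank > 0L && any(W == 0))
    completed <- refine_completion(completed, W, rank, iters = refine)
  list(completed = completed, rank = rank, fit = fit)
}

# annihilating-filter polish of the completion: a rank-r Hankel trajectory
# obeys an order-r linear recurrence shared by all channels; the filter is the
# smallest right singular vector of the (r+1)-column block-Hankel matrix,
# estimated from the fully observed windows when enough exist so that it is
# untouched by the filled values, and the missing entries then solve the
# resulting linear least-squares system. A couple of outer iterations
# re-estimate the filter when too few clean windows are available.
refine_completion <- function(completed, W, rank, iters = 5L) {
  D <- nrow(completed)
  T_len <- ncol(completed)
  r <- as.integer(rank)
  if (r + 2L >= T_len) return(completed)
  miss <- which(W == 0)
  miss_t <- unique(((miss - 1L) %/% D) + 1L)
  nw <- T_len - r
  spec2 <- hankel_spec(D, 1L, nw, r + 1L)
  clean_win <- vapply(seq_len(nw),
                      function(t) !any((t:(t + r)) %in% miss_t), logical(1))
  for (it in seq_len(iters)) {
    H <- hankel_map(completed, spec2)
    Ho <- if (sum(clean_win) >= r + 2L) {
      rows <- as.vector(outer(seq_len(D), (which(clean_win) - 1L) * D, "+"))
      H[rows, , drop = FALSE]
    } else H
    a <- svd(Ho, nu = 0)$v[, r + 1L]
    A <- matrix(0, nw * D, length(miss))
    b <- numeric(nw * D)
    row <- 0L
    for (t in seq_len(nw)) {
      for (d in seq_len(D)) {
        row <- row + 1L
        for (i in 0:r) {
          idx <- (t + i - 1L) * D + d
          mpos <- match(idx, miss)
          if (!is.na(mpos)) A[row, mpos] <- a[i + 1L]
          else b[row] <- b[row] - a[i + 1L] * completed[d, t + i]
        }
      }
    }
    sol <- tryCatch(lstsq(A, b), error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol))) break
    delta <- sqrt(sum((sol - completed[miss])^2))
    completed[miss] <- sol
    if (delta < 1e-13 * max(sqrt(sum(completed^2)), 1) ||
        sum(clean_win) >= r + 2L) break  # clean-window filter: one pass exact
  }
  completed
}
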