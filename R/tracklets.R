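#' Tracklet: a contiguous fragment of one target's 2-D detections
#'
#' @param id Identity label.
#' @param start First frame (integer).
#' @param coords `2 x len` matrix of (x, y) detections, one column per frame.
#' @param imputed Optional logical vector marking imputed (gap-filled) frames.
#' @return An object of class `"tracklet"`.
#' @export
tracklet <- function(id, start, coords, imputed = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) != 2L) stop("coords must be a 2 x len matrix")
  if (any(!is.finite(coords))) stop("coords must be finite")
  if (is.null(imputed)) imputed <- rep(FALSE, ncol(coords))
  structure(list(id = id, start = as.integer(start), coords = coords,
                 imputed = imputed), class = "tracklet")
}

tracklet_end <- function(tr) tr$start + ncol(tr$coords) - 1L
tracklet_frames <- function(tr) tr$start:tracklet_end(tr)

#' @export
print.tracklet <- function(x, ...) {
  cat(sprintf("Tracklet %s: frames %d-%d (%d detections, %d imputed)\n",
              format(x$id), x$start, tracklet_end(x), ncol(x$coords),
              sum(x$imputed)))
  invisible(x)
}

#' Read tracklets from a MOT-style delimited file
#'
#' Expects comma-separated columns `frame, id, x, y` (extra columns are
#' ignored). Non-contiguous frame runs of one identity are split into
#' separate tracklets.
#'
#' @param path File path.
#' @return List of [tracklet()] objects.
#' @export
read_tracklets <- function(path) {
  tab <- utils::read.csv(path, header = FALSE)
  if (ncol(tab) < 4L) stop("expected at least 4 columns: frame, id, x, y")
  names(tab)[1:4] <- c("frame", "id", "x", "y")
  out <- list()
  for (ident in unique(tab$id)) {
    sub <- tab[tab$id == ident, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    runs <- cumsum(c(1L, diff(sub$frame) != 1L))
    for (rr in unique(runs)) {
      blk <- sub[runs == rr, , drop = FALSE]
      out[[length(out) + 1L]] <- tracklet(ident, blk$frame[1],
                                          rbind(blk$x, blk$y))
    }
  }
  out
}

#' Write tracklets to a MOT-style delimited file
#'
#' Emits `frame, id, x, y, imputed` rows; `imputed` is 1 for gap-filled
#' detections.
#'
#' @param tracklets List of [tracklet()] objects.
#' @param path File path.
#' @export
write_tracklets <- function(tracklets, path) {
  rows <- do.call(rbind, lapply(tracklets, function(tr) {
    data.frame(frame = tracklet_frames(tr), id = tr$id,
               x = tr$coords[1, ], y = tr$coords[2, ],
               imputed = as.integer(tr$imputed))
  }))
  rows <- rows[order(rows$frame, rows$id), ]
  utils::write.table(rows, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# numerical Hankel rank of a tracklet's coordinate trajectory
tracklet_rank <- function(coords, rank_tol = 1e-3) {
  T_len <- ncol(coords)
  if (T_len < 3L) return(min(2L, T_len))
  spec <- default_hankel_spec(2L, T_len)
  estimate_rank(hankel_map(coords, spec), rank_tol)
}

#' Dynamical similarity of two tracklets
#'
#' Builds the joint trajectory `[Yi, gap, Yj]` with the intermediate block
#' masked as missing, completes it by structured rank minimization, and
#' scores how much dynamical complexity the join adds:
#' `p_ij = (rank H(Yi) + rank H(Yj)) / (2 * rank H(completed))`, clipped to
#' \[0, 1\]. The score is 1 exactly when joining adds no complexity (both
#' fragments are outputs of the same autonomous LTI system) and decreases as
#' the joint system order grows. Temporally incompatible pairs score 0.
#'
#' @param ti,tj [tracklet()] objects; `ti` must end before `tj` starts.
#' @param lambda Regularization weight for the completion.
#' @param p Schatten exponent.
#' @param q Sparsity exponent; 2 (Frobenius fit) is the tracking default.
#' @param rank_tol Relative threshold for the rank estimates.
#' @param control A [srm_control()]; the tracking pipeline tightens both
#'   tolerances to 1e-7.
#' @return List with the similarity `p` and the completed `gap_coords`
#'   (`2 x gap`, `NULL` when the gap is empty).
#' @export
tracklet_similarity <- function(ti, tj, lambda = 100, p = 0.5, q = 2,
                                rank_tol = 1e-3,
                                control = srm_control(eps1 = 1e-7,
                                                      eps2 = 1e-7)) {
  gap <- tj$start - tracklet_end(ti) - 1L
  if (gap < 0L) return(list(p = 0, gap_coords = NULL))
  M <- cbind(ti$coords, matrix(NA_real_, 2L, gap), tj$coords)
  if (ncol(M) < 6L) {
    # too short for a meaningful Hankel completion: with no gap the raw joint
    # rank still scores the pair, otherwise the pair cannot be assessed
    if (gap > 0L) return(list(p = 0, gap_coords = NULL))
    r_joint <- tracklet_rank(M, rank_tol)
    pij <- (tracklet_rank(ti$coords, rank_tol) +
              tracklet_rank(tj$coords, rank_tol)) / (2 * max(1L, r_joint))
    return(list(p = min(1, max(0, pij)), gap_coords = NULL))
  }
  cmp <- complete_trajectory(M, lambda = lambda, p = p, q = q,
                             control = control)
  r_joint <- tracklet_rank(cmp$completed, rank_tol)
  r_i <- tracklet_rank(ti$coords, rank_tol)
  r_j <- tracklet_rank(tj$coords, rank_tol)
  pij <- (r_i + r_j) / (2 * max(1L, r_joint))
  gap_coords <- if (gap > 0L)
    cmp$completed[, ncol(ti$coords) + seq_len(gap), drop = FALSE] else NULL
  list(p = min(1, max(0, pij)), gap_coords = gap_coords)
}

#' Generalized linear assignment by the Hungarian algorithm
#'
#' Maximizes `sum(P * K)` over binary adjacency matrices `K` whose rows and
#' columns each sum to at most 1 (a partial matching: `k[i, j] = 1` reads
#' "tracklet i precedes tracklet j"). Entries below `threshold` are never
#' matched. Solved exactly by the Hungarian algorithm on a matrix padded so
#' the inequality constraints become a square assignment.
#'
#' @param P Square similarity matrix with zero diagonal.
#' @param threshold Minimum similarity for a match.
#' @return List with binary matrix `K` and the achieved `objective`.
#' @export
gla_match <- function(P, threshold = 0) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (ncol(P) != n) stop("P must be square")
  W <- P
  W[W < threshold] <- 0
  sol <- hungarian_max(W)
  K <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    j <- sol[i]
    if (j > 0 && W[i, j] > 0 && P[i, j] >= threshold) K[i, j] <- 1L
  }
  list(K = K, objective = sum(P * K))
}

# maximum-weight perfect matching on a square nonnegative matrix via the
# shortest-augmenting-path (Jonker-Volgenant) method, O(n^3); slot n+1 plays
# the role of the virtual start column; returns the column assigned to each row
hungarian_max <- function(W) {
  n <- nrow(W)
  if (n == 0L) return(integer(0))
  C <- max(W) - W  # minimize cost
  u <- numeric(n)         # row potentials
  v <- numeric(n + 1L)    # column potentials (slot n+1 = virtual)
  p_col <- integer(n + 1L)  # row matched to column j, 0 = unmatched
  for (i in seq_len(n)) {
    p_col[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    way <- integer(n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p_col[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- C[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p_col[j] > 0L) u[p_col[j]] <- u[p_col[j]] + delta
          v[j] <- v[j] - delta
        } else if (j <= n) {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p_col[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p_col[j0] <- p_col[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p_col[j] > 0L) assign[p_col[j]] <- j
  assign
}

#' Stitch tracklets into full trajectories
#'
#' Scores every temporally admissible ordered pair (predecessor ends before
#' successor starts, gap at most `max_gap`) with [tracklet_similarity()],
#' solves the generalized linear assignment, concatenates the resulting
#' predecessor chains and fills the gaps with the completed coordinates.
#'
#' @param tracklets List of [tracklet()] objects.
#' @param lambda,p,q,control Passed to [tracklet_similarity()].
#' @param max_gap Maximum allowed gap (frames) between matched tracklets.
#' @param threshold Minimum similarity for a match.
#' @return List with `tracklets` (merged set, imputed frames flagged), the
#'   similarity matrix `P` and the assignment `K`.
#' @export
stitch_tracklets <- function(tracklets, lambda = 100, p = 0.5, q = 2,
                             max_gap = 20L, threshold = 0.5,
                             control = srm_control(eps1 = 1e-7,
                                                   eps2 = 1e-7)) {
  n <- length(tracklets)
  if (n <= 1L)
    return(list(tracklets = tracklets, P = matrix(0, n, n),
                K = matrix(0L, n, n)))
  P <- matrix(0, n, n)
  gaps <- vector("list", n)
  for (i in seq_len(n)) gaps[[i]] <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      gap <- tracklets[[j]]$start - tracklet_end(tracklets[[i]]) - 1L
      if (gap < 0L || gap > max_gap) next
      sim <- tracklet_similarity(tracklets[[i]], tracklets[[j]],
                                 lambda = lambda, p = p, q = q,
                                 control = control)
      P[i, j] <- sim$p
      gaps[[i]][j] <- list(sim$gap_coords)  # keeps NULLs as empty slots
    }
  }
  match <- gla_match(P, threshold)
  K <- match$K
  succ <- apply(K, 1, function(row) if (any(row == 1L)) which(row == 1L) else 0L)
  has_pred <- colSums(K) > 0
  merged <- list()
  for (head in seq_len(n)) {
    if (has_pred[head]) next  # chains start at tracklets with no predecessor
    cur <- head
    tr <- tracklets[[cur]]
    while (succ[cur] > 0L) {
      nxt <- succ[cur]
      gap_coords <- gaps[[cur]][[nxt]]
      gap <- tracklets[[nxt]]$start - tracklet_end(tr) - 1L
      if (gap > 0L && is.null(gap_coords))
        gap_coords <- matrix(NA_real_, 2L, gap)
      tr <- tracklet(tr$id, tr$start,
                     cbind(tr$coords, gap_coords, tracklets[[nxt]]$coords),
                     imputed = c(tr$imputed, rep(TRUE, gap),
                                 tracklets[[nxt]]$imputed))
      cur <- nxt
    }
    merged[[length(merged) + 1L]] <- tr
  }
  list(tracklets = merged, P = P, K = K)
}
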