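#' Relative reconstruction error
#'
#' `||s - s_hat|| / ||s||` in the Euclidean/Frobenius norm.
#'
#' @param s Reference signal (vector or matrix), must be nonzero.
#' @param s_hat Estimate of the same shape.
#' @return Scalar error.
#' @export
rel_error <- function(s, s_hat) {
  s <- as.numeric(s); s_hat <- as.numeric(s_hat)
  if (length(s) != length(s_hat)) stop("signals must have the same length")
  ns <- sqrt(sum(s^2))
  if (ns == 0) stop("reference signal has zero norm")
  sqrt(sum((s - s_hat)^2)) / ns
}

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation; errors on constant inputs, the degenerate case
#' the validation scoring must flag rather than silently return `NA`.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Scalar in \[-1, 1\].
#' @export
pearson_cor <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("inputs must have the same length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for constant input")
  stats::cor(a, b)
}

#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed model, single-rater consistency: with `BMS` and `EMS` the
#' between-target and residual mean squares of the two-way (target x judge)
#' ANOVA decomposition and `k` judges,
#' `ICC(3,1) = (BMS - EMS) / (BMS + (k - 1) * EMS)`. Judges differing by a
#' constant offset are perfectly consistent (ICC = 1).
#'
#' @param ratings Numeric matrix, targets in rows, judges in columns.
#' @return Scalar at most 1.
#' @export
icc31 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need at least 2 targets and 2 judges")
  if (stats::var(rowMeans(ratings)) == 0)
    stop("zero between-target variance; ICC undefined")
  df <- data.frame(y = as.vector(ratings),
                   target = factor(rep(seq_len(n), k)),
                   judge = factor(rep(seq_len(k), each = n)))
  # only the mean squares are used; the F-test warning on perfect fits
  # (identical judges) is irrelevant here
  ms <- suppressWarnings(
    anova(stats::aov(y ~ target + judge, data = df))[["Mean Sq"]])
  bms <- ms[1]; ems <- ms[3]
  (bms - ems) / (bms + (k - 1) * ems)
}

#' Tracking error counts
#'
#' @param fn,fp,mm,g Per-frame vectors of false negatives, false positives,
#'   identity mismatches and ground-truth detections.
#' @return An object of class `"track_counts"`.
#' @export
track_counts <- function(fn, fp, mm, g) {
  if (any(fn < 0 | fp < 0 | mm < 0 | g < 0)) stop("counts must be nonnegative")
  structure(list(fn = fn, fp = fp, mm = mm, g = g), class = "track_counts")
}

#' Multiple-object tracking accuracy
#'
#' `MOTA = 1 - sum(fn + fp + mm) / sum(g)`; can be negative when the error
#' counts exceed the ground truth (no clipping).
#'
#' @param counts A [track_counts()].
#' @return Scalar.
#' @export
mota <- function(counts) {
  g <- sum(counts$g)
  if (g <= 0) stop("no ground-truth detections")
  1 - (sum(counts$fn) + sum(counts$fp) + sum(counts$mm)) / g
}

#' Mismatch ratio
#'
#' `MMR = sum(mm) / sum(g)`.
#'
#' @param counts A [track_counts()].
#' @return Scalar.
#' @export
mmr <- function(counts) {
  g <- sum(counts$g)
  if (g <= 0) stop("no ground-truth detections")
  sum(counts$mm) / g
}

#' Frame-by-frame tracking evaluation
#'
#' Greedy nearest-detection matching within `match_radius` per frame;
#' unmatched ground-truth detections count as false negatives, unmatched
#' predictions as false positives, and a ground-truth identity whose matched
#' predicted identity changes between its consecutive matched frames counts
#' as one mismatch.
#'
#' @param truth,predicted Lists of [tracklet()] objects.
#' @param match_radius Maximum distance for a detection match.
#' @return A [track_counts()].
#' @export
evaluate_tracking <- function(truth, predicted, match_radius = 1) {
  frames_t <- detections_by_frame(truth)
  frames_p <- detections_by_frame(predicted)
  all_frames <- as.character(
    sort(unique(as.integer(c(names(frames_t), names(frames_p))))))
  nf <- length(all_frames)
  fn <- fp <- mm <- g <- integer(nf)
  last_match <- list()  # truth id -> predicted id at the last matched frame
  for (fi in seq_along(all_frames)) {
    fr <- all_frames[fi]
    dt <- frames_t[[fr]]
    dp <- frames_p[[fr]]
    nt <- if (is.null(dt)) 0L else nrow(dt)
    np <- if (is.null(dp)) 0L else nrow(dp)
    g[fi] <- nt
    if (nt == 0L) { fp[fi] <- np; next }
    if (np == 0L) { fn[fi] <- nt; next }
    dist <- outer(seq_len(nt), seq_len(np), function(a, b)
      sqrt((dt$x[a] - dp$x[b])^2 + (dt$y[a] - dp$y[b])^2))
    pairs <- which(dist <= match_radius, arr.ind = TRUE)
    matched_t <- rep(FALSE, nt); matched_p <- rep(FALSE, np)
    if (nrow(pairs)) {
      ord <- order(dist[pairs])
      for (kidx in ord) {
        a <- pairs[kidx, 1]; b <- pairs[kidx, 2]
        if (matched_t[a] || matched_p[b]) next
        matched_t[a] <- TRUE; matched_p[b] <- TRUE
        tid <- as.character(dt$id[a]); pid <- as.character(dp$id[b])
        prev <- last_match[[tid]]
        if (!is.null(prev) && prev != pid) mm[fi] <- mm[fi] + 1L
        last_match[[tid]] <- pid
      }
    }
    fn[fi] <- sum(!matched_t)
    fp[fi] <- sum(!matched_p)
  }
  track_counts(fn, fp, mm, g)
}

detections_by_frame <- function(tracklets) {
  rows <- do.call(rbind, lapply(tracklets, function(tr) {
    data.frame(frame = tracklet_frames(tr), id = tr$id,
               x = tr$coords[1, ], y = tr$coords[2, ])
  }))
  if (is.null(rows)) return(list())
  split(rows, as.character(rows$frame))
}

#' Remove true detections uniformly at random
#'
#' Emulates a false-negative stress scenario: a given percentage of the
#' detections across all tracklets is removed uniformly; surviving runs are
#' re-split into contiguous tracklets and empty tracklets dropped.
#'
#' @param tracklets List of [tracklet()] objects.
#' @param pct Fraction in \[0, 1\] of detections to remove.
#' @param seed Integer seed.
#' @param min_len Minimum surviving fragment length (shorter fragments are
#'   dropped).
#' @return List of tracklets.
#' @export
remove_detections <- function(tracklets, pct, seed = 0L, min_len = 1L) {
  if (pct < 0 || pct > 1) stop("pct must lie in [0, 1]")
  set.seed(seed)
  pool <- do.call(rbind, lapply(seq_along(tracklets), function(i) {
    cbind(i, seq_len(ncol(tracklets[[i]]$coords)))
  }))
  n_remove <- round(pct * nrow(pool))
  drop <- if (n_remove > 0) pool[sample.int(nrow(pool), n_remove), ,
                                 drop = FALSE] else pool[0, , drop = FALSE]
  out <- list()
  for (i in seq_along(tracklets)) {
    tr <- tracklets[[i]]
    keep <- rep(TRUE, ncol(tr$coords))
    keep[drop[drop[, 1] == i, 2]] <- FALSE
    if (!any(keep)) next
    idx <- which(keep)
    runs <- cumsum(c(1L, diff(idx) != 1L))
    for (rr in unique(runs)) {
      sel <- idx[runs == rr]
      if (length(sel) < min_len) next
      out[[length(out) + 1L]] <- tracklet(tr$id, tr$start + sel[1] - 1L,
                                          tr$coords[, sel, drop = FALSE])
    }
  }
  out
}

#' Inject uniformly distributed false detections
#'
#' Emulates a false-positive stress scenario: spurious single-frame tracklets
#' with coordinates uniform over the bounding box of the scene are added; the
#' number injected is `pct` times the current detection count.
#'
#' @param tracklets List of [tracklet()] objects.
#' @param pct Fraction in \[0, 1\] of the detection count to inject.
#' @param seed Integer seed.
#' @return List of tracklets (originals plus clutter).
#' @export
inject_false_detections <- function(tracklets, pct, seed = 0L) {
  if (pct < 0 || pct > 1) stop("pct must lie in [0, 1]")
  set.seed(seed)
  all_xy <- do.call(cbind, lapply(tracklets, function(tr) tr$coords))
  frames <- unlist(lapply(tracklets, tracklet_frames))
  n_inject <- round(pct * sum(vapply(tracklets, function(tr)
    ncol(tr$coords), integer(1))))
  out <- tracklets
  if (n_inject > 0) {
    next_id <- paste0("fp", seq_len(n_inject))
    for (i in seq_len(n_inject)) {
      fr <- sample(frames, 1)
      xy <- c(stats::runif(1, min(all_xy[1, ]), max(all_xy[1, ])),
              stats::runif(1, min(all_xy[2, ]), max(all_xy[2, ])))
      out[[length(out) + 1L]] <- tracklet(next_id[i], fr, matrix(xy, 2, 1))
    }
  }
  out
}
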