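# assemble the Q0 linear operator (L*I - H*H) as a dense matrix acting on
# vec(trajectory), by applying it to unit vectors
assemble_q0 <- function(spec) {
  D <- spec$m
  T_len <- spec$n_blk * hankel_T(spec)
  n <- D * T_len
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- matrix(0, D, T_len)
    e[i] <- 1
    Q[, i] <- as.vector(apply_q0(e, spec))
  }
  Q
}

# brute-force optimum of the generalized linear assignment: enumerate all
# partial matchings (each row/column used at most once, entries >= threshold)
gla_brute_force <- function(P, threshold = 0) {
  n <- nrow(P)
  best <- 0
  recurse <- function(i, used_cols, acc) {
    if (i > n) {
      best <<- max(best, acc)
      return()
    }
    recurse(i + 1L, used_cols, acc)           # row i unmatched
    for (j in seq_len(n)) {
      if (j != i && !used_cols[j] && P[i, j] >= threshold && P[i, j] > 0) {
        used_cols[j] <- TRUE
        recurse(i + 1L, used_cols, acc + P[i, j])
        used_cols[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, n), 0)
  best
}

# two constant-velocity targets crossing mid-sequence, each split into two
# fragments around the crossing; ground truth and fragments returned
make_crossing_scene <- function(seed, T_len = 40L) {
  set.seed(seed)
  t <- 0:(T_len - 1)
  a <- rbind(0.5 * t, 0.3 * t + stats::runif(1, -1, 1))
  b <- rbind(0.5 * t, 12 - 0.3 * t + stats::runif(1, -1, 1))
  cut1 <- 17L; cut2 <- 23L
  list(truth = list(tracklet("A", 1, a), tracklet("B", 1, b)),
       frags = list(tracklet("A1", 1, a[, 1:cut1]),
                    tracklet("A2", cut2, a[, cut2:T_len]),
                    tracklet("B1", 1, b[, 1:cut1]),
                    tracklet("B2", cut2, b[, cut2:T_len])))
}

# square-ish scalar Hankel spec for a length-T signal
square_spec <- function(T_len) {
  hankel_spec(1L, 1L, T_len %/% 2L + 1L, T_len - T_len %/% 2L)
}
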