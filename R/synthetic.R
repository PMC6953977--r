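#' Sample stable conjugate pole pairs
#'
#' Draws `n/2` conjugate pairs `z = rho * exp(+-i theta)` with
#' `rho ~ Uniform(0.5, 0.95)` and `theta ~ Uniform(0.1*pi, 0.9*pi)`: stable
#' (all magnitudes below 1), oscillatory poles away from the real axis.
#'
#' @param n Even system order (number of poles).
#' @param seed Integer seed.
#' @return Complex vector of length `n` (conjugates adjacent).
#' @export
sample_poles <- function(n, seed = 0L) {
  n <- as.integer(n)
  if (n < 2L || n %% 2L != 0L) stop("n must be an even order >= 2")
  set.seed(seed)
  rho <- stats::runif(n / 2L, 0.5, 0.95)
  theta <- stats::runif(n / 2L, 0.1 * pi, 0.9 * pi)
  z <- rho * exp(1i * theta)
  as.vector(rbind(z, Conj(z)))
}

#' Generate outputs of an autonomous stable LTI system
#'
#' `y(t) = sum_k z_k^t` for `t = 1, ..., T`. With the poles in conjugate
#' pairs the signal is real; the imaginary residue is checked against 1e-10
#' (relative) before being discarded. The Hankel matrix of the result has
#' numerical rank equal to the number of distinct poles.
#'
#' @param poles Complex vector of stable poles (conjugate-symmetric set).
#' @param T_len Number of samples.
#' @return `1 x T_len` real matrix.
#' @export
generate_outputs <- function(poles, T_len) {
  if (any(Mod(poles) >= 1)) stop("all poles must satisfy |z| < 1 (stability)")
  y <- vapply(seq_len(T_len), function(t) sum(poles^t), complex(1))
  scale <- max(abs(Re(y)), 1)
  if (max(abs(Im(y))) > 1e-10 * scale)
    stop("pole set is not conjugate-symmetric: imaginary residue too large")
  matrix(Re(y), 1L)
}

#' Corrupt a signal with Bernoulli-sparse Gaussian noise
#'
#' The support is i.i.d. Bernoulli(`rho`); nonzero values are drawn
#' `Normal(0, (amplitude * sd(y))^2)`, so at the default amplitude the
#' corruptions are on the scale of the signal itself (gross errors, not
#' jitter).
#'
#' @param y Clean signal (`1 x T` matrix or vector).
#' @param rho Corruption probability in \[0, 1\].
#' @param amplitude Noise scale as a multiple of the signal's standard
#'   deviation.
#' @param seed Integer seed.
#' @return List with `y_tilde` (corrupted) and `eta` (noise), both `1 x T`.
#' @export
add_sparse_noise <- function(y, rho = 0.2, amplitude = 1, seed = 0L) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  y <- matrix(as.numeric(y), 1L)
  set.seed(seed)
  T_len <- ncol(y)
  support <- stats::rbinom(T_len, 1L, rho) == 1L
  eta <- matrix(0, 1L, T_len)
  sigma <- amplitude * stats::sd(as.vector(y))
  eta[1, support] <- stats::rnorm(sum(support), 0, sigma)
  list(y_tilde = y + eta, eta = eta)
}

#' Random stable input-output LTI system with simulated trajectories
#'
#' `A` has its spectral radius rescaled to 0.9; `B`, `C`, `D`, `x0` are
#' standard normal; inputs are i.i.d. standard normal (persistently exciting
#' with probability 1) and outputs come from exact simulation.
#'
#' @param n State order (`0` gives a pure feedthrough system).
#' @param d Number of inputs.
#' @param m Number of outputs.
#' @param T_len Number of samples.
#' @param seed Integer seed.
#' @return List with `model` ([ss_model()]), `U` (`d x T`) and `Y` (`m x T`).
#' @export
generate_io_system <- function(n, d, m, T_len, seed = 0L) {
  set.seed(seed)
  if (n > 0) {
    A <- matrix(stats::rnorm(n * n), n, n)
    rho <- max(Mod(eigen(A, only.values = TRUE)$values))
    A <- A * (0.9 / rho)
    B <- matrix(stats::rnorm(n * d), n, d)
    C <- matrix(stats::rnorm(m * n), m, n)
    x0 <- stats::rnorm(n)
  } else {
    A <- matrix(0, 0, 0); B <- matrix(0, 0, d)
    C <- matrix(0, m, 0); x0 <- numeric(0)
  }
  D <- matrix(stats::rnorm(m * d), m, d)
  model <- ss_model(A, B, C, D, x0)
  U <- matrix(stats::rnorm(d * T_len), d, T_len)
  Y <- simulate_lti(model, U)
  list(model = model, U = U, Y = Y)
}

#' Synthetic recovery benchmark
#'
#' For each system order and repetition: generate a clean pole-sum signal,
#' corrupt it with Bernoulli-sparse noise, tune the sparsity weight per
#' instance by oracle-free masked-entry validation ([tune_lambda_masked()]),
#' and record the recovery metrics of the tuned solution for every `(p, q)`
#' setting: relative reconstruction errors of the clean signal and of the
#' noise, the correlation with the clean signal, the rank estimate and the
#' iteration count.
#'
#' @param orders Integer vector of system orders.
#' @param reps Repetitions per order.
#' @param pq List of `c(p, q)` pairs.
#' @param T_len Trajectory length.
#' @param rho Corruption probability.
#' @param amplitude Corruption scale (multiples of the clean signal's sd).
#' @param lambda_grid Candidate regularization weights; default 20 values
#'   log-spaced in \[1e-3, 1\].
#' @param seed Base seed; repetition `i` of order `n` uses `seed + 1000*n + i`.
#' @param control A [srm_control()].
#' @return List with `raw` (one row per order/rep/setting) and `summary`
#'   (mean and sd per cell, Table-style layout), both data frames.
#' @export
run_benchmark <- function(orders = c(6L, 12L, 18L), reps = 10L,
                          pq = list(c(1, 1), c(0.9, 0.9), c(0.5, 0.5),
                                    c(0.1, 0.1)),
                          T_len = 100L, rho = 0.2, amplitude = 1,
                          lambda_grid = 10^seq(-3, 0, length.out = 20),
                          seed = 0L, control = srm_control()) {
  spec <- hankel_spec(1L, 1L, T_len %/% 2L + 1L, T_len - T_len %/% 2L)
  raw <- list()
  for (n in orders) {
    for (rep_i in seq_len(reps)) {
      inst_seed <- seed + 1000L * n + rep_i
      inst <- synthetic_instance(n, T_len, rho, amplitude, inst_seed)
      for (setting in pq) {
        p <- setting[1]; q <- setting[2]
        cell <- benchmark_cell(inst, p, q, lambda_grid, spec, control)
        raw[[length(raw) + 1L]] <- data.frame(
          order = n, rep = rep_i, p = p, q = q,
          err_y = cell$err_y, err_eta = cell$err_eta, cor = cell$cor,
          rank = cell$rank, iterations = cell$iterations,
          converged = cell$converged, lambda = cell$lambda)
      }
    }
  }
  raw <- do.call(rbind, raw)
  agg <- stats::aggregate(
    cbind(err_y, err_eta, cor, rank, iterations) ~ order + p + q, data = raw,
    FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  list(raw = raw, summary = do.call(data.frame, agg))
}

#' Generate one synthetic corrupted instance
#'
#' Bundles [sample_poles()], [generate_outputs()] and [add_sparse_noise()].
#'
#' @inheritParams run_benchmark
#' @param n Even system order.
#' @param seed Integer seed (drives both the poles and the noise).
#' @return List with `y`, `y_tilde`, `eta`, `poles`, `order`, `seed`.
#' @export
synthetic_instance <- function(n, T_len = 100L, rho = 0.2, amplitude = 1,
                               seed = 0L) {
  poles <- sample_poles(n, seed)
  y <- generate_outputs(poles, T_len)
  noise <- add_sparse_noise(y, rho, amplitude, seed + 1L)
  list(y = y, y_tilde = noise$y_tilde, eta = noise$eta, poles = poles,
       order = n, seed = seed)
}

#' Oracle-free sparsity-weight tuning by masked-entry validation
#'
#' Out-of-sample selection of `lambda` when no clean reference exists: a
#' random subset of entries is withheld (treated as missing through the
#' solver's weight matrix), the structured completion is computed for every
#' candidate, and the candidate whose completed values correlate best with
#' the withheld observations is selected (ties to the smallest `lambda`).
#' With sparse gross corruption most withheld entries are clean, so the
#' correlation score tracks denoising quality without seeing the truth.
#'
#' @param M Observed trajectory (`D x T`).
#' @param lambda_grid Candidate values.
#' @param p,q Norm exponents.
#' @param spec A [hankel_spec()] (gamma identity).
#' @param n_hold Number of entries to withhold.
#' @param seed Integer seed for the hold-out draw.
#' @param control A [srm_control()].
#' @return List with `lambda`, `score` and the `scores` vector.
#' @export
tune_lambda_masked <- function(M, lambda_grid, p = 1, q = 1, spec = NULL,
                               n_hold = 20L, seed = 0L,
                               control = srm_control()) {
  if (length(lambda_grid) == 0L) stop("lambda_grid must be nonempty")
  lambda_grid <- sort(lambda_grid)
  M <- as.matrix(M)
  if (is.null(spec)) spec <- default_hankel_spec(nrow(M), ncol(M))
  set.seed(seed)
  hold <- sample(length(M), min(n_hold, length(M) - 1L))
  W <- matrix(1, nrow(M), ncol(M))
  W[hold] <- 0
  scores <- vapply(lambda_grid, function(lam) {
    fit <- tryCatch(
      srm_solve(M, lambda = lam, p = p, q = q, W = W, spec = spec,
                control = control),
      error = function(e) NULL)
    if (is.null(fit)) return(-Inf)
    filled <- dehankel_average(fit$N, spec)
    tryCatch(pearson_cor(M[hold], filled[hold]), error = function(e) -Inf)
  }, numeric(1))
  if (all(!is.finite(scores)))
    stop("no lambda in the grid produced a usable validation completion")
  best <- which.max(scores)
  list(lambda = lambda_grid[best], score = scores[best], scores = scores)
}

benchmark_cell <- function(inst, p, q, lambda_grid, spec, control) {
  lam <- tryCatch(
    tune_lambda_masked(inst$y_tilde, lambda_grid, p = p, q = q, spec = spec,
                       seed = inst$seed + 500L, control = control)$lambda,
    error = function(e) NULL)
  fit <- if (is.null(lam)) NULL else tryCatch(
    srm_solve(inst$y_tilde, lambda = lam, p = p, q = q, spec = spec,
              control = control),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(err_y = NA_real_, err_eta = NA_real_, cor = NA_real_,
                rank = NA_integer_, iterations = NA_integer_,
                converged = FALSE, lambda = NA_real_))
  list(err_y = rel_error(inst$y, fit$L),
       err_eta = if (sum(inst$eta^2) > 0) rel_error(inst$eta, fit$E)
                 else sqrt(sum(fit$E^2)),
       cor = pearson_cor(as.vector(inst$y), as.vector(fit$L)),
       rank = fit$rank_estimate, iterations = fit$iterations,
       converged = fit$converged, lambda = lam)
}
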