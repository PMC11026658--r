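#' Draw learning rates from the truncated-normal simulation prior
#'
#' Samples i.i.d. learning rates from a normal distribution with mean
#' 0.34 and variance 0.88 truncated to `[0, 1]` — the distribution used
#' to generate hypothetical participants for parameter-recovery
#' simulation. Sampling is by inverse-CDF, so a fixed seed gives
#' identical draws on any platform.
#'
#' @param n Number of draws.
#' @param mean,variance Mean and variance of the untruncated normal.
#' @param lower,upper Truncation bounds.
#' @param seed Optional integer seed (the caller's RNG state is
#'   restored afterwards).
#' @return Numeric vector of `n` learning rates.
#' @examples
#' draw_alpha(5, seed = 1)
#' @export
draw_alpha <- function(n, mean = 0.34, variance = 0.88,
                       lower = 0, upper = 1, seed = NULL) {
  stopifnot(n >= 1, variance >= 0, lower < upper)
  if (variance == 0) return(rep(mean, n))
  sdv <- sqrt(variance)
  with_seed_(seed, {
    u <- runif(n, pnorm(lower, mean, sdv), pnorm(upper, mean, sdv))
    qnorm(u, mean, sdv)
  })
}

#' Simulate task responses from known parameters
#'
#' `simulate_binary()` draws each trial's binarised prediction from a
#' Bernoulli with probability [softmax_prob()]`(v_t, beta)`;
#' `simulate_continuous()` adds Gaussian noise with standard deviation
#' `sigma` to the trajectory and clips the result to `[0, 1]`;
#' `simulate_dual_continuous()` does the same for the valence-specific
#' two-rate model. All simulators run the Rescorla-Wagner trajectory on
#' the schedule's contingency-space outcomes, using the same outcome
#' sequence for every simulated subject (as in the task itself).
#'
#' @param alpha Learning rate(s); one simulated subject per element.
#' @param beta Softmax inverse temperature (shared across subjects).
#' @param sigma Response-noise standard deviation, `>= 0`.
#' @param alpha_p,alpha_n Valence-specific learning rates (equal length).
#' @param schedule A [blt_schedule()].
#' @param v0 Initial predicted outcome.
#' @param seed Optional integer seed.
#' @return A tibble with columns `subject`, `trial`, and `yb` (binary) or
#'   `y` (continuous), in contingency space, ready for the `fit_*()`
#'   functions.
#' @examples
#' sched <- blt_schedule(seed = 1)
#' sim <- simulate_binary(alpha = c(0.2, 0.6), beta = 8, schedule = sched,
#'                        seed = 2)
#' @export
simulate_binary <- function(alpha, beta, schedule, v0 = 0.5, seed = NULL) {
  stopifnot(beta > 0, all(alpha >= 0 & alpha <= 1))
  o <- as.numeric(schedule$o)
  V <- rw_matrix_(o, alpha, v0)$V
  P <- softmax_prob(V, beta)
  Yb <- with_seed_(seed, matrix(as.integer(runif(length(P)) < P), nrow(P)))
  sim_tbl_(Yb, "yb", length(o), length(alpha))
}

#' @rdname simulate_binary
#' @export
simulate_continuous <- function(alpha, sigma, schedule, v0 = 0.5,
                                seed = NULL) {
  stopifnot(sigma >= 0, all(alpha >= 0 & alpha <= 1))
  o <- as.numeric(schedule$o)
  V <- rw_matrix_(o, alpha, v0)$V
  Y <- with_seed_(seed, V + rnorm(length(V), 0, sigma))
  Y <- pmin(pmax(Y, 0), 1)
  sim_tbl_(matrix(Y, nrow(V)), "y", length(o), length(alpha))
}

#' @rdname simulate_binary
#' @export
simulate_dual_continuous <- function(alpha_p, alpha_n, sigma, schedule,
                                     v0 = 0.5, seed = NULL) {
  stopifnot(sigma >= 0, length(alpha_p) == length(alpha_n))
  o <- as.numeric(schedule$o)
  V <- rw_dual_matrix_(o, as.integer(schedule$s), alpha_p, alpha_n, v0)$V
  Y <- with_seed_(seed, V + rnorm(length(V), 0, sigma))
  Y <- pmin(pmax(Y, 0), 1)
  sim_tbl_(matrix(Y, nrow(V)), "y", length(o), length(alpha_p))
}

#' @rdname simulate_binary
#' @export
simulate_dual_binary <- function(alpha_p, alpha_n, beta, schedule,
                                 v0 = 0.5, seed = NULL) {
  stopifnot(beta > 0, length(alpha_p) == length(alpha_n))
  o <- as.numeric(schedule$o)
  V <- rw_dual_matrix_(o, as.integer(schedule$s), alpha_p, alpha_n, v0)$V
  P <- softmax_prob(V, beta)
  Yb <- with_seed_(seed, matrix(as.integer(runif(length(P)) < P), nrow(P)))
  sim_tbl_(Yb, "yb", length(o), length(alpha_p))
}

sim_tbl_ <- function(M, col, n_trials, n_subjects) {
  out <- tibble(
    subject = rep(seq_len(n_subjects), each = n_trials),
    trial = rep(seq_len(n_trials), n_subjects)
  )
  out[[col]] <- as.vector(M)
  out
}

#' Fisher-z averaged correlation
#'
#' Averages correlation coefficients by transforming to Fisher z
#' (`atanh`), taking the mean, and transforming back (`tanh`) — the
#' standard way to pool Pearson r across simulation runs.
#'
#' @param r Vector of correlation coefficients in `[-1, 1]`.
#' @return The pooled correlation.
#' @examples
#' fisher_z_mean(c(0, 0.8))  # exactly 0.5
#' @export
fisher_z_mean <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("`r` must lie in [-1, 1]", call. = FALSE)
  tanh(mean(atanh(r), na.rm = TRUE))
}
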