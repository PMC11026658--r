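# Independent oracles: deliberately naive re-derivations used to check the
# package's vectorised/optimised paths. Kept free of package internals.

# direct per-trial substitution into the update rule
oracle_rw <- function(o, alpha, v0 = 0.5) {
  v <- v0
  out <- numeric(length(o) + 1)
  out[1] <- v0
  for (t in seq_along(o)) {
    if (!is.na(o[t])) v <- v + alpha * (o[t] - v)
    out[t + 1] <- v
  }
  out
}

# literal softmax from the two-exponential form (safe for moderate beta)
oracle_softmax <- function(v, beta) {
  exp(beta * v) / (exp(beta * v) + exp(beta * (1 - v)))
}

# per-trial product likelihoods, summed in log space by brute force
oracle_binary_ll <- function(yb, v, beta) {
  tot <- 0
  for (t in seq_along(yb)) {
    if (is.na(yb[t])) next
    p1 <- oracle_softmax(v[t], beta)
    tot <- tot + log(if (yb[t] == 1) p1 else 1 - p1)
  }
  tot
}

oracle_continuous_ll <- function(y, v, phi, eps = 1e-4) {
  tot <- 0
  for (t in seq_along(y)) {
    if (is.na(y[t])) next
    yt <- min(max(y[t], eps), 1 - eps)
    mu <- min(max(v[t], eps), 1 - eps)
    tot <- tot + dbeta(yt, mu * phi, (1 - mu) * phi, log = TRUE)
  }
  tot
}

# exhaustive grid search over the binary MAP objective for one subject
oracle_binary_grid <- function(o, yb, alpha_grid, beta_grid,
                               alpha_prior = c(0.34, 0.88),
                               beta_prior = c(4.21, 1.75)) {
  best <- list(obj = -Inf)
  for (a in alpha_grid) {
    v <- oracle_rw(o, a)[seq_along(o)]
    for (b in beta_grid) {
      obj <- oracle_binary_ll(yb, v, b) -
        (a - alpha_prior[1])^2 / (2 * alpha_prior[2]) -
        (b - beta_prior[1])^2 / (2 * beta_prior[2])
      if (obj > best$obj) best <- list(obj = obj, alpha = a, beta = b)
    }
  }
  best
}

# closed-form mean of a normal truncated to [lo, hi]
oracle_truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# tiny synthetic cohort shared by several tests
make_cohort <- function(n_subjects, sigma = NULL, beta = NULL,
                        alpha = NULL, sched_seed = 5, sim_seed = 6) {
  sched <- blt_schedule(seed = sched_seed)
  if (is.null(alpha)) alpha <- draw_alpha(n_subjects, seed = sim_seed + 1)
  if (!is.null(sigma)) {
    dat <- simulate_continuous(alpha, sigma, sched, seed = sim_seed)
  } else {
    dat <- simulate_binary(alpha, beta, sched, seed = sim_seed)
  }
  list(schedule = sched, alpha = alpha, data = dat)
}
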