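test_that("information criteria follow the shared penalised form", {
  ic <- information_criteria(-100, 2, 80)
  expect_equal(ic$aic, 204)
  expect_equal(ic$bic, 200 + 2 * log(80))
  expect_equal(ic$bic, 208.7641, tolerance = 1e-4)
  # no free parameters: both collapse to the deviance
  ic0 <- information_criteria(-55.45, 0, 80)
  expect_equal(ic0$bic, ic0$aic)
  expect_equal(ic0$bic, 110.9)
  expect_error(information_criteria(-10, 1, 0), "n_obs")
})

test_that("Bayes factors convert criterion differences correctly", {
  expect_equal(bayes_factor(10, 10), 1)
  expect_equal(bayes_factor(-1298, -1315), exp(8.5))
  expect_equal(bayes_factor(-1298, -1315), 4914.769, tolerance = 1e-4)
  expect_equal(bayes_factor(1691, 1253), exp(219))
})

test_that("binary null model has the closed-form chance likelihood", {
  sched <- blt_schedule(seed = 5)
  sim <- simulate_binary(c(0.2, 0.7), beta = 4, schedule = sched, seed = 9)
  nf <- fit_null(sim, sched, "binary")
  expect_equal(nf$loglik, rep(80 * log(0.5), 2))
  expect_equal(80 * log(0.5), -55.45177, tolerance = 1e-5)
  # no free parameters: BIC equals AIC
  g <- glance(nf)
  expect_equal(g$kappa, 0L)
  expect_equal(g$bic, g$aic)
  expect_equal(g$loglik, 160 * log(0.5))
})

test_that("continuous null dispersion matches a 1-D grid-search oracle", {
  sched <- blt_schedule(seed = 5)
  sim <- simulate_continuous(c(0.1, 0.5, 0.8), sigma = 0.25,
                             schedule = sched, seed = 10)
  nf <- fit_null(sim, sched, "continuous")
  y <- pmin(pmax(sim$y, 1e-4), 1 - 1e-4)
  grid <- exp(seq(log(1e-3), log(500), length.out = 4000))
  ll <- sapply(grid, function(p) sum(dbeta(y, 0.5 * p, 0.5 * p, log = TRUE)))
  expect_equal(nf$phi[1], grid[which.max(ll)], tolerance = 1e-2)
  expect_equal(sum(nf$loglik), max(ll), tolerance = 1e-4)
  expect_equal(attr(nf, "kappa"), 1L)
})

test_that("binary MAP estimates match an exhaustive grid-search oracle", {
  co <- make_cohort(3, beta = 6, alpha = c(0.15, 0.45, 0.8))
  fit <- fit_binary(co$data, co$schedule)
  o <- as.numeric(co$schedule$o)
  for (j in 1:3) {
    yb <- co$data$yb[co$data$subject == j]
    best <- oracle_binary_grid(o, yb, seq(0, 1, by = 0.01),
                               seq(0.5, 15, by = 0.1))
    expect_equal(fit$alpha[j], best$alpha, tolerance = 0.02)
    expect_equal(fit$beta[j], best$beta, tolerance = 0.15)
    # optimiser must not fall below the grid optimum
    expect_gte(fit$log_posterior[j], best$obj - 1e-4)
  }
  expect_true(all(fit$converged))
})

test_that("MAP cannot be worse than its prior-mean start point", {
  co <- make_cohort(4, beta = 2, sim_seed = 31)
  fit <- fit_binary(co$data, co$schedule)
  pa <- blt_priors()
  o <- as.numeric(co$schedule$o)
  for (j in 1:4) {
    yb <- co$data$yb[co$data$subject == j]
    v <- oracle_rw(o, 0.34)[1:80]
    start_obj <- oracle_binary_ll(yb, v, 4.21) # priors contribute 0 at their means
    expect_gte(fit$log_posterior[j], start_obj - 1e-8)
  }
})

test_that("constant-response posteriors resolve to the 1-D grid optimum", {
  sched <- blt_schedule(seed = 5)
  # identical responses on every trial say nothing about learning
  dat <- tibble::tibble(subject = 1, trial = 1:80, yb = 1)
  fit <- fit_binary(dat, sched)
  o <- as.numeric(sched$o)
  grid <- seq(0, 1, by = 0.001)
  post <- sapply(grid, function(a) {
    v <- oracle_rw(o, a)[1:80]
    oracle_binary_ll(rep(1, 80), v, fit$beta[1]) - (a - 0.34)^2 / (2 * 0.88)
  })
  expect_lt(abs(fit$alpha[1] - grid[which.max(post)]), 0.005)
})

test_that("noise-free continuous fits recover the generating rate", {
  co <- make_cohort(1, sigma = 0, alpha = 0.2)
  fit <- fit_continuous(co$data, co$schedule)
  expect_equal(fit$alpha[1], 0.2, tolerance = 0.005)
  expect_gt(fit$phi[1], 100) # noise-free data drive dispersion to its ceiling

  # grid-search oracle over (alpha, phi) on the same subject
  o <- as.numeric(co$schedule$o)
  y <- co$data$y
  agrid <- seq(0.1, 0.3, by = 0.005)
  pgrid <- exp(seq(log(50), log(500), length.out = 60))
  obj <- outer(agrid, pgrid, Vectorize(function(a, p) {
    oracle_continuous_ll(y, oracle_rw(o, a)[1:80], p) -
      (a - 0.34)^2 / (2 * 0.88)
  }))
  idx <- which(obj == max(obj), arr.ind = TRUE)
  expect_equal(fit$alpha[1], agrid[idx[1]], tolerance = 0.01)
})

test_that("subjects with identical data get identical estimates", {
  sched <- blt_schedule(seed = 5)
  one <- simulate_continuous(0.35, 0.1, sched, seed = 13)
  two <- dplyr::mutate(one, subject = 2)
  fit <- fit_continuous(dplyr::bind_rows(one, two), sched)
  expect_equal(fit$alpha[1], fit$alpha[2], tolerance = 1e-6)
})

test_that("recovered dispersion decreases as response noise grows", {
  sched <- blt_schedule(seed = 5)
  alpha <- draw_alpha(40, seed = 14)
  phis <- sapply(c(0.05, 0.15, 0.3), function(s) {
    fit_continuous(simulate_continuous(alpha, s, sched, seed = 15),
                   sched)$phi[1]
  })
  expect_true(all(diff(phis) < 0))
})

test_that("dual fits behave like nested extensions of the single model", {
  sched <- blt_schedule(seed = 5)
  alpha <- c(0.2, 0.5, 0.75)
  sim <- simulate_continuous(alpha, 0.1, sched, seed = 16)

  dual <- fit_dual(sim, sched, "continuous")
  # data generated with alpha_p = alpha_n: estimates approximately equal
  # (per-subject identifiability is limited with one 80-trial session)
  expect_lt(max(abs(dual$alpha_p - dual$alpha_n)), 0.15)

  # dual posterior at its optimum dominates the single solution embedded
  # in the dual space
  single <- fit_continuous(sim, sched)
  pa <- bltlearn:::prior_row_(blt_priors(), "alpha")
  pad <- list(p = bltlearn:::prior_row_(blt_priors(), "alpha_p"),
              n = bltlearn:::prior_row_(blt_priors(), "alpha_n"))
  Y <- matrix(sim$y, 80, 3)
  fg <- bltlearn:::cont_fg_factory_(as.numeric(sched$o), Y, pad, 1e-4, 0.5,
                                    dual = TRUE, s = as.integer(sched$s))
  at_dual <- -fg(c(dual$alpha_p, dual$alpha_n, log(dual$phi[1])))$value
  at_single <- -fg(c(single$alpha, single$alpha, log(single$phi[1])))$value
  expect_gte(at_dual, at_single - 1e-6)

  # null model's likelihood cannot beat the learning model's
  null <- fit_null(sim, sched, "continuous")
  expect_gte(attr(single, "loglik"), attr(null, "loglik"))
})

test_that("a valence never experienced leaves its rate at the prior mean", {
  sched <- blt_schedule(seed = 5)
  sched$s[] <- 1L # every trial negative valence
  sim <- simulate_dual_continuous(rep(0.5, 2), rep(0.3, 2), 0.05, sched,
                                  seed = 17)
  fit <- fit_dual(sim, sched, "continuous")
  expect_equal(fit$alpha_p, rep(0.34, 2), tolerance = 0.01)
  expect_equal(fit$alpha_n, rep(0.3, 2), tolerance = 0.05)
})

test_that("binary dual fit recovers distinct valence-specific rates", {
  sched <- blt_schedule(seed = 5)
  sim <- simulate_dual_binary(rep(0.7, 30), rep(0.15, 30), beta = 8,
                              schedule = sched, seed = 18)
  fit <- fit_dual(sim, sched, "binary")
  expect_gt(mean(fit$alpha_p), mean(fit$alpha_n))
  expect_equal(attr(fit, "kappa"), 90L)
})

test_that("glance/tidy expose pooled criteria consistent with the rows", {
  co <- make_cohort(3, sigma = 0.1, sim_seed = 19)
  fit <- fit_continuous(co$data, co$schedule)
  g <- glance(fit)
  expect_equal(g$loglik, sum(fit$loglik))
  expect_equal(g$kappa, 4L) # 3 subject alphas + shared phi
  expect_equal(g$n_obs, 240L)
  expect_equal(g$bic, -2 * g$loglik + log(g$n_obs) * g$kappa)
  td <- tidy(fit)
  expect_setequal(unique(td$term), c("alpha", "phi"))
  expect_equal(nrow(td), 6)
})

test_that("model comparison orders learning and null models sensibly", {
  sched <- blt_schedule(seed = 5)
  sim <- simulate_continuous(draw_alpha(10, seed = 20), 0.1, sched, seed = 21)
  cmp <- compare_fits(
    model = fit_continuous(sim, sched),
    null = fit_null(sim, sched, "continuous")
  )
  expect_equal(cmp$name[1], "model")
  expect_true(all(cmp$bf_vs_best >= 1))
  expect_gt(cmp$bf_vs_best[2], 1e3)
})
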