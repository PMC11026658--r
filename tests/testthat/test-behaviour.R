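make_raw <- function(slider, cue = rep(1L, length(slider)),
                     subject = 1L) {
  tibble::tibble(
    subject = subject, trial = seq_along(slider), cue = cue,
    resistance = rep_len(c(1L, 0L), length(slider)), slider = slider
  )
}

test_that("preprocessing rescales, maps and binarises responses", {
  pp <- blt_preprocess(make_raw(c(0, 5, 10)))
  expect_equal(pp$y, c(0, 0.5, 1))
  expect_equal(pp$yb, c(0L, NA, 1L)) # 0.5 is missed for the binary model
  expect_equal(pp$o, to_contingency_outcome(pp$cue, pp$resistance))

  # cue-2 predictions are reflected into contingency space
  pp2 <- blt_preprocess(make_raw(c(7, 3), cue = c(2L, 2L)))
  expect_equal(pp2$y, c(0.3, 0.7))

  # spec'd binarisation cases
  pp3 <- blt_preprocess(make_raw(c(7, 3, 5)))
  expect_equal(pp3$yb, c(1L, 0L, NA))
})

test_that("subjects missing more than the threshold are excluded", {
  sl_bad <- c(rep(NA_real_, 11), rep(7, 69))
  sl_edge <- c(rep(NA_real_, 10), rep(7, 70))
  raw <- dplyr::bind_rows(
    make_raw(sl_bad, subject = "drop"),
    make_raw(sl_edge, subject = "keep")
  )
  expect_message(pp <- blt_preprocess(raw), "excluding 1 subject")
  expect_equal(unique(pp$subject), "keep")
  excl <- attr(pp, "exclusions")
  expect_equal(excl$subject, "drop")
  expect_match(excl$reason, "missed 11")
})

test_that("malformed rows are rejected by name", {
  bad <- make_raw(c(5, 12))
  expect_error(blt_preprocess(bad), "malformed")
  expect_error(blt_preprocess(make_raw(5)[, -3]), "lacks columns")
})

test_that("certainty score matches its definition and symmetries", {
  expect_equal(certainty_score(c(0, 1)), 0.5)
  expect_equal(certainty_score(c(0.5, 0.5)), 0)
  expect_equal(certainty_score(c(0, 1, 0.5)), 1 / 3)
  y <- runif(30)
  expect_equal(certainty_score(y), certainty_score(1 - y))
  expect_equal(certainty_score(c(0.2, NA, 0.9)), certainty_score(c(0.2, 0.9)))
  expect_error(certainty_score(NA_real_), "undefined")
})

test_that("proportion correct summarises cohort accuracy per trial", {
  sched <- blt_schedule(seed = 21)
  # omniscient cohort: responses equal outcomes
  resp <- tidyr::expand_grid(subject = 1:4, trial = 1:80) |>
    dplyr::left_join(sched[c("trial", "o")], by = "trial") |>
    dplyr::mutate(yb = o)
  pc <- proportion_correct(resp)
  expect_true(all(pc$prop_correct == 1))

  # comparison with itself is a perfect correlation
  sim <- simulate_binary(draw_alpha(12, seed = 22), 4, sched, seed = 23)
  sim <- dplyr::left_join(sim, sched[c("trial", "o")], by = "trial")
  pc2 <- proportion_correct(sim)
  self <- proportion_correct(sim, reference = pc2$prop_correct)
  expect_equal(attr(self, "r"), 1)
  expect_error(proportion_correct(sim, reference = 1:10), "per trial")
})

test_that("group trajectory validation mirrors cohort behaviour", {
  sched <- blt_schedule(seed = 21)
  alpha <- draw_alpha(25, seed = 24)
  sim <- simulate_continuous(alpha, 0.05, sched, seed = 25)
  fit <- fit_continuous(sim, sched)
  val <- group_trajectory_validation(fit, sim, sched)
  expect_gt(val$r, 0.95)
  expect_lt(val$p, 1e-6)

  # null model: constant modelled series, correlation 0 by convention
  nul <- fit_null(sim, sched, "continuous")
  val0 <- group_trajectory_validation(nul, sim, sched)
  expect_equal(val0$r, 0)
  expect_true(is.na(val0$p))

  # shuffling one series destroys the alignment
  shuffled <- sim |> dplyr::group_by(subject) |>
    dplyr::mutate(y = sample(y)) |> dplyr::ungroup()
  val_s <- group_trajectory_validation(fit, shuffled, sched)
  expect_lt(abs(val_s$r), 0.5)
})

test_that("binary group validation uses softmax response probabilities", {
  sched <- blt_schedule(seed = 21)
  sim <- simulate_binary(draw_alpha(30, seed = 26), 6, sched, seed = 27)
  fit <- fit_binary(sim, sched)
  val <- group_trajectory_validation(fit, sim, sched)
  expect_gt(val$r, 0.8)
  expect_true(all(val$series$modelled >= 0 & val$series$modelled <= 1))
})

test_that("spearman matrix has rank-statistic structure", {
  set.seed(28)
  n <- 40
  x <- rnorm(n)
  scores <- tibble::tibble(
    subject = 1:n,
    A = x + rnorm(n, 0, 0.5),
    B = -x + rnorm(n, 0, 0.5),
    C = rnorm(n)
  )
  m <- spearman_matrix(scores)
  expect_equal(m$rho[m$var1 == m$var2], rep(1, 3))
  wide <- tidyr::pivot_wider(m[c("var1", "var2", "rho")],
                             names_from = "var2", values_from = "rho")
  expect_equal(wide$B[wide$var1 == "A"], wide$A[wide$var1 == "B"])
  expect_true(all(abs(m$rho) <= 1))
  expect_lt(m$rho[m$var1 == "A" & m$var2 == "B"], -0.5)

  # monotone transforms leave rank correlations untouched
  m2 <- spearman_matrix(dplyr::mutate(scores, A = exp(3 * A)))
  expect_equal(m2$rho, m$rho)
})

test_that("small-sample spearman matches hand-computed ranks", {
  scores <- tibble::tibble(subject = 1:5,
                           u = c(3, 1, 4, 1.5, 5),
                           w = c(2, 1, 3, 5, 4))
  m <- spearman_matrix(scores)
  hand <- cor(rank(scores$u), rank(scores$w))
  expect_equal(m$rho[m$var1 == "u" & m$var2 == "w"], hand)
})

test_that("constant columns are flagged rather than silently dropped", {
  scores <- tibble::tibble(subject = 1:6, A = rnorm(6), B = rep(2, 6))
  expect_warning(m <- spearman_matrix(scores), "constant")
  expect_true(is.na(m$rho[m$var1 == "A" & m$var2 == "B"]))
  p <- suppressWarnings(autoplot(spearman_matrix(
    tibble::tibble(subject = 1:6, A = rnorm(6), B = rnorm(6)))))
  expect_s3_class(p, "ggplot")
})
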