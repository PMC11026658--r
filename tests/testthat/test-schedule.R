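test_that("default schedule reproduces the published task design", {
  sched <- blt_schedule(seed = 1)
  expect_s3_class(sched, "blt_schedule")
  expect_equal(nrow(sched), 80)
  expect_equal(attr(sched, "block_lengths"), c(30L, 13L, 12L, 13L, 12L))
  expect_equal(length(unique(sched$block_id)), 5) # 5 blocks = 4 reversals
  expect_equal(as.vector(table(sched$block_id)), c(30, 13, 12, 13, 12))
})

test_that("exact_proportion fixes contingency-consistent counts per block", {
  sched <- blt_schedule(seed = 3)
  # block 1: cue 1 is the high cue, so consistent trials have o = 1
  expect_equal(sum(sched$o[sched$block_id == 1]), round(0.8 * 30))
  # swapped blocks: consistent trials have o = 0
  counts <- tapply(sched$o, sched$block_id, sum)
  lens <- c(30, 13, 12, 13, 12)
  expected <- ifelse(seq_len(5) %% 2 == 1,
                     round(0.8 * lens), lens - round(0.8 * lens))
  expect_equal(as.vector(counts), as.vector(expected))
  # mean(o) alternates about 0.5 between consecutive blocks
  m <- tapply(sched$o, sched$block_id, mean)
  expect_true(all((m > 0.5) == c(TRUE, FALSE, TRUE, FALSE, TRUE)))
})

test_that("schedule invariants hold across realizations and seeds", {
  for (seed in c(2, 9, 41)) {
    for (real in c("exact_proportion", "bernoulli")) {
      sched <- blt_schedule(seed = seed, realization = real)
      # coding rule links o, cue and resistance on every trial
      expect_equal(sched$o,
                   to_contingency_outcome(sched$cue, sched$resistance))
      expect_equal(sched$s, sched$resistance)
      # cue presentation balanced within each block (at most one extra)
      bal <- tapply(sched$cue, sched$block_id, function(x) {
        abs(sum(x == 1) - sum(x == 2))
      })
      expect_true(all(bal <= 1))
    }
  }
})

test_that("same seed gives a bit-identical schedule", {
  expect_identical(blt_schedule(seed = 7), blt_schedule(seed = 7))
  expect_false(identical(blt_schedule(seed = 7), blt_schedule(seed = 8)))
})

test_that("degenerate p_high = 1 makes every trial contingency-consistent", {
  sched <- blt_schedule(p_high = 1, seed = 4)
  parity <- as.integer(sched$block_id %% 2 == 1)
  expect_equal(sched$o, parity)
})

test_that("schedule construction validates its inputs", {
  expect_error(blt_schedule(n_trials = 80, block_lengths = c(30, 30)),
               "sum")
  expect_error(blt_schedule(p_high = 0.5), "p_high")
  expect_error(blt_schedule(p_high = 0.3), "p_high")
})

test_that("contingency-space coding follows the pairing rule", {
  # all four cue/resistance cases
  expect_equal(to_contingency_outcome(1, 1), 1L)
  expect_equal(to_contingency_outcome(1, 0), 0L)
  expect_equal(to_contingency_outcome(2, 1), 0L)
  expect_equal(to_contingency_outcome(2, 0), 1L)
  expect_error(to_contingency_outcome(3, 1), "cue")
})

test_that("prediction mapping reflects cue-2 predictions and is an involution", {
  expect_equal(to_contingency_prediction(1, 0.9), 0.9)
  expect_equal(to_contingency_prediction(2, 0.9), 0.1)
  expect_equal(to_contingency_prediction(2, 0.5), 0.5)
  y <- runif(20)
  cue <- sample(1:2, 20, replace = TRUE)
  expect_equal(to_contingency_prediction(cue, to_contingency_prediction(cue, y)),
               y)
  expect_error(to_contingency_prediction(1, 1.2), "0, 1")
})

test_that("contingency coding is label-symmetric for both likelihoods", {
  sched <- blt_schedule(seed = 11)
  alpha <- 0.3
  v <- rw_trajectory(sched$o, alpha)$v
  v_swap <- rw_trajectory(1 - sched$o, alpha)$v
  set.seed(2)
  y <- pmin(pmax(v + rnorm(80, 0, 0.2), 0), 1)
  yb <- as.integer(y > 0.5)
  expect_equal(continuous_loglik(y, v, phi = 6),
               continuous_loglik(1 - y, v_swap, phi = 6))
  expect_equal(binary_loglik(yb, v, beta = 4),
               binary_loglik(1 - yb, v_swap, beta = 4))
})

test_that("schedules round-trip through CSV", {
  sched <- blt_schedule(seed = 13)
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule(sched, path)
  back <- read_schedule(path)
  expect_equal(as.data.frame(back), as.data.frame(sched),
               ignore_attr = TRUE)
})
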