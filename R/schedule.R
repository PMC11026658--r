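#' Build a probabilistic-reversal trial schedule
#'
#' Generates the cue/outcome sequence for a Breathing Learning Task (BLT)
#' session: two visual cues probabilistically predict an inspiratory
#' resistance, with the cue-resistance pairing reversing between blocks.
#' The default design is 80 trials in five blocks (30, 13, 12, 13, 12
#' trials), giving four reversals, with the high-probability cue followed
#' by its outcome on 80% of trials.
#'
#' Events are additionally coded in *contingency space*: the per-trial
#' outcome `o` is 1 when cue 1 was paired with a resistance or cue 2 with
#' no resistance (see [to_contingency_outcome()]), so that a single axis
#' carries both coupled contingencies. The stimulus valence `s` equals the
#' resistance indicator (resistance is the negative-valence stimulus).
#'
#' @param n_trials Total number of trials.
#' @param block_lengths Integer vector of block lengths; must sum to
#'   `n_trials`. The cue-resistance pairing swaps between consecutive
#'   blocks.
#' @param p_high Probability that the currently high cue is followed by a
#'   resistance (and the low cue by no resistance). Must lie in (0.5, 1].
#' @param realization `"exact_proportion"` fixes the number of
#'   contingency-consistent trials per block at `round(p_high * length)`;
#'   `"bernoulli"` draws each trial independently.
#' @param seed Integer seed; the same seed always yields the same schedule.
#'   `NULL` uses the current RNG stream.
#'
#' @return A tibble of class `blt_schedule` with columns `trial` (1-based),
#'   `cue` (1 or 2), `resistance` (0/1), `block_id`, `o` (contingency-space
#'   outcome) and `s` (stimulus valence), plus attributes recording the
#'   design (`p_high`, `block_lengths`, `realization`, `seed`).
#'
#' @examples
#' sched <- blt_schedule(seed = 1)
#' table(sched$block_id)
#' # mean contingency-space outcome alternates about 0.5 across blocks
#' tapply(sched$o, sched$block_id, mean)
#' @export
blt_schedule <- function(n_trials = 80L,
                         block_lengths = c(30L, 13L, 12L, 13L, 12L),
                         p_high = 0.8,
                         realization = c("exact_proportion", "bernoulli"),
                         seed = NULL) {
  realization <- match.arg(realization)
  if (sum(block_lengths) != n_trials) {
    stop("`block_lengths` must sum to `n_trials` (", sum(block_lengths),
         " != ", n_trials, ")", call. = FALSE)
  }
  if (p_high <= 0.5 || p_high > 1) {
    stop("`p_high` must lie in (0.5, 1]", call. = FALSE)
  }

  blocks <- with_seed_(seed, {
    purrr::imap(as.integer(block_lengths), function(len, b) {
      # balanced cue presentation, uniformly shuffled; odd blocks place the
      # extra trial on a random cue
      cue <- rep(1:2, length.out = len)
      cue <- sample(cue)
      consistent <- switch(realization,
        exact_proportion = {
          k <- round(p_high * len)
          sample(rep(c(1L, 0L), c(k, len - k)))
        },
        bernoulli = as.integer(runif(len) < p_high)
      )
      # odd-numbered blocks pair cue 1 with the high resistance probability;
      # the pairing swaps every block, so in contingency space o = 1 on
      # consistent trials of odd blocks and inconsistent trials of even ones
      o <- if (b %% 2L == 1L) consistent else 1L - consistent
      tibble(
        cue = cue,
        o = o,
        resistance = ifelse(cue == 1L, o, 1L - o),
        block_id = b
      )
    })
  })

  out <- dplyr::bind_rows(blocks)
  out <- tibble(
    trial = seq_len(n_trials),
    cue = out$cue,
    resistance = as.integer(out$resistance),
    block_id = out$block_id,
    o = as.integer(out$o),
    s = as.integer(out$resistance)
  )
  structure(out,
    class = c("blt_schedule", class(out)),
    p_high = p_high,
    block_lengths = as.integer(block_lengths),
    realization = realization,
    seed = seed
  )
}

#' Code a cue/resistance pair in contingency space
#'
#' The BLT couples its two contingencies: when cue 1 carries an 80% chance
#' of resistance, cue 2 carries 20%, and vice versa. Both can therefore be
#' tracked on one axis by coding a trial as 1 when cue 1 was paired with a
#' resistance or cue 2 with no resistance, and 0 when the pairing was
#' reversed. The coding is label-symmetric: swapping cue labels simply
#' complements `o`, which leaves model likelihoods unchanged.
#'
#' @param cue Cue label(s), 1 or 2.
#' @param resistance Resistance indicator(s), 0 or 1.
#' @return Integer vector of contingency-space outcomes.
#' @examples
#' to_contingency_outcome(1, 1) # 1
#' to_contingency_outcome(2, 1) # 0
#' @export
to_contingency_outcome <- function(cue, resistance) {
  if (!all(cue %in% c(1L, 2L) | is.na(cue))) {
    stop("`cue` must be 1 or 2", call. = FALSE)
  }
  if (!all(resistance %in% c(0L, 1L) | is.na(resistance))) {
    stop("`resistance` must be 0 or 1", call. = FALSE)
  }
  as.integer(ifelse(cue == 1L, resistance, 1L - resistance))
}

#' Map a cue-referenced prediction into contingency space
#'
#' A slider prediction is made about the *presented* cue ("how certain are
#' you that this cue will be followed by a resistance?"). To share one axis
#' with the contingency-space outcome, predictions under cue 2 are
#' reflected: the probability assigned to "cue 2 followed by resistance"
#' is the probability that the contingency-space outcome is 0.
#' The mapping is an involution, so it also converts contingency-space
#' predictions back to cue-referenced ones.
#'
#' @param cue Cue label(s), 1 or 2.
#' @param y Prediction(s) in `[0, 1]` (probability of resistance under the
#'   shown cue). Missing values pass through.
#' @return Numeric vector of contingency-space predictions.
#' @examples
#' to_contingency_prediction(2, 0.9) # 0.1
#' @export
to_contingency_prediction <- function(cue, y) {
  if (!all(cue %in% c(1L, 2L) | is.na(cue))) {
    stop("`cue` must be 1 or 2", call. = FALSE)
  }
  if (any(y < 0 | y > 1, na.rm = TRUE)) {
    stop("`y` must lie in [0, 1]", call. = FALSE)
  }
  ifelse(cue == 1L, y, 1 - y)
}

#' Read or write a trial schedule as CSV
#'
#' @param schedule A `blt_schedule`.
#' @param path File path.
#' @return `write_schedule()` returns `schedule` invisibly;
#'   `read_schedule()` returns a `blt_schedule` tibble.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(schedule)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path)
  need <- c("trial", "cue", "resistance", "block_id", "o", "s")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("schedule file lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- as_tibble(df[need])
  structure(out, class = c("blt_schedule", class(out)))
}
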