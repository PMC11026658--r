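#' Rescorla-Wagner prediction trajectory
#'
#' Runs the Rescorla-Wagner update on a sequence of binary outcomes.
#' The predicted outcome for trial `t + 1` is
#' \deqn{v_{t+1} = v_t + \alpha \, \delta_t, \qquad \delta_t = o_t - v_t,}
#' where \eqn{\alpha} is the learning rate and \eqn{\delta_t} the
#' prediction error. The initial prediction `v0` defaults to 0.5
#' (complete uncertainty about the first outcome). Trials with a missing
#' outcome carry the prediction forward unchanged.
#'
#' @param o Outcome sequence in contingency space (0/1, `NA` allowed), or a
#'   [blt_schedule()] whose `o` column is used.
#' @param alpha Learning rate in `[0, 1]`.
#' @param v0 Initial predicted outcome.
#' @return A tibble of class `blt_trajectory` with columns `trial`, `o`,
#'   `v` (the prediction *entering* each trial) and `delta`; the
#'   post-update value after the final trial is kept in attribute
#'   `v_final`.
#' @examples
#' rw_trajectory(c(1, 1), alpha = 0.5)   # v = 0.5, 0.75 (then 0.875)
#' @export
rw_trajectory <- function(o, alpha, v0 = 0.5) {
  o <- schedule_outcomes_(o)
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1) {
    stop("`alpha` must be a single value in [0, 1]", call. = FALSE)
  }
  v <- rw_values_(o, alpha, v0)
  n <- length(o)
  out <- tibble(
    trial = seq_len(n),
    o = o,
    v = v[seq_len(n)],
    delta = o - v[seq_len(n)]
  )
  structure(out,
    class = c("blt_trajectory", class(out)),
    v_final = v[n + 1L], alpha = alpha, v0 = v0
  )
}

#' Dual-learning-rate Rescorla-Wagner trajectory
#'
#' As [rw_trajectory()], but the update on each trial uses a
#' valence-specific learning rate: `alpha_p` when the stimulus was
#' positive valence (`s = 0`, no resistance) and `alpha_n` when it was
#' negative valence (`s = 1`, resistance). With `alpha_p == alpha_n` the
#' trajectory reduces exactly to the single-rate model.
#'
#' @inheritParams rw_trajectory
#' @param s Stimulus-valence sequence (0/1) aligned with `o`; taken from
#'   the schedule when `o` is a `blt_schedule`.
#' @param alpha_p,alpha_n Learning rates in `[0, 1]` for positive- and
#'   negative-valence trials.
#' @return A `blt_trajectory` tibble with an additional `s` column.
#' @examples
#' rw_dual_trajectory(c(1, 1), s = c(1, 0), alpha_p = 0.2, alpha_n = 0.8)
#' @export
rw_dual_trajectory <- function(o, s = NULL, alpha_p, alpha_n, v0 = 0.5) {
  if (inherits(o, "blt_schedule") && is.null(s)) s <- o$s
  o <- schedule_outcomes_(o)
  if (is.null(s)) stop("`s` is required when `o` is not a schedule", call. = FALSE)
  if (length(s) != length(o)) {
    stop("`o` and `s` must have the same length", call. = FALSE)
  }
  for (a in c(alpha_p, alpha_n)) {
    if (is.na(a) || a < 0 || a > 1) {
      stop("learning rates must lie in [0, 1]", call. = FALSE)
    }
  }
  v <- rw_dual_values_(o, s, alpha_p, alpha_n, v0)
  n <- length(o)
  out <- tibble(
    trial = seq_len(n),
    o = o,
    s = as.integer(s),
    v = v[seq_len(n)],
    delta = o - v[seq_len(n)]
  )
  structure(out,
    class = c("blt_trajectory", class(out)),
    v_final = v[n + 1L], alpha_p = alpha_p, alpha_n = alpha_n, v0 = v0
  )
}

schedule_outcomes_ <- function(o) {
  if (inherits(o, "blt_schedule")) o <- o$o
  if (!all(o %in% c(0, 1) | is.na(o))) {
    stop("outcomes must be 0, 1 or NA", call. = FALSE)
  }
  as.numeric(o)
}

# length-(n+1) value sequence; v[t] enters trial t, v[n+1] is post-final
rw_values_ <- function(o, alpha, v0 = 0.5) {
  n <- length(o)
  v <- numeric(n + 1L)
  v[1L] <- v0
  for (t in seq_len(n)) {
    v[t + 1L] <- if (is.na(o[t])) v[t] else v[t] + alpha * (o[t] - v[t])
  }
  v
}

rw_dual_values_ <- function(o, s, alpha_p, alpha_n, v0 = 0.5) {
  n <- length(o)
  a <- ifelse(s == 1, alpha_n, alpha_p)
  v <- numeric(n + 1L)
  v[1L] <- v0
  for (t in seq_len(n)) {
    v[t + 1L] <- if (is.na(o[t])) v[t] else v[t] + a[t] * (o[t] - v[t])
  }
  v
}

# Vectorised over subjects: n x S matrix of per-trial predictions for a
# shared outcome sequence and subject-specific rates. Also returns the
# sensitivity dv/dalpha used by the analytic MAP gradients.
rw_matrix_ <- function(o, alpha, v0 = 0.5, grad = FALSE) {
  n <- length(o)
  S <- length(alpha)
  V <- matrix(0, n, S)
  G <- if (grad) matrix(0, n, S) else NULL
  v <- rep(v0, S)
  g <- numeric(S)
  for (t in seq_len(n)) {
    V[t, ] <- v
    if (grad) G[t, ] <- g
    if (!is.na(o[t])) {
      d <- o[t] - v
      if (grad) g <- g * (1 - alpha) + d
      v <- v + alpha * d
    }
  }
  list(V = V, G = G)
}

# Dual-rate version: sensitivities with respect to alpha_p and alpha_n.
rw_dual_matrix_ <- function(o, s, alpha_p, alpha_n, v0 = 0.5, grad = FALSE) {
  n <- length(o)
  S <- length(alpha_p)
  V <- matrix(0, n, S)
  Gp <- Gn <- if (grad) matrix(0, n, S) else NULL
  v <- rep(v0, S)
  gp <- gn <- numeric(S)
  for (t in seq_len(n)) {
    V[t, ] <- v
    if (grad) {
      Gp[t, ] <- gp
      Gn[t, ] <- gn
    }
    if (!is.na(o[t])) {
      a <- if (s[t] == 1) alpha_n else alpha_p
      d <- o[t] - v
      if (grad) {
        gp <- gp * (1 - a) + if (s[t] == 0) d else 0
        gn <- gn * (1 - a) + if (s[t] == 1) d else 0
      }
      v <- v + a * d
    }
  }
  list(V = V, Gp = Gp, Gn = Gn)
}
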