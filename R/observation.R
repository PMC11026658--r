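#' Softmax response probability for binary predictions
#'
#' Maps a predicted outcome \eqn{v_t \in [0,1]} to the probability of a
#' "contingency-consistent" binary prediction through a two-option softmax
#' \deqn{p(y_t = 1 \mid v_t, \beta) =
#'   \frac{e^{\beta v_t}}{e^{\beta v_t} + e^{\beta (1 - v_t)}}
#'   = \mathrm{logistic}(\beta (2 v_t - 1)),}
#' where the inverse temperature \eqn{\beta > 0} controls decision noise:
#' larger \eqn{\beta} gives steeper, more deterministic choice. Computed
#' on the log-odds scale, so it does not overflow even for very large
#' \eqn{\beta}.
#'
#' @param v Predicted outcome(s) in `[0, 1]`.
#' @param beta Softmax inverse temperature, `> 0`.
#' @return Probability of responding 1.
#' @examples
#' softmax_prob(0.5, 10)      # 0.5 regardless of beta
#' softmax_prob(0.8, 4)       # 0.9168...
#' @export
softmax_prob <- function(v, beta) {
  if (any(beta <= 0)) stop("`beta` must be > 0", call. = FALSE)
  if (any(v < 0 | v > 1, na.rm = TRUE)) {
    stop("`v` must lie in [0, 1]", call. = FALSE)
  }
  plogis(beta * (2 * v - 1))
}

#' Log-likelihood of binary predictions under the softmax model
#'
#' Sums the per-trial log-probability of each observed binarised
#' prediction given a Rescorla-Wagner trajectory and a softmax inverse
#' temperature. Missing responses contribute nothing (the trajectory
#' itself is computed from outcomes, which the participant experienced
#' whether or not a response was logged).
#'
#' @param yb Binary response sequence (0/1, `NA` for missed trials).
#' @param traj A `blt_trajectory` or a numeric vector of per-trial
#'   predictions `v`.
#' @param beta Softmax inverse temperature.
#' @return The summed log-likelihood (a single number).
#' @export
binary_loglik <- function(yb, traj, beta) {
  v <- traj_values_(traj)
  if (length(yb) != length(v)) {
    stop("`yb` and trajectory must align", call. = FALSE)
  }
  obs <- !is.na(yb)
  if (!any(obs)) stop("all responses missing: likelihood undefined", call. = FALSE)
  x <- beta * (2 * v[obs] - 1)
  sum(ifelse(yb[obs] == 1,
             plogis(x, log.p = TRUE),
             plogis(-x, log.p = TRUE)))
}

#' Beta shape parameters from mean and dispersion
#'
#' Re-parameterises the beta distribution in terms of its mean \eqn{\mu}
#' and a dispersion (concentration) parameter \eqn{\phi}:
#' \eqn{a = \mu \phi}, \eqn{b = (1 - \mu) \phi}, so that
#' \eqn{E[\mathrm{Beta}(a, b)] = \mu} and larger \eqn{\phi} concentrates
#' the distribution more tightly around \eqn{\mu} (less response noise).
#'
#' @param mu Mean(s) in `(0, 1)`.
#' @param phi Dispersion, `> 0`.
#' @return A tibble with columns `a` and `b`.
#' @examples
#' beta_shapes(0.5, 2)    # a = b = 1: the uniform distribution
#' beta_shapes(0.8, 10)   # a = 8, b = 2
#' @export
beta_shapes <- function(mu, phi) {
  if (any(phi <= 0)) stop("`phi` must be > 0", call. = FALSE)
  if (any(mu <= 0 | mu >= 1, na.rm = TRUE)) {
    stop("`mu` must lie strictly inside (0, 1); clip boundary values first",
         call. = FALSE)
  }
  tibble(a = mu * phi, b = (1 - mu) * phi)
}

#' Log-likelihood of continuous predictions under the beta model
#'
#' Each observed slider prediction \eqn{y_t \in [0,1]} is modelled as a
#' draw from a beta distribution with mean equal to the Rescorla-Wagner
#' prediction \eqn{v_t} and shared dispersion \eqn{\phi}
#' (see [beta_shapes()]). Because the beta density is degenerate at the
#' boundaries, both responses and means are clipped to
#' `[eps, 1 - eps]` before evaluation. Missing responses contribute
#' nothing.
#'
#' @param y Continuous response sequence in `[0, 1]` (`NA` for missed
#'   trials).
#' @param traj A `blt_trajectory` or numeric vector of predictions.
#' @param phi Dispersion parameter, `> 0`.
#' @param eps Boundary clipping width.
#' @return The summed log-likelihood.
#' @examples
#' # at v = 0.5 and phi = 2 the model is uniform: log-density 0 everywhere
#' continuous_loglik(c(0.2, 0.9), c(0.5, 0.5), phi = 2)
#' @export
continuous_loglik <- function(y, traj, phi, eps = 1e-4) {
  if (length(phi) != 1L || is.na(phi) || phi <= 0) {
    stop("`phi` must be a single value > 0", call. = FALSE)
  }
  v <- traj_values_(traj)
  if (length(y) != length(v)) {
    stop("`y` and trajectory must align", call. = FALSE)
  }
  obs <- !is.na(y)
  if (!any(obs)) stop("all responses missing: likelihood undefined", call. = FALSE)
  yc <- clip01_(y[obs], eps)
  mu <- clip01_(v[obs], eps)
  sum(dbeta(yc, mu * phi, (1 - mu) * phi, log = TRUE))
}

traj_values_ <- function(traj) {
  if (inherits(traj, "blt_trajectory")) traj$v
  else as.numeric(traj)
}
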