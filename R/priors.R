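#' Default native-space priors for MAP estimation
#'
#' Gaussian priors specified in native parameter space, combined with hard
#' box bounds during optimisation (a truncated Gaussian whose
#' normalisation constant is irrelevant to the MAP location). The
#' defaults are learning rate \eqn{\alpha \sim N(0.34, 0.88)} bounded to
#' `[0, 1]` (shared by `alpha`, `alpha_p` and `alpha_n`) and softmax
#' inverse temperature \eqn{\beta \sim N(4.21, 1.75)} with a positivity
#' bound; both were derived from maximum-likelihood fits to a separate
#' pilot cohort. The beta-model dispersion \eqn{\phi} carries an improper
#' flat prior over `(0, 500]`, so its estimate is likelihood-driven.
#'
#' @param alpha_mean,alpha_var Prior mean and variance for the learning
#'   rates.
#' @param beta_mean,beta_var Prior mean and variance for the softmax
#'   inverse temperature.
#' @param phi_max Upper bound of the flat dispersion prior.
#' @return A tibble of class `blt_priors` with columns `parameter`,
#'   `mean`, `variance`, `lower`, `upper`. An infinite variance encodes a
#'   flat prior.
#' @examples
#' blt_priors()
#' @export
blt_priors <- function(alpha_mean = 0.34, alpha_var = 0.88,
                       beta_mean = 4.21, beta_var = 1.75,
                       phi_max = 500) {
  stopifnot(alpha_var > 0, beta_var > 0, phi_max > 0)
  out <- tibble(
    parameter = c("alpha", "alpha_p", "alpha_n", "beta", "phi"),
    mean = c(alpha_mean, alpha_mean, alpha_mean, beta_mean, NA_real_),
    variance = c(alpha_var, alpha_var, alpha_var, beta_var, Inf),
    lower = c(0, 0, 0, 1e-3, 1e-3),
    upper = c(1, 1, 1, Inf, phi_max)
  )
  structure(out, class = c("blt_priors", class(out)))
}

prior_row_ <- function(priors, parameter) {
  row <- priors[priors$parameter == parameter, ]
  if (nrow(row) != 1L) {
    stop("priors must contain exactly one row for '", parameter, "'",
         call. = FALSE)
  }
  as.list(row)
}

# Gaussian log-density up to a constant; flat prior contributes 0.
log_prior_ <- function(x, pr) {
  if (!is.finite(pr$variance)) return(0)
  -(x - pr$mean)^2 / (2 * pr$variance)
}

dlog_prior_ <- function(x, pr) {
  if (!is.finite(pr$variance)) return(0)
  -(x - pr$mean) / pr$variance
}
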