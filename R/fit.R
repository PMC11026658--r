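#' MAP fits of learning models to trial-level response data
#'
#' `fit_binary()` estimates a learning rate \eqn{\alpha} and softmax
#' inverse temperature \eqn{\beta} per subject from binarised predictions.
#' `fit_continuous()` jointly estimates one \eqn{\alpha} per subject and a
#' single group-level beta-distribution dispersion \eqn{\phi} from
#' continuous predictions. `fit_dual()` replaces \eqn{\alpha} by
#' valence-specific rates \eqn{\alpha_p} (no-resistance trials) and
#' \eqn{\alpha_n} (resistance trials). `fit_null()` fits the no-learning
#' reference in which \eqn{\alpha} is fixed at 0 so the predicted outcome
#' stays clamped at 0.5.
#'
#' All fits are maximum a posteriori: the summed response log-likelihood
#' plus Gaussian log-priors in native space (see [blt_priors()]) is
#' maximised with single-start bounded L-BFG-B optimisation started at the
#' prior means, using analytic gradients. The dispersion \eqn{\phi} is
#' optimised on the log scale for conditioning; under its flat prior this
#' leaves the optimum unchanged. Trials with missing responses still
#' update the trajectory (the stimulus was experienced) but drop out of
#' the likelihood.
#'
#' @param data A tibble with columns `subject`, `trial` and the response:
#'   `yb` (0/1, `NA` for missed trials) for binary fits, `y` (in `[0, 1]`)
#'   for continuous fits. Responses and outcomes must both be in
#'   contingency space (see [blt_preprocess()]).
#' @param schedule A [blt_schedule()] supplying the outcome sequence `o`
#'   (and valence `s` for dual fits).
#' @param priors A [blt_priors()] tibble.
#' @param eps Boundary clipping width for the beta likelihood.
#' @param v0 Initial predicted outcome (fixed, not estimated).
#' @return A tibble of class `blt_fit` with one row per subject
#'   (estimates, per-subject log-likelihood, `n_obs`, `converged`) and
#'   pooled attributes; [glance()] returns the pooled log-likelihood,
#'   parameter count \eqn{\kappa}, observation count and BIC/AIC,
#'   [tidy()] the estimates in long form.
#' @seealso [information_criteria()], [bayes_factor()]
#' @examples
#' sched <- blt_schedule(seed = 2)
#' sim <- simulate_continuous(alpha = c(0.1, 0.4), sigma = 0.1,
#'                            schedule = sched, seed = 3)
#' fit <- fit_continuous(sim, sched)
#' glance(fit)
#' @export
fit_binary <- function(data, schedule, priors = blt_priors(), v0 = 0.5) {
  rm_ <- resp_matrix_(data, "yb", schedule)
  pa <- prior_row_(priors, "alpha")
  pb <- prior_row_(priors, "beta")
  o <- as.numeric(schedule$o)

  rows <- purrr::map(seq_along(rm_$subjects), function(j) {
    yb <- rm_$Y[, j]
    fit <- optim_map_(
      par = c(alpha = pa$mean, beta = pb$mean),
      lower = c(pa$lower, pb$lower), upper = c(pa$upper, pb$upper),
      fg = function(par) binary_fg_(par[1], par[2], o, yb, pa, pb, v0)
    )
    ll <- binary_loglik(yb, rw_values_(o, fit$par[1], v0)[seq_along(o)],
                        fit$par[2])
    tibble(
      subject = rm_$subjects[j],
      alpha = fit$par[1], beta = fit$par[2],
      loglik = ll, log_posterior = fit$value,
      n_obs = sum(!is.na(yb)), converged = fit$converged
    )
  })
  new_blt_fit_(dplyr::bind_rows(rows), model_id = "binary",
               kappa = 2L * length(rm_$subjects), priors = priors)
}

#' @rdname fit_binary
#' @export
fit_continuous <- function(data, schedule, priors = blt_priors(),
                           eps = 1e-4, v0 = 0.5) {
  rm_ <- resp_matrix_(data, "y", schedule)
  pa <- prior_row_(priors, "alpha")
  pphi <- prior_row_(priors, "phi")
  o <- as.numeric(schedule$o)
  S <- length(rm_$subjects)

  fg <- cont_fg_factory_(o, rm_$Y, pa, eps, v0, dual = FALSE, s = NULL)
  fit <- optim_map_(
    par = c(rep(pa$mean, S), log(10)),
    lower = c(rep(pa$lower, S), log(pphi$lower)),
    upper = c(rep(pa$upper, S), log(pphi$upper)),
    fg = fg, maxit = 2000L
  )
  alpha <- fit$par[seq_len(S)]
  phi <- exp(fit$par[S + 1L])
  ll_sub <- cont_subject_logliks_(o, rm_$Y, alpha, NULL, phi, eps, v0)

  out <- tibble(
    subject = rm_$subjects, alpha = alpha, phi = phi,
    loglik = ll_sub, n_obs = colSums(!is.na(rm_$Y)),
    converged = fit$converged
  )
  new_blt_fit_(out, model_id = "continuous", kappa = S + 1L,
               priors = priors, phi = phi, eps = eps)
}

#' @rdname fit_binary
#' @param model Observation model for `fit_dual()` / `fit_null()`.
#' @export
fit_dual <- function(data, schedule, model = c("continuous", "binary"),
                     priors = blt_priors(), eps = 1e-4, v0 = 0.5) {
  model <- match.arg(model)
  o <- as.numeric(schedule$o)
  s <- as.integer(schedule$s)
  pap <- prior_row_(priors, "alpha_p")
  pan <- prior_row_(priors, "alpha_n")

  if (model == "binary") {
    rm_ <- resp_matrix_(data, "yb", schedule)
    pb <- prior_row_(priors, "beta")
    rows <- purrr::map(seq_along(rm_$subjects), function(j) {
      yb <- rm_$Y[, j]
      fit <- optim_map_(
        par = c(pap$mean, pan$mean, pb$mean),
        lower = c(pap$lower, pan$lower, pb$lower),
        upper = c(pap$upper, pan$upper, pb$upper),
        fg = function(par) {
          dual_binary_fg_(par[1], par[2], par[3], o, s, yb, pap, pan, pb, v0)
        }
      )
      v <- rw_dual_values_(o, s, fit$par[1], fit$par[2], v0)[seq_along(o)]
      tibble(
        subject = rm_$subjects[j],
        alpha_p = fit$par[1], alpha_n = fit$par[2], beta = fit$par[3],
        loglik = binary_loglik(yb, v, fit$par[3]),
        log_posterior = fit$value,
        n_obs = sum(!is.na(yb)), converged = fit$converged
      )
    })
    return(new_blt_fit_(dplyr::bind_rows(rows), model_id = "binary_dual",
                        kappa = 3L * length(rm_$subjects), priors = priors))
  }

  rm_ <- resp_matrix_(data, "y", schedule)
  pphi <- prior_row_(priors, "phi")
  S <- length(rm_$subjects)
  fg <- cont_fg_factory_(o, rm_$Y, list(p = pap, n = pan), eps, v0,
                         dual = TRUE, s = s)
  fit <- optim_map_(
    par = c(rep(pap$mean, S), rep(pan$mean, S), log(10)),
    lower = c(rep(pap$lower, S), rep(pan$lower, S), log(pphi$lower)),
    upper = c(rep(pap$upper, S), rep(pan$upper, S), log(pphi$upper)),
    fg = fg, maxit = 3000L
  )
  alpha_p <- fit$par[seq_len(S)]
  alpha_n <- fit$par[S + seq_len(S)]
  phi <- exp(fit$par[2L * S + 1L])
  ll_sub <- cont_subject_logliks_(o, rm_$Y, alpha_p, alpha_n, phi, eps, v0,
                                  s = s)
  out <- tibble(
    subject = rm_$subjects, alpha_p = alpha_p, alpha_n = alpha_n, phi = phi,
    loglik = ll_sub, n_obs = colSums(!is.na(rm_$Y)), converged = fit$converged
  )
  new_blt_fit_(out, model_id = "continuous_dual", kappa = 2L * S + 1L,
               priors = priors, phi = phi, eps = eps)
}

#' @rdname fit_binary
#' @export
fit_null <- function(data, schedule, model = c("binary", "continuous"),
                     priors = blt_priors(), eps = 1e-4) {
  model <- match.arg(model)
  if (model == "binary") {
    rm_ <- resp_matrix_(data, "yb", schedule)
    n_obs <- colSums(!is.na(rm_$Y))
    # v clamped at 0.5 makes the softmax probability exactly 0.5 whatever
    # beta is: the likelihood has no free parameters at all
    out <- tibble(
      subject = rm_$subjects,
      alpha = 0, beta = prior_row_(priors, "beta")$mean,
      loglik = n_obs * log(0.5), n_obs = n_obs, converged = TRUE
    )
    return(new_blt_fit_(out, model_id = "binary_null", kappa = 0L,
                        priors = priors))
  }
  rm_ <- resp_matrix_(data, "y", schedule)
  pphi <- prior_row_(priors, "phi")
  yc <- clip01_(rm_$Y[!is.na(rm_$Y)], eps)
  if (!length(yc)) stop("no non-missing responses", call. = FALSE)
  opt <- optimize(
    function(lphi) -sum(dbeta(yc, 0.5 * exp(lphi), 0.5 * exp(lphi), log = TRUE)),
    interval = log(c(pphi$lower, pphi$upper)), tol = 1e-8
  )
  phi <- exp(opt$minimum)
  ll_sub <- apply(rm_$Y, 2, function(y) {
    yo <- clip01_(y[!is.na(y)], eps)
    sum(dbeta(yo, 0.5 * phi, 0.5 * phi, log = TRUE))
  })
  out <- tibble(
    subject = rm_$subjects, alpha = 0, phi = phi,
    loglik = ll_sub, n_obs = colSums(!is.na(rm_$Y)), converged = TRUE
  )
  new_blt_fit_(out, model_id = "continuous_null", kappa = 1L,
               priors = priors, phi = phi, eps = eps)
}

#' Information criteria from a fitted log-likelihood
#'
#' Both criteria share the form \eqn{-2 \ln \hat{L} + c \kappa} with
#' parameter count \eqn{\kappa}: \eqn{c = \ln n} for the BIC (with
#' \eqn{n} the number of observations) and \eqn{c = 2} for the AIC.
#' Smaller values indicate the better accuracy/complexity trade-off.
#'
#' @param loglik Maximised log-likelihood \eqn{\hat{L}} (vectorised).
#' @param kappa Number of free parameters.
#' @param n_obs Number of observations entering the likelihood.
#' @return A tibble with columns `bic` and `aic`.
#' @examples
#' information_criteria(-100, 2, 80)
#' @export
information_criteria <- function(loglik, kappa, n_obs) {
  if (any(n_obs < 1)) stop("`n_obs` must be >= 1", call. = FALSE)
  tibble(
    bic = -2 * loglik + log(n_obs) * kappa,
    aic = -2 * loglik + 2 * kappa
  )
}

#' Bayes factor from two information-criterion scores
#'
#' Converts the difference between two BIC (or AIC) scores computed on the
#' same data into an approximate Bayes factor
#' \eqn{\exp((\mathrm{score}_\mathrm{worse} - \mathrm{score}_\mathrm{better}) / 2)};
#' values above 1 quantify how strongly the better-scoring model is
#' preferred.
#'
#' @param score_worse,score_better Criterion scores on the same data.
#' @return The Bayes factor (a single number).
#' @examples
#' bayes_factor(1691, 1253)   # ~1.4e95: overwhelming preference
#' @export
bayes_factor <- function(score_worse, score_better) {
  exp((score_worse - score_better) / 2)
}

# ---- internals --------------------------------------------------------

resp_matrix_ <- function(data, col, schedule) {
  data <- as_tibble(data)
  need <- c("subject", "trial", col)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("`data` lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(schedule)
  if (any(data$trial < 1 | data$trial > n)) {
    stop("`data$trial` must index the schedule (1..", n, ")", call. = FALSE)
  }
  subjects <- unique(data$subject)
  Y <- matrix(NA_real_, n, length(subjects))
  Y[cbind(data$trial, match(data$subject, subjects))] <- data[[col]]
  keep <- colSums(!is.na(Y)) > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " subject(s) with no non-missing ",
            "responses", call. = FALSE)
    Y <- Y[, keep, drop = FALSE]
    subjects <- subjects[keep]
  }
  if (!length(subjects)) stop("no subjects with responses", call. = FALSE)
  list(Y = Y, subjects = subjects)
}

# Bounded single-start L-BFGS-B minimising the negative log-posterior.
# `fg(par)` returns list(value, grad) for the negative objective; value
# and gradient are memoised so optim's separate fn/gr calls share work.
optim_map_ <- function(par, lower, upper, fg, maxit = 500L) {
  last <- new.env(parent = emptyenv())
  eval_ <- function(p) {
    if (!is.null(last$par) && identical(p, last$par)) return(last$res)
    res <- fg(p)
    last$par <- p
    last$res <- res
    res
  }
  opt <- optim(
    par, fn = function(p) eval_(p)$value, gr = function(p) eval_(p)$grad,
    method = "L-BFGS-B", lower = lower, upper = upper,
    control = list(maxit = maxit, factr = 1e7)
  )
  list(par = unname(opt$par), value = -opt$value,
       converged = opt$convergence == 0L)
}

# negative log-posterior and gradient for one subject's binary fit
binary_fg_ <- function(alpha, beta, o, yb, pa, pb, v0) {
  n <- length(o)
  v <- g <- numeric(n)
  vt <- v0; gt <- 0
  for (t in seq_len(n)) {
    v[t] <- vt; g[t] <- gt
    if (!is.na(o[t])) {
      d <- o[t] - vt
      gt <- gt * (1 - alpha) + d
      vt <- vt + alpha * d
    }
  }
  obs <- !is.na(yb)
  x <- beta * (2 * v - 1)
  p <- plogis(x)
  ll <- sum(ifelse(yb[obs] == 1, plogis(x[obs], log.p = TRUE),
                   plogis(-x[obs], log.p = TRUE)))
  resid <- numeric(n)
  resid[obs] <- yb[obs] - p[obs]
  d_alpha <- sum(2 * beta * resid * g) + dlog_prior_(alpha, pa)
  d_beta <- sum((2 * v - 1) * resid) + dlog_prior_(beta, pb)
  lp <- ll + log_prior_(alpha, pa) + log_prior_(beta, pb)
  list(value = -lp, grad = -c(d_alpha, d_beta))
}

dual_binary_fg_ <- function(alpha_p, alpha_n, beta, o, s, yb, pap, pan, pb,
                            v0) {
  n <- length(o)
  v <- gp <- gn <- numeric(n)
  vt <- v0; gpt <- 0; gnt <- 0
  for (t in seq_len(n)) {
    v[t] <- vt; gp[t] <- gpt; gn[t] <- gnt
    if (!is.na(o[t])) {
      a <- if (s[t] == 1L) alpha_n else alpha_p
      d <- o[t] - vt
      gpt <- gpt * (1 - a) + if (s[t] == 0L) d else 0
      gnt <- gnt * (1 - a) + if (s[t] == 1L) d else 0
      vt <- vt + a * d
    }
  }
  obs <- !is.na(yb)
  x <- beta * (2 * v - 1)
  p <- plogis(x)
  ll <- sum(ifelse(yb[obs] == 1, plogis(x[obs], log.p = TRUE),
                   plogis(-x[obs], log.p = TRUE)))
  resid <- numeric(n)
  resid[obs] <- yb[obs] - p[obs]
  lp <- ll + log_prior_(alpha_p, pap) + log_prior_(alpha_n, pan) +
    log_prior_(beta, pb)
  list(value = -lp, grad = -c(
    sum(2 * beta * resid * gp) + dlog_prior_(alpha_p, pap),
    sum(2 * beta * resid * gn) + dlog_prior_(alpha_n, pan),
    sum((2 * v - 1) * resid) + dlog_prior_(beta, pb)
  ))
}

# Factory for the joint continuous objective: per-subject rates plus one
# shared log-dispersion, fully vectorised across subjects.
cont_fg_factory_ <- function(o, Y, pa, eps, v0, dual, s) {
  obs <- !is.na(Y)
  if (!any(obs)) stop("no non-missing responses", call. = FALSE)
  yc <- clip01_(ifelse(obs, Y, 0.5), eps)
  lyc <- log(yc); l1yc <- log1p(-yc)
  S <- ncol(Y)

  function(par) {
    phi <- exp(par[length(par)])
    if (dual) {
      ap <- par[seq_len(S)]; an <- par[S + seq_len(S)]
      rw <- rw_dual_matrix_(o, s, ap, an, v0, grad = TRUE)
    } else {
      ap <- par[seq_len(S)]
      rw <- rw_matrix_(o, ap, v0, grad = TRUE)
    }
    mu <- clip01_(rw$V, eps)
    a <- mu * phi; b <- (1 - mu) * phi
    term <- lgamma(phi) - lgamma(a) - lgamma(b) +
      (a - 1) * lyc + (b - 1) * l1yc
    ll <- sum(term[obs])

    dmu <- phi * (-digamma(a) + digamma(b) + lyc - l1yc)
    dmu[!obs] <- 0
    dmu[rw$V <= eps | rw$V >= 1 - eps] <- 0
    dphi_term <- digamma(phi) - mu * digamma(a) - (1 - mu) * digamma(b) +
      mu * lyc + (1 - mu) * l1yc
    dlphi <- phi * sum(dphi_term[obs])

    if (dual) {
      lp <- ll + sum(log_prior_(ap, pa$p)) + sum(log_prior_(an, pa$n))
      grad <- -c(
        colSums(rw$Gp * dmu) + dlog_prior_(ap, pa$p),
        colSums(rw$Gn * dmu) + dlog_prior_(an, pa$n),
        dlphi
      )
    } else {
      lp <- ll + sum(log_prior_(ap, pa))
      grad <- -c(colSums(rw$G * dmu) + dlog_prior_(ap, pa), dlphi)
    }
    list(value = -lp, grad = grad)
  }
}

cont_subject_logliks_ <- function(o, Y, alpha, alpha_n, phi, eps, v0,
                                  s = NULL) {
  V <- if (is.null(alpha_n)) rw_matrix_(o, alpha, v0)$V
       else rw_dual_matrix_(o, s, alpha, alpha_n, v0)$V
  mu <- clip01_(V, eps)
  obs <- !is.na(Y)
  yc <- clip01_(ifelse(obs, Y, 0.5), eps)
  term <- dbeta(yc, mu * phi, (1 - mu) * phi, log = TRUE)
  term[!obs] <- 0
  colSums(term)
}

new_blt_fit_ <- function(tbl, model_id, kappa, priors, phi = NULL,
                         eps = NULL) {
  loglik <- sum(tbl$loglik)
  n_obs <- sum(tbl$n_obs)
  ic <- information_criteria(loglik, kappa, n_obs)
  structure(tbl,
    class = c("blt_fit", class(tbl)),
    model_id = model_id, kappa = as.integer(kappa),
    loglik = loglik, n_obs = n_obs, bic = ic$bic, aic = ic$aic,
    priors = priors, phi = phi, eps = eps
  )
}

#' @export
print.blt_fit <- function(x, ...) {
  cat("<blt_fit> model:", attr(x, "model_id"),
      " subjects:", nrow(x),
      " loglik:", format(attr(x, "loglik"), digits = 6),
      " kappa:", attr(x, "kappa"),
      " BIC:", format(attr(x, "bic"), digits = 6), "\n")
  NextMethod()
}
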