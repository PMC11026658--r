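#' Tidy and summarise fitted models and recovery results
#'
#' Broom-style accessors. For a `blt_fit`, [tidy()] returns the
#' per-subject parameter estimates in long form and [glance()] a one-row
#' summary with the pooled log-likelihood, parameter count \eqn{\kappa},
#' observation count and BIC/AIC. For a `blt_recovery`, [tidy()] returns
#' the per-run correlations and [glance()] the Fisher-z pooled summary
#' per noise level and parameter.
#'
#' @param x A `blt_fit` or `blt_recovery` object.
#' @param ... Unused.
#' @return A tibble.
#' @name blt-tidiers
NULL

#' @rdname blt-tidiers
#' @export
tidy.blt_fit <- function(x, ...) {
  params <- intersect(c("alpha", "alpha_p", "alpha_n", "beta", "phi"),
                      names(x))
  as_tibble(x)[c("subject", params)] |>
    tidyr::pivot_longer(dplyr::all_of(params), names_to = "term",
                        values_to = "estimate") |>
    dplyr::arrange(.data$subject)
}

#' @rdname blt-tidiers
#' @export
glance.blt_fit <- function(x, ...) {
  tibble(
    model_id = attr(x, "model_id"),
    n_subjects = nrow(x),
    loglik = attr(x, "loglik"),
    kappa = attr(x, "kappa"),
    n_obs = attr(x, "n_obs"),
    bic = attr(x, "bic"),
    aic = attr(x, "aic"),
    converged = all(x$converged)
  )
}

#' @rdname blt-tidiers
#' @export
tidy.blt_recovery <- function(x, ...) x$runs

#' @rdname blt-tidiers
#' @export
glance.blt_recovery <- function(x, ...) x$summary

#' Compare fitted models by information criterion
#'
#' Lines up several fits of the *same data* and reports each model's
#' pooled log-likelihood, \eqn{\kappa}, BIC and AIC, together with the
#' Bayes factor of the best-scoring model over each alternative.
#'
#' @param ... Named `blt_fit` objects fitted to the same responses.
#' @param criterion `"bic"` or `"aic"`.
#' @return A tibble sorted by the chosen criterion, with a
#'   `bf_vs_best` column.
#' @examples
#' \donttest{
#' sched <- blt_schedule(seed = 1)
#' sim <- simulate_continuous(draw_alpha(8, seed = 2), 0.2, sched, seed = 3)
#' compare_fits(model = fit_continuous(sim, sched),
#'              null = fit_null(sim, sched, "continuous"))
#' }
#' @export
compare_fits <- function(..., criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  fits <- list(...)
  if (length(fits) < 2) stop("supply at least two fits", call. = FALSE)
  out <- purrr::imap(fits, function(f, nm) {
    g <- glance(f)
    g$name <- if (nzchar(nm)) nm else g$model_id
    g
  }) |> dplyr::bind_rows()
  if (length(unique(out$n_obs)) > 1) {
    warning("fits have different observation counts; criteria are only ",
            "comparable on the same data", call. = FALSE)
  }
  out <- dplyr::arrange(out, .data[[criterion]])
  out$bf_vs_best <- bayes_factor(out[[criterion]], out[[criterion]][1])
  dplyr::relocate(out, "name")
}
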