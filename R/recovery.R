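#' Simulation-based parameter-recovery experiment
#'
#' Runs the full validation loop for a model: draw ground-truth learning
#' rates from the truncated-normal simulation prior (see [draw_alpha()]),
#' simulate task responses at a given noise level, re-fit the matching
#' model by MAP, and correlate simulated with recovered parameters. The
#' design mirrors the published validation: 10 independent runs of 500
#' simulated subjects per noise level, with per-run Pearson correlations
#' pooled across runs by Fisher-z averaging.
#'
#' For the binary model the noise parameter is the softmax inverse
#' temperature \eqn{\beta} used for simulation (re-estimated per subject
#' during fitting); for the continuous model it is the standard deviation
#' \eqn{\sigma} of the clipped Gaussian response noise. Dual-rate
#' recovery draws `alpha_p` and `alpha_n` independently from the same
#' truncated normal.
#'
#' @param model `"binary"` or `"continuous"`.
#' @param noise Vector of noise levels (\eqn{\beta} values for binary,
#'   \eqn{\sigma} values for continuous).
#' @param dual Use the valence-specific two-rate model?
#' @param n_runs Simulation/recovery runs per noise level.
#' @param n_subjects Simulated subjects per run.
#' @param schedule A [blt_schedule()]; defaults to the standard 80-trial
#'   design with exact per-block contingency proportions.
#' @param priors A [blt_priors()] tibble used for fitting.
#' @param seed Master seed; spawns one sub-seed per run so each run is
#'   independently reproducible.
#' @return An object of class `blt_recovery`: a list with
#'   * `summary` — tibble of Fisher-z mean correlations per noise level
#'     and parameter,
#'   * `runs` — tibble of per-run correlations,
#'   * `draws` — tibble of per-subject simulated/recovered pairs.
#'   [glance()] returns `summary`, [tidy()] returns `runs`, and
#'   [autoplot()] draws simulated-vs-recovered scatter plots.
#' @examples
#' \donttest{
#' rec <- recovery_experiment("continuous", noise = 0.1, n_runs = 2,
#'                            n_subjects = 50, seed = 1)
#' glance(rec)
#' }
#' @export
recovery_experiment <- function(model = c("binary", "continuous"),
                                noise,
                                dual = FALSE,
                                n_runs = 10L,
                                n_subjects = 500L,
                                schedule = NULL,
                                priors = blt_priors(),
                                seed = NULL) {
  model <- match.arg(model)
  stopifnot(length(noise) >= 1, n_runs >= 1, n_subjects >= 2)
  if (is.null(schedule)) {
    schedule <- blt_schedule(seed = if (is.null(seed)) NULL else seed + 1L)
  }
  run_seeds <- with_seed_(seed,
    matrix(sample.int(.Machine$integer.max - 1L, length(noise) * n_runs),
           nrow = n_runs))

  per_noise <- purrr::imap(as.numeric(noise), function(nv, i) {
    runs <- purrr::map(seq_len(n_runs), function(run) {
      recovery_run_(model, dual, nv, n_subjects, schedule, priors,
                    seed = run_seeds[run, i], run = run)
    })
    runs
  })
  runs_tbl <- dplyr::bind_rows(purrr::map(purrr::flatten(per_noise), "runs"))
  draws_tbl <- dplyr::bind_rows(purrr::map(purrr::flatten(per_noise), "draws"))

  summary_tbl <- runs_tbl |>
    dplyr::group_by(.data$noise, .data$parameter) |>
    dplyr::summarise(
      mean_r = fisher_z_mean(.data$r),
      n_runs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(model_id = model_id_(model, dual),
                  n_subjects = n_subjects)

  structure(
    list(summary = summary_tbl, runs = runs_tbl, draws = draws_tbl,
         model_id = model_id_(model, dual), seed = seed),
    class = "blt_recovery"
  )
}

model_id_ <- function(model, dual) if (dual) paste0(model, "_dual") else model

recovery_run_ <- function(model, dual, noise, n_subjects, schedule, priors,
                          seed, run) {
  pa <- prior_row_(priors, "alpha")
  sim <- with_seed_(seed, {
    if (dual) {
      ap <- draw_alpha(n_subjects, pa$mean, pa$variance, pa$lower, pa$upper)
      an <- draw_alpha(n_subjects, pa$mean, pa$variance, pa$lower, pa$upper)
      dat <- if (model == "continuous") {
        simulate_dual_continuous(ap, an, noise, schedule)
      } else {
        simulate_dual_binary(ap, an, noise, schedule)
      }
      list(truth = tibble(subject = seq_len(n_subjects),
                          alpha_p = ap, alpha_n = an),
           data = dat)
    } else {
      a <- draw_alpha(n_subjects, pa$mean, pa$variance, pa$lower, pa$upper)
      dat <- if (model == "continuous") {
        simulate_continuous(a, noise, schedule)
      } else {
        simulate_binary(a, noise, schedule)
      }
      list(truth = tibble(subject = seq_len(n_subjects), alpha = a),
           data = dat)
    }
  })

  fit <- if (dual) {
    fit_dual(sim$data, schedule, model = model, priors = priors)
  } else if (model == "continuous") {
    fit_continuous(sim$data, schedule, priors = priors)
  } else {
    fit_binary(sim$data, schedule, priors = priors)
  }

  params <- intersect(c("alpha", "alpha_p", "alpha_n"), names(sim$truth))
  draws <- purrr::map(params, function(p) {
    rec <- fit[[p]][match(sim$truth$subject, fit$subject)]
    tibble(noise = noise, run = run, parameter = p,
           subject = sim$truth$subject,
           simulated = sim$truth[[p]], recovered = rec)
  }) |> dplyr::bind_rows()
  if (any(is.na(draws$recovered))) {
    warning("excluding ", sum(is.na(draws$recovered)),
            " failed subject fit(s) from recovery correlations",
            call. = FALSE)
  }
  runs <- draws |>
    dplyr::group_by(.data$noise, .data$run, .data$parameter) |>
    dplyr::summarise(
      r = cor(.data$simulated, .data$recovered, use = "complete.obs"),
      .groups = "drop"
    )
  list(runs = runs, draws = draws)
}

#' @export
print.blt_recovery <- function(x, ...) {
  cat("<blt_recovery> model:", x$model_id, "\n")
  print(x$summary)
  invisible(x)
}
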