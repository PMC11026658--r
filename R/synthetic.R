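#' Specify a synthetic BLT study
#'
#' Bundles everything needed to generate a complete artificial study:
#' cohort size, trial-schedule configuration, the distribution of
#' ground-truth learning rates, the response model and its noise level,
#' a missed-trial rate, and questionnaire-like scores with a controllable
#' rank correlation to behaviour. The defaults emulate a small
#' single-session cohort: 20 subjects, the standard 80-trial reversal
#' schedule, continuous slider responses with moderate noise, and
#' questionnaire marginals matching published cohort medians/IQRs
#' (converted to Gaussian mean and sd; cosmetic only).
#'
#' @param n_subjects Cohort size.
#' @param mode Response model: `"continuous"`, `"binary"` or `"dual"`
#'   (dual-rate continuous).
#' @param noise Response noise: \eqn{\sigma} for continuous modes,
#'   \eqn{\beta} for binary.
#' @param alpha_mean,alpha_var,alpha_bounds Truncated-normal parameters
#'   for the ground-truth learning rates.
#' @param missingness Probability that any given trial's response is
#'   missing.
#' @param lapse_rate Probability that the report-phase answer fails to
#'   echo the true stimulus.
#' @param questionnaires A tibble with columns `name`, `mean`, `sd`,
#'   `target` (`"alpha"`, `"certainty"` or `"none"`) and `rho` (target
#'   Spearman correlation with the behavioural anchor, in (-1, 1)).
#' @param schedule_args List of arguments passed to [blt_schedule()].
#' @param seed Integer seed for the whole study.
#' @return A list of class `blt_study_spec`.
#' @examples
#' spec <- blt_study_spec(n_subjects = 10, seed = 1)
#' @export
blt_study_spec <- function(n_subjects = 20L,
                           mode = c("continuous", "binary", "dual"),
                           noise = 0.2,
                           alpha_mean = 0.34, alpha_var = 0.88,
                           alpha_bounds = c(0, 1),
                           missingness = 0.02,
                           lapse_rate = 0.02,
                           questionnaires = default_questionnaires(),
                           schedule_args = list(),
                           seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_subjects >= 1, noise >= 0,
            missingness >= 0, missingness <= 1,
            lapse_rate >= 0, lapse_rate <= 1)
  if (!is.null(questionnaires)) {
    stopifnot(all(c("name", "mean", "sd", "target", "rho") %in%
                    names(questionnaires)))
    if (any(abs(questionnaires$rho) >= 1)) {
      stop("target correlations must lie in (-1, 1)", call. = FALSE)
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects), mode = mode, noise = noise,
         alpha_mean = alpha_mean, alpha_var = alpha_var,
         alpha_bounds = alpha_bounds, missingness = missingness,
         lapse_rate = lapse_rate, questionnaires = questionnaires,
         schedule_args = schedule_args, seed = as.integer(seed)),
    class = "blt_study_spec"
  )
}

#' Default questionnaire marginals for synthetic cohorts
#'
#' Gaussian marginals for thirteen affective and interoceptive
#' instruments, with means set to published cohort medians and standard
#' deviations to IQR/1.349. By default all are generated independently of
#' behaviour (`rho = 0`); set `target`/`rho` to induce a rank correlation
#' with the ground-truth learning rate or the certainty score.
#'
#' @return A tibble with columns `name`, `mean`, `sd`, `target`, `rho`.
#' @export
default_questionnaires <- function() {
  tibble(
    name = c("STAI_T", "STAI_S", "GAD7", "ASI3", "CESD", "PANAS_P",
             "PANAS_N", "FSS", "CD_RISC", "GSE", "MAIA", "PCS_B", "PVAQ_B"),
    mean = c(36.5, 33, 2.5, 17.5, 10, 33.5, 18, 35, 71, 31, 21.29, 11.5,
             32.5),
    sd = c(18.75, 18.75, 4.75, 24.75, 7.75, 8.5, 10.25, 17.75, 18.25, 19,
           6.37, 29, 8.5) / 1.349,
    target = "none",
    rho = 0
  )
}

#' Generate a complete synthetic study
#'
#' Produces a full artificial data set from a [blt_study_spec()]: one
#' shared trial schedule, ground-truth learning rates drawn from the
#' truncated-normal prior, responses simulated with the requested model
#' and noise, uniform-at-random missed trials, report-phase answers
#' echoing the true stimulus with an occasional lapse, and
#' questionnaire-like scores tied to behaviour through a Gaussian copula
#' (a latent-normal construction whose correlation is chosen as
#' \eqn{2 \sin(\pi \rho_s / 6)} so the scores attain the requested
#' Spearman \eqn{\rho_s} with the anchor in large samples).
#'
#' The responses table uses the raw task dialect — cue-referenced slider
#' positions on the 0-10 scale — so the whole pipeline, starting at
#' [blt_preprocess()], can be exercised end to end.
#'
#' @param spec A [blt_study_spec()].
#' @return A list of class `blt_study` with elements `responses` (raw
#'   trial tibble), `questionnaires` (subject x instrument tibble),
#'   `schedule` (the shared [blt_schedule()]) and `truth` (generating
#'   parameters per subject plus the spec).
#' @examples
#' study <- generate_study(blt_study_spec(n_subjects = 5, seed = 42))
#' head(study$responses)
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "blt_study_spec"))
  with_seed_(spec$seed, {
    schedule <- do.call(blt_schedule, spec$schedule_args)
    n <- nrow(schedule)
    S <- spec$n_subjects

    alpha <- draw_alpha(S, spec$alpha_mean, spec$alpha_var,
                        spec$alpha_bounds[1], spec$alpha_bounds[2])
    truth <- tibble(subject = seq_len(S), alpha = alpha)
    sim <- switch(spec$mode,
      continuous = simulate_continuous(alpha, spec$noise, schedule),
      binary = simulate_binary(alpha, spec$noise, schedule),
      dual = {
        alpha_n <- draw_alpha(S, spec$alpha_mean, spec$alpha_var,
                              spec$alpha_bounds[1], spec$alpha_bounds[2])
        truth$alpha_p <- truth$alpha
        truth$alpha_n <- alpha_n
        simulate_dual_continuous(alpha, alpha_n, spec$noise, schedule)
      }
    )

    # back to the raw dialect: cue-referenced slider on the 0-10 scale
    ycol <- if (spec$mode == "binary") "yb" else "y"
    raw <- sim |>
      dplyr::left_join(schedule[c("trial", "cue", "resistance", "s")],
                       by = "trial") |>
      dplyr::mutate(
        slider = 10 * to_contingency_prediction(.data$cue,
                                                as.numeric(.data[[ycol]])),
        report = ifelse(runif(dplyr::n()) < spec$lapse_rate,
                        1L - .data$s, .data$s)
      )
    miss <- runif(nrow(raw)) < spec$missingness
    raw$slider[miss] <- NA_real_
    responses <- raw[c("subject", "trial", "cue", "resistance", "slider",
                       "report")]

    questionnaires <- NULL
    if (!is.null(spec$questionnaires) && nrow(spec$questionnaires)) {
      cert <- responses |>
        dplyr::mutate(y = to_contingency_prediction(.data$cue,
                                                    .data$slider / 10)) |>
        dplyr::group_by(.data$subject) |>
        dplyr::summarise(certainty = certainty_score(.data$y),
                         .groups = "drop")
      anchors <- list(
        alpha = truth$alpha,
        certainty = cert$certainty[match(truth$subject, cert$subject)],
        none = NULL
      )
      questionnaires <- tibble(subject = seq_len(S))
      for (i in seq_len(nrow(spec$questionnaires))) {
        q <- spec$questionnaires[i, ]
        questionnaires[[q$name]] <-
          copula_scores_(anchors[[q$target]], q$rho, q$mean, q$sd, S)
      }
    }

    structure(
      list(responses = responses, questionnaires = questionnaires,
           schedule = schedule,
           truth = c(as.list(truth), list(spec = spec))),
      class = "blt_study"
    )
  })
}

# Gaussian-copula score generator: ties a Gaussian marginal to the rank
# order of `anchor` so that Spearman(score, anchor) ~= rho_s.
copula_scores_ <- function(anchor, rho_s, mean, sd, n) {
  if (is.null(anchor) || rho_s == 0) return(rnorm(n, mean, sd))
  r <- 2 * sin(pi * rho_s / 6)
  z_a <- qnorm((rank(anchor, ties.method = "average") - 0.5) / length(anchor))
  z <- r * z_a + sqrt(1 - r^2) * rnorm(n)
  mean + sd * z
}

#' Write a synthetic study to disk
#'
#' Emits the same plain-text dialects the preprocessing step consumes:
#' `responses.csv`, `questionnaires.csv`, `schedule.csv` and
#' `truth.json` (the generating parameters).
#'
#' @param study A `blt_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "blt_study"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("writing a study requires the 'jsonlite' package", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_responses(study$responses, file.path(dir, "responses.csv"))
  if (!is.null(study$questionnaires)) {
    utils::write.csv(as.data.frame(study$questionnaires),
                     file.path(dir, "questionnaires.csv"), row.names = FALSE)
  }
  write_schedule(study$schedule, file.path(dir, "schedule.csv"))
  truth <- study$truth
  truth$spec <- unclass(truth$spec)
  truth$spec$questionnaires <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
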