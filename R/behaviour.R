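#' Preprocess raw slider responses into model-ready form
#'
#' Takes a raw trial table as produced by the task software (one row per
#' subject and trial, with the shown cue, the delivered resistance, and
#' the slider position on the 0-10 "definitely no" to "definitely yes"
#' scale) and derives everything the models consume:
#'
#' * the slider is rescaled to `[0, 1]` and mapped into contingency space
#'   via [to_contingency_prediction()];
#' * outcomes are coded in contingency space via
#'   [to_contingency_outcome()], and the stimulus valence `s` set to the
#'   resistance indicator;
#' * predictions are binarised (`> 0.5` becomes 1, `< 0.5` becomes 0,
#'   exactly 0.5 is treated as missed for the binary model);
#' * subjects missing more than `max_missed` trials are excluded, with
#'   the reason logged in the `exclusions` attribute.
#'
#' Report-phase answers, if present, are carried through untouched; they
#' validate that the stimulus was perceived and never enter a likelihood.
#'
#' @param raw A data frame with columns `subject`, `trial`, `cue`,
#'   `resistance`, `slider` (0-10, `NA` for missed trials) and optionally
#'   `report`.
#' @param max_missed Exclusion threshold: subjects with more missed
#'   trials than this are dropped.
#' @return A tibble of class `blt_responses` with columns `subject`,
#'   `trial`, `cue`, `resistance`, `o`, `s`, `y` (continuous prediction
#'   in contingency space), `yb` (binarised) and `report` (if supplied).
#'   Attribute `subjects` holds a per-subject summary (missed-trial count
#'   and certainty score); attribute `exclusions` the dropped subjects.
#' @examples
#' raw <- tibble::tibble(subject = 1, trial = 1:3, cue = c(1, 2, 1),
#'                       resistance = c(1, 0, 0), slider = c(9, 2, 5))
#' blt_preprocess(raw)
#' @export
blt_preprocess <- function(raw, max_missed = 10L) {
  raw <- as_tibble(raw)
  need <- c("subject", "trial", "cue", "resistance", "slider")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("`raw` lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(raw$cue %in% c(1, 2)) |
                 !(raw$resistance %in% c(0, 1)) |
                 (!is.na(raw$slider) & (raw$slider < 0 | raw$slider > 10)))
  if (length(bad)) {
    stop("malformed rows (bad cue/resistance/slider): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }

  out <- raw |>
    dplyr::mutate(
      o = to_contingency_outcome(.data$cue, .data$resistance),
      s = as.integer(.data$resistance),
      y = to_contingency_prediction(.data$cue, .data$slider / 10),
      yb = dplyr::case_when(
        is.na(.data$y) ~ NA_integer_,
        .data$y > 0.5 ~ 1L,
        .data$y < 0.5 ~ 0L,
        TRUE ~ NA_integer_
      )
    )

  subj <- out |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_missed = sum(is.na(.data$y)),
      certainty = if (all(is.na(.data$y))) NA_real_
                  else certainty_score(.data$y),
      .groups = "drop"
    )
  excluded <- subj |>
    dplyr::filter(.data$n_missed > max_missed) |>
    dplyr::mutate(reason = paste0("missed ", .data$n_missed,
                                  " trials (> ", max_missed, ")"))
  if (nrow(excluded)) {
    message("excluding ", nrow(excluded), " subject(s): ",
            paste(excluded$subject, collapse = ", "),
            " (more than ", max_missed, " missed trials)")
    out <- dplyr::filter(out, !(.data$subject %in% excluded$subject))
    subj <- dplyr::filter(subj, !(.data$subject %in% excluded$subject))
  }
  keep <- intersect(
    c("subject", "trial", "cue", "resistance", "o", "s", "y", "yb", "report"),
    names(out)
  )
  out <- out[keep]
  structure(out,
    class = c("blt_responses", class(out)),
    subjects = subj, exclusions = excluded
  )
}

#' Average prediction certainty
#'
#' The certainty score is the mean absolute deviation of a subject's
#' continuous predictions from 0.5, averaged over non-missed trials: 0
#' means the slider never left the indecision point, 0.5 means every
#' response was at an extreme. It is invariant under the contingency
#' reflection `y -> 1 - y`.
#'
#' @param y Continuous predictions in `[0, 1]` (`NA` ignored).
#' @return A single value in `[0, 0.5]`.
#' @examples
#' certainty_score(c(0, 1, 0.5))  # 1/3
#' @export
certainty_score <- function(y) {
  y <- y[!is.na(y)]
  if (!length(y)) stop("certainty undefined: no non-missing responses",
                       call. = FALSE)
  mean(abs(y - 0.5))
}

#' Per-trial proportion of correct binarised responses
#'
#' For each trial, the fraction of subjects whose binarised
#' contingency-space prediction matched the contingency-space outcome —
#' the task-validation summary used to compare cohorts. When a reference
#' per-trial series is supplied (e.g. from another cohort), the Pearson
#' correlation between the two series is attached as attributes `r` and
#' `p`.
#'
#' @param responses A `blt_responses` tibble (or any tibble with
#'   `trial`, `yb` and `o` columns).
#' @param reference Optional numeric vector of per-trial proportions to
#'   compare against (same trial count).
#' @return A tibble with columns `trial`, `prop_correct` and `n`
#'   (responding subjects), with comparison attributes when `reference`
#'   is given.
#' @export
proportion_correct <- function(responses, reference = NULL) {
  out <- responses |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(
      prop_correct = mean(.data$yb == .data$o, na.rm = TRUE),
      n = sum(!is.na(.data$yb)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$trial)
  if (!is.null(reference)) {
    if (length(reference) != nrow(out)) {
      stop("`reference` must have one value per trial (",
           nrow(out), ")", call. = FALSE)
    }
    ct <- cor.test(out$prop_correct, reference)
    attr(out, "r") <- unname(ct$estimate)
    attr(out, "p") <- ct$p.value
  }
  out
}

#' Group-level trajectory validation
#'
#' Compares the model's average fitted prediction trajectory with the
#' participants' average observed predictions, trial by trial. For a
#' binary fit the modelled prediction is the softmax response probability
#' and the observed series the per-trial mean of binarised responses; for
#' a continuous fit, the trajectory value \eqn{v_t} against the mean
#' continuous response. Agreement is summarised by a Pearson correlation;
#' if either series is constant (as for a null model, whose trajectory is
#' clamped at 0.5), the correlation is reported as 0 with `p = NA` by
#' convention.
#'
#' @param fit A `blt_fit` from [fit_binary()], [fit_continuous()],
#'   [fit_dual()] or [fit_null()].
#' @param responses The response tibble the model was fitted to.
#' @param schedule The [blt_schedule()] used for fitting.
#' @return A list of class `blt_validation` with elements `series` (a
#'   tibble of per-trial `modelled` and `observed` means), `r` and `p`.
#' @export
group_trajectory_validation <- function(fit, responses, schedule) {
  model_id <- attr(fit, "model_id")
  binary <- grepl("^binary", model_id)
  col <- if (binary) "yb" else "y"
  rm_ <- resp_matrix_(responses, col, schedule)
  idx <- match(rm_$subjects, fit$subject)
  if (any(is.na(idx))) stop("fit and responses cover different subjects",
                            call. = FALSE)
  o <- as.numeric(schedule$o)
  s <- as.integer(schedule$s)

  V <- if (!is.null(fit[["alpha_p"]])) {
    rw_dual_matrix_(o, s, fit$alpha_p[idx], fit$alpha_n[idx])$V
  } else {
    rw_matrix_(o, fit$alpha[idx])$V
  }
  M <- if (binary) {
    softmax_prob(V, matrix(rep(fit$beta[idx], each = length(o)), length(o)))
  } else V

  obs <- !is.na(rm_$Y)
  if (!any(obs)) stop("no overlapping trials between fit and responses",
                      call. = FALSE)
  series <- tibble(
    trial = seq_along(o),
    modelled = rowMeans(M),
    observed = rowMeans(rm_$Y, na.rm = TRUE)
  )
  if (sd(series$modelled) == 0 || sd(series$observed, na.rm = TRUE) == 0) {
    r <- 0; p <- NA_real_
  } else {
    ct <- cor.test(series$modelled, series$observed)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(series = series, r = r, p = p, model_id = model_id),
            class = "blt_validation")
}

#' @export
print.blt_validation <- function(x, ...) {
  cat("<blt_validation> model:", x$model_id,
      " r =", format(x$r, digits = 3),
      " p =", format(x$p, digits = 3), "\n")
  invisible(x)
}

#' Exploratory Spearman correlation matrix
#'
#' Pairwise Spearman rank correlations (with uncorrected p-values)
#' between questionnaire totals and behavioural/model measures such as
#' fitted learning rates and the certainty score — the exploratory
#' individual-differences analysis. Columns with no variance are flagged
#' with `NA` correlations.
#'
#' @param scores A tibble with a `subject` column and one numeric column
#'   per measure; typically questionnaire totals joined with model
#'   estimates and certainty via `dplyr::left_join()`.
#' @param min_pairs Minimum number of complete pairs required per cell.
#' @return A tibble of class `blt_corr_matrix` in long form: `var1`,
#'   `var2`, `rho`, `p`, `n`. [autoplot()] renders it as a heatmap.
#' @export
spearman_matrix <- function(scores, min_pairs = 3L) {
  scores <- as_tibble(scores)
  vars <- setdiff(names(scores), "subject")
  num <- vars[purrr::map_lgl(scores[vars], is.numeric)]
  if (length(num) < 2) stop("need at least two numeric columns", call. = FALSE)
  constant <- num[purrr::map_lgl(scores[num],
                                 ~ sd(.x, na.rm = TRUE) %in% c(0, NA))]
  if (length(constant)) {
    warning("constant column(s), rho undefined: ",
            paste(constant, collapse = ", "), call. = FALSE)
  }
  grid <- tidyr::expand_grid(var1 = num, var2 = num)
  out <- purrr::pmap(grid, function(var1, var2) {
    x <- scores[[var1]]; y <- scores[[var2]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < min_pairs || var1 %in% constant || var2 %in% constant) {
      return(tibble(var1 = var1, var2 = var2, rho = NA_real_,
                    p = NA_real_, n = n))
    }
    if (var1 == var2) {
      return(tibble(var1 = var1, var2 = var2, rho = 1, p = 0, n = n))
    }
    ct <- suppressWarnings(
      cor.test(x[ok], y[ok], method = "spearman", exact = NULL)
    )
    tibble(var1 = var1, var2 = var2, rho = unname(ct$estimate),
           p = ct$p.value, n = n)
  }) |> dplyr::bind_rows()
  structure(out, class = c("blt_corr_matrix", class(out)), variables = num)
}

#' Read or write raw response tables
#'
#' CSV round-trip for the raw trial dialect consumed by
#' [blt_preprocess()]: columns `subject`, `trial`, `cue`, `resistance`,
#' `slider` (0-10) and optionally `report`.
#'
#' @param responses A data frame of raw responses.
#' @param path File path.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE)
  invisible(responses)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  as_tibble(utils::read.csv(path))
}
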