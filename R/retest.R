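#' Frozen model parameters for rescoring
#'
#' The unit of model persistence across timepoints: the item-difficulty map
#' and the two normalising constants `rt_max` and `at_max`. Freezing these
#' is what makes specific ability and mean delay comparable between a
#' baseline fit and a follow-up session scored later.
#'
#' @param x an `idoct` fit, an `idoct_model` loaded with [load_model()], or
#'   a list with elements `difficulty` (named numeric vector), `rt_max`,
#'   `at_max`.
#' @return An object of class `frozen_params`.
#' @export
frozen_params <- function(x) {
  UseMethod("frozen_params")
}

#' @export
frozen_params.idoct <- function(x) {
  new_frozen_params(stats::setNames(x$item_scales$difficulty, x$item_scales$item_id),
                    x$rt_max, x$at_max)
}

#' @export
frozen_params.idoct_model <- function(x) {
  new_frozen_params(x$difficulty, x$rt_max, x$at_max)
}

#' @export
frozen_params.list <- function(x) {
  new_frozen_params(x$difficulty, x$rt_max, x$at_max)
}

new_frozen_params <- function(difficulty, rt_max, at_max) {
  if (is.null(names(difficulty)) || anyNA(difficulty) ||
      any(difficulty < 0) || any(difficulty > 1)) {
    stop("'difficulty' must be a named vector of values in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(rt_max) || rt_max <= 0) stop("'rt_max' must be positive", call. = FALSE)
  if (!is.numeric(at_max) || at_max <= 0 || at_max > rt_max) {
    stop("'at_max' must satisfy 0 < at_max <= rt_max", call. = FALSE)
  }
  structure(list(difficulty = difficulty,
                 rt_max = as.numeric(rt_max),
                 at_max = as.numeric(at_max)),
            class = "frozen_params")
}

#' @export
print.frozen_params <- function(x, ...) {
  cat(sprintf("Frozen IDoCT parameters: %d items, rt_max = %.1f ms, at_max = %.1f ms\n",
              length(x$difficulty), x$rt_max, x$at_max))
  invisible(x)
}

#' Score new sessions with frozen baseline parameters
#'
#' Runs only the answer-time decomposition and specific-ability stages, with
#' the item-difficulty map, `rt_max`, and `at_max` fixed to their baseline
#' values, so that the resulting specific abilities and mean delays are on
#' the same scale as the baseline fit.
#'
#' @param trials trial table for the new sessions ([read_trials()] schema).
#' @param frozen a [frozen_params()] object.
#' @param unknown_items what to do with trials whose item is absent from the
#'   frozen map: `"error"` (default) or `"drop"` (dropped rows are counted).
#' @param rt_overflow what to do with reaction times above the frozen
#'   `rt_max`: `"error"` (default) or `"clip"` to `rt_max` (clipped rows are
#'   counted).
#' @param control an [idoct_control()] list.
#' @return A list with `participants` (`participant_id`, `ability`,
#'   `specific_ability`, `mean_delay_ms`, `personal_floor_ms`, `n_trials`),
#'   `trial_performance`, `n_dropped`, `n_clipped`.
#' @export
score_frozen <- function(trials, frozen,
                         unknown_items = c("error", "drop"),
                         rt_overflow = c("error", "clip"),
                         control = idoct_control()) {
  stopifnot(inherits(frozen, "frozen_params"))
  unknown_items <- match.arg(unknown_items)
  rt_overflow <- match.arg(rt_overflow)
  trials <- check_trials(trials, require_session = FALSE)

  unknown <- setdiff(unique(trials$item_id), names(frozen$difficulty))
  n_dropped <- 0L
  if (length(unknown)) {
    if (unknown_items == "error") {
      stop("item(s) absent from the frozen difficulty map: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    drop <- trials$item_id %in% unknown
    n_dropped <- sum(drop)
    message(sprintf("dropping %d trial(s) on %d unknown item(s)",
                    n_dropped, length(unknown)))
    trials <- trials[!drop, , drop = FALSE]
    if (nrow(trials) == 0L) stop("no scorable trials remain", call. = FALSE)
  }

  over <- trials$rt_ms > frozen$rt_max
  n_clipped <- 0L
  if (any(over)) {
    if (rt_overflow == "error") {
      stop(sprintf("%d reaction time(s) exceed the frozen rt_max (%.1f ms); ",
                   sum(over), frozen$rt_max),
           "use rt_overflow = \"clip\" to cap them", call. = FALSE)
    }
    n_clipped <- sum(over)
    warning(sprintf("clipped %d reaction time(s) to the frozen rt_max", n_clipped))
    trials$rt_ms[over] <- frozen$rt_max
  }

  item_scales <- data.frame(item_id = names(frozen$difficulty),
                            difficulty = as.numeric(frozen$difficulty),
                            stringsAsFactors = FALSE)
  stage2 <- decompose_answer_time(trials, item_scales, frozen$rt_max, control)
  scores <- specific_ability(stage2$trial_performance, frozen$at_max)
  delays <- participant_delay(stage2$trial_performance)

  participants <- merge(stage2$participants,
                        scores[, c("participant_id", "specific_ability")],
                        by = "participant_id", sort = TRUE)
  participants <- merge(participants, delays, by = "participant_id", sort = TRUE)
  participants <- participants[, c("participant_id", "ability", "specific_ability",
                                   "mean_delay_ms", "personal_floor_ms", "n_trials")]

  list(participants = participants,
       trial_performance = stage2$trial_performance,
       n_dropped = n_dropped,
       n_clipped = n_clipped)
}

#' Test-retest reliability summary (Pearson + Bland-Altman)
#'
#' Matches baseline and follow-up scores by participant (inner join) and
#' reports the Pearson correlation together with the Bland-Altman agreement
#' summary: mean difference (follow-up minus baseline) and the
#' `mean +/- 1.96 * SD` limits of agreement.
#'
#' @param baseline,followup data.frames with `participant_id` and the score
#'   column named by `score`.
#' @param score name of the score column (e.g. `"specific_ability"`,
#'   `"mean_delay_ms"`).
#' @return An object of class `reliability_report`: a list with `score`,
#'   `pearson_r`, `mean_difference`, `sd_difference`,
#'   `limits_of_agreement` (length-2 vector), `n_pairs`, and the matched
#'   `pairs` table.
#' @export
reliability_summary <- function(baseline, followup, score = "specific_ability") {
  for (d in list(baseline, followup)) {
    if (!all(c("participant_id", score) %in% names(d))) {
      stop("both tables need columns 'participant_id' and '", score, "'", call. = FALSE)
    }
  }
  pairs <- merge(baseline[, c("participant_id", score)],
                 followup[, c("participant_id", score)],
                 by = "participant_id", suffixes = c("_baseline", "_followup"))
  x <- pairs[[paste0(score, "_baseline")]]
  y <- pairs[[paste0(score, "_followup")]]
  if (nrow(pairs) < 2L) stop("need at least 2 matched pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("scores must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the score vectors; correlation undefined", call. = FALSE)
  }
  diffs <- y - x
  md <- mean(diffs)
  sdd <- stats::sd(diffs)
  structure(
    list(score = score,
         pearson_r = stats::cor(x, y),
         mean_difference = md,
         sd_difference = sdd,
         limits_of_agreement = c(lower = md - 1.96 * sdd, upper = md + 1.96 * sdd),
         n_pairs = nrow(pairs),
         pairs = pairs),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("Test-retest reliability of '%s' (%d matched pairs)\n",
              x$score, x$n_pairs))
  cat(sprintf("  Pearson r = %.3f\n", x$pearson_r))
  cat(sprintf("  Bland-Altman: mean difference %.4g, limits of agreement [%.4g, %.4g]\n",
              x$mean_difference, x$limits_of_agreement[["lower"]],
              x$limits_of_agreement[["upper"]]))
  invisible(x)
}
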