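MODEL_FORMAT_VERSION <- 1L

#' Read and validate a long-format trial table
#'
#' Reads a delimited text file (comma- or tab-separated, chosen by
#' extension unless `sep` is given) with the required header
#' `participant_id, session, trial_index, item_id, rt_ms, correct`.
#' Reaction times are in milliseconds; `correct` must be literally 0 or 1
#' (truthy strings are rejected); `trial_index` is 1-based within each
#' `(participant, session)`.
#'
#' Malformed headers, duplicate `(participant, session, trial_index)` rows,
#' and empty files are hard errors. Participants whose sessions are
#' incomplete — a gap in the 1..n trial-index sequence, a non-positive or
#' missing reaction time, or missing/non-binary correctness — are excluded
#' in full, with per-reason participant counts in the report.
#'
#' @param path file path.
#' @param sep field separator; default by extension (`.tsv`/`.tab` = tab,
#'   otherwise comma).
#' @return list with `trials` (validated data.frame) and `exclusions`
#'   (data.frame `reason`, `n_participants`).
#' @export
read_trials <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", encoding = "UTF-8",
                           check.names = FALSE, quote = "\"")
  required <- c("participant_id", "session", "trial_index", "item_id",
                "rt_ms", "correct")
  if (!identical(sort(intersect(required, names(raw))), sort(required))) {
    stop("malformed header: need columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("empty trial file: ", path, call. = FALSE)
  raw <- raw[required]

  ti <- suppressWarnings(as.numeric(raw$trial_index))
  if (anyNA(ti) || any(ti != as.integer(ti)) || any(ti < 1)) {
    stop("'trial_index' must be a positive integer in every row", call. = FALSE)
  }
  raw$trial_index <- as.integer(ti)
  key <- paste(raw$participant_id, raw$session, raw$trial_index, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1L]
    stop(sprintf(
      "duplicate (participant, session, trial_index) at data row %d: (%s, %s, %d)",
      bad, raw$participant_id[bad], raw$session[bad], raw$trial_index[bad]),
      call. = FALSE)
  }

  rt <- suppressWarnings(as.numeric(raw$rt_ms))
  ok_rt <- !is.na(rt) & rt > 0
  ok_correct <- raw$correct %in% c("0", "1")

  bad_rt <- unique(raw$participant_id[!ok_rt])
  bad_correct <- unique(raw$participant_id[!ok_correct])

  # contiguity of trial indices within (participant, session)
  ps <- split(raw$trial_index, paste(raw$participant_id, raw$session, sep = "\r"))
  gap <- vapply(ps, function(idx) !setequal(idx, seq_len(max(idx))), logical(1))
  bad_gap <- unique(sub("\r.*$", "", names(ps)[gap]))

  excluded <- union(union(bad_rt, bad_correct), bad_gap)
  report <- data.frame(
    reason = c("non_positive_or_missing_rt", "invalid_correctness",
               "missing_trial_index"),
    n_participants = c(length(bad_rt), length(bad_correct), length(bad_gap))
  )

  keep <- !(raw$participant_id %in% excluded)
  trials <- raw[keep, , drop = FALSE]
  if (nrow(trials) == 0L) {
    stop("no participants remain after completeness filtering", call. = FALSE)
  }
  trials$rt_ms <- as.numeric(trials$rt_ms)
  trials$correct <- as.numeric(trials$correct)
  rownames(trials) <- NULL
  list(trials = trials, exclusions = report)
}

#' Persist a fitted model's frozen parameters and provenance as JSON
#'
#' Writes the global parameters a rescoring run needs (`rt_max`, `at_max`,
#' the item-difficulty map), the iteration counts and convergence
#' histories, the control echo, and the package version, at full numeric
#' precision. The round trip `save -> load -> save` is byte-identical.
#'
#' @param fit an `idoct` fit (or an `idoct_model` loaded earlier).
#' @param path output path for the JSON file.
#' @return `path`, invisibly.
#' @export
save_model <- function(fit, path) {
  if (inherits(fit, "idoct")) {
    state <- list(
      format_version = MODEL_FORMAT_VERSION,
      package_version = as.character(utils::packageVersion("idoct")),
      rt_max = fit$rt_max,
      at_max = fit$at_max,
      difficulty = as.list(stats::setNames(fit$item_scales$difficulty,
                                           fit$item_scales$item_id)),
      scaled_difficulty = as.list(stats::setNames(fit$item_scales$scaled_difficulty,
                                                  fit$item_scales$item_id)),
      n_presentations = as.list(stats::setNames(fit$item_scales$n_presentations,
                                                fit$item_scales$item_id)),
      difficulty_iterations = fit$difficulty_iterations,
      decomposition_iterations = fit$decomposition_iterations,
      convergence = list(
        difficulty = fit$convergence$difficulty,
        decomposition = fit$convergence$decomposition
      ),
      control = unclass(fit$control)
    )
  } else if (inherits(fit, "idoct_model")) {
    state <- fit$state
  } else {
    stop("'fit' must be an 'idoct' fit or an 'idoct_model'", call. = FALSE)
  }
  jsonlite::write_json(state, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a persisted model state
#'
#' Validates the format version and the presence of every frozen
#' parameter; a file missing any of them (e.g. truncated, or written by an
#' incompatible version) is an error.
#'
#' @param path path to a JSON file written by [save_model()].
#' @return An object of class `idoct_model`: list with `difficulty` (named
#'   vector), `rt_max`, `at_max`, `state` (the full parsed state).
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  state <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                    error = function(e) stop("unreadable model file: ",
                                             conditionMessage(e), call. = FALSE))
  if (is.null(state$format_version) ||
      state$format_version != MODEL_FORMAT_VERSION) {
    stop("model format version mismatch (expected ", MODEL_FORMAT_VERSION,
         ", found ", state$format_version %||% "none", ")", call. = FALSE)
  }
  for (field in c("rt_max", "at_max", "difficulty")) {
    if (is.null(state[[field]])) {
      stop("model file is missing required field '", field, "'", call. = FALSE)
    }
  }
  structure(
    list(difficulty = unlist(state$difficulty),
         rt_max = state$rt_max,
         at_max = state$at_max,
         state = state),
    class = "idoct_model"
  )
}

#' Write the fitted tables of a decomposition to a directory
#'
#' Emits `items.csv` (`item_id`, `difficulty`, `scaled_difficulty`,
#' `n_presentations`), `participants.csv` (`participant_id`, `ability`,
#' `specific_ability`, `mean_delay_ms`, `n_trials`), and `model.json` (the
#' [save_model()] artifact).
#'
#' @param fit an `idoct` fit.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_idoct_outputs <- function(fit, dir) {
  stopifnot(inherits(fit, "idoct"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fit$item_scales, file.path(dir, "items.csv"),
                   row.names = FALSE)
  utils::write.csv(
    fit$participants[, c("participant_id", "ability", "specific_ability",
                         "mean_delay_ms", "n_trials")],
    file.path(dir, "participants.csv"), row.names = FALSE)
  save_model(fit, file.path(dir, "model.json"))
  invisible(dir)
}
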