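#' Control parameters for the IDoCT fixed-point iterations
#'
#' Collects the numerical knobs of the two iterative stages: the convergence
#' tolerance on the mean absolute relative change of the iterated quantities,
#' the iteration caps, the relaxation (damping) factor of the difficulty
#' update, an optional percentile cap on the global maximum reaction time,
#' and which scaled-difficulty convention to use.
#'
#' @param tol convergence tolerance: iteration stops when the mean absolute
#'   relative change of the iterated quantities (item difficulties in stage 1,
#'   participant abilities in stage 2) falls below `tol`. Default `1e-6`.
#' @param max_iter_difficulty iteration cap for the difficulty loop (stage 1).
#' @param max_iter_decomposition iteration cap for the answer-time
#'   decomposition loop (stage 2).
#' @param damping relaxation factor \eqn{\lambda} of the difficulty update,
#'   `new = (1 - damping) * old + damping * update`. The default 1 is the
#'   plain synchronous update; the solver drops to 0.5 on its own if the
#'   history shows sign-alternating mean changes for 10 consecutive
#'   iterations (oscillation near the marginal regime where reaction times
#'   approach 0). Damping moves the path, never the fixed point.
#' @param rt_max_quantile optional quantile in (0, 1] at which to cap the
#'   global maximum reaction time for outlier robustness. `NULL` (default)
#'   uses the exact maximum over all trials and participants.
#' @param ds_rescale scaled-difficulty convention. `"printed"` (default) is
#'   `DS(t) = D(t) * mean(AS)` over the participants who completed item `t`.
#'   `"cohort-mean"` additionally divides by the cohort-mean specific
#'   ability, so that an item seen by a representative slice of the cohort
#'   keeps `DS = D`; see the methods vignette for why the printed form
#'   compresses the scale.
#' @param eps absolute tolerance used in relative-change denominators and
#'   bound comparisons. Default `1e-12`.
#'
#' @return A list of class `idoct_control`.
#' @export
#' @examples
#' idoct_control(tol = 1e-8)
idoct_control <- function(tol = 1e-6,
                          max_iter_difficulty = 1000L,
                          max_iter_decomposition = 500L,
                          damping = 1,
                          rt_max_quantile = NULL,
                          ds_rescale = c("printed", "cohort-mean"),
                          eps = 1e-12) {
  ds_rescale <- match.arg(ds_rescale)
  stopifnot(is.numeric(tol), length(tol) == 1L, tol > 0,
            is.numeric(max_iter_difficulty), max_iter_difficulty >= 1,
            is.numeric(max_iter_decomposition), max_iter_decomposition >= 1,
            is.numeric(damping), damping > 0, damping <= 1,
            is.numeric(eps), eps > 0)
  if (!is.null(rt_max_quantile)) {
    stopifnot(is.numeric(rt_max_quantile), length(rt_max_quantile) == 1L,
              rt_max_quantile > 0, rt_max_quantile <= 1)
  }
  structure(
    list(tol = tol,
         max_iter_difficulty = as.integer(max_iter_difficulty),
         max_iter_decomposition = as.integer(max_iter_decomposition),
         damping = damping,
         rt_max_quantile = rt_max_quantile,
         ds_rescale = ds_rescale,
         eps = eps),
    class = "idoct_control"
  )
}

# Validate a long-format trial table. Returns the table with canonical
# column types; stops with a descriptive error otherwise.
check_trials <- function(trials, require_session = TRUE) {
  if (!is.data.frame(trials) || nrow(trials) == 0L) {
    stop("'trials' must be a non-empty data.frame of trial records", call. = FALSE)
  }
  needed <- c("participant_id", "item_id", "rt_ms", "correct")
  if (require_session) needed <- c(needed, "session", "trial_index")
  missing <- setdiff(needed, names(trials))
  if (length(missing)) {
    stop("'trials' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(trials$rt_ms) || anyNA(trials$rt_ms) || any(trials$rt_ms <= 0)) {
    stop("'rt_ms' must be positive and non-missing for every trial", call. = FALSE)
  }
  if (anyNA(trials$correct) || !all(trials$correct %in% c(0, 1))) {
    stop("'correct' must be coded 0/1 with no missing values", call. = FALSE)
  }
  trials$participant_id <- as.character(trials$participant_id)
  trials$item_id <- as.character(trials$item_id)
  trials$correct <- as.numeric(trials$correct)
  trials
}

# mean absolute relative change between successive iterates
mean_rel_change <- function(new, old, eps) {
  mean(abs(new - old) / pmax(abs(old), eps))
}

non_convergence_error <- function(stage, iterations, history) {
  stop(structure(
    class = c("idoct_non_convergence", "error", "condition"),
    list(message = sprintf(
           "%s loop failed to converge within %d iterations (final mean relative change %.3g)",
           stage, iterations, utils::tail(history$mean_rel_change, 1L)),
         call = NULL,
         history = history)
  ))
}
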