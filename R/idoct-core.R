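#' Per-trial performance score
#'
#' The performance of a correct response is the residual speed fraction
#' `1 - rt / rt_max` weighted by the trial's difficulty; an incorrect
#' response scores 0 regardless of speed. This is the quantity whose
#' participant-wise mean defines ability and whose item-wise mean (of its
#' complement) defines data-driven difficulty.
#'
#' @param rt reaction time in milliseconds, `0 < rt <= rt_max`.
#' @param correct 0/1 correctness indicator.
#' @param difficulty trial difficulty in `[0, 1]`.
#' @param rt_max global maximum reaction time (ms) across all trials and
#'   participants.
#' @return Performance in `[0, difficulty]`. Vectorised over all arguments.
#' @export
#' @examples
#' trial_performance(5000, 1, 0.6, 10000)  # 0.3
#' trial_performance(5000, 0, 0.6, 10000)  # 0
trial_performance <- function(rt, correct, difficulty, rt_max) {
  if (any(rt <= 0) || any(rt > rt_max)) {
    stop("'rt' must satisfy 0 < rt <= rt_max", call. = FALSE)
  }
  if (any(difficulty < 0) || any(difficulty > 1)) {
    stop("'difficulty' must lie in [0, 1]", call. = FALSE)
  }
  if (!all(correct %in% c(0, 1))) {
    stop("'correct' must be coded 0/1", call. = FALSE)
  }
  correct * (1 - rt / rt_max) * difficulty
}

# Split rt into (at, rt - at) such that at + dt == rt holds bit-exactly:
# the rounded complement can miss by one ulp, so re-complement until the
# identity closes (one pass in practice; at moves by <= 1 ulp).
split_rt <- function(rt, at) {
  dt <- rt - at
  for (pass in 1:4) {
    bad <- at + dt != rt
    if (!any(bad)) break
    at[bad] <- rt[bad] - dt[bad]
    dt[bad] <- rt[bad] - at[bad]
  }
  list(at = at, dt = dt)
}

# Resolve the global RT ceiling, optionally capped at a quantile.
resolve_rt_max <- function(rt, control) {
  if (is.null(control$rt_max_quantile)) {
    max(rt)
  } else {
    as.numeric(stats::quantile(rt, control$rt_max_quantile, names = FALSE))
  }
}

#' Fixed-point estimation of data-driven item difficulty
#'
#' Stage 1 of the decomposition. Item difficulties start at 1 and are
#' iterated through the mutual recursion between per-trial performance
#' `P = correct * (1 - rt/rt_max) * D` and per-item difficulty
#' `D = mean(1 - P)` over all presentations of the item, until the mean
#' absolute relative change across items falls below `control$tol`. Each
#' presentation event counts once, so repeated presentations of an item to
#' the same participant are weighted by their number.
#'
#' @param trials data.frame with columns `participant_id`, `item_id`,
#'   `rt_ms`, `correct` (plus any others, ignored here).
#' @param control an [idoct_control()] list.
#' @param rt_max optional externally fixed RT ceiling (used when rescoring
#'   with frozen parameters); default is computed from `trials`.
#' @return A list with `item_scales` (data.frame `item_id`, `difficulty`,
#'   `n_presentations`), `rt_max`, `iterations`, and `history` (data.frame
#'   `iteration`, `mean_rel_change`).
#' @export
#' @examples
#' tr <- data.frame(participant_id = c("p1", "p2"), item_id = "w1",
#'                  rt_ms = c(5000, 5000), correct = 1)
#' fit_item_difficulty(tr)$item_scales$difficulty  # 2/3
fit_item_difficulty <- function(trials, control = idoct_control(), rt_max = NULL) {
  trials <- check_trials(trials, require_session = FALSE)
  if (is.null(rt_max)) rt_max <- resolve_rt_max(trials$rt_ms, control)
  if (any(trials$rt_ms > rt_max)) {
    stop("some reaction times exceed rt_max", call. = FALSE)
  }

  item <- factor(trials$item_id)
  items <- levels(item)
  # per-presentation speed credit; its item mean drives the update
  # D_new = 1 - mean(correct * (1 - rt/rt_max)) * D_old
  credit <- trials$correct * (1 - trials$rt_ms / rt_max)
  credit_mean <- as.numeric(tapply(credit, item, mean))
  n_pres <- as.integer(tabulate(item))

  d <- rep(1, length(items))
  lambda <- control$damping
  history <- data.frame(iteration = integer(), mean_rel_change = numeric())
  signed_changes <- numeric()
  converged <- FALSE

  for (it in seq_len(control$max_iter_difficulty)) {
    update <- 1 - credit_mean * d
    d_new <- (1 - lambda) * d + lambda * update
    change <- mean_rel_change(d_new, d, control$eps)
    signed <- mean(d_new - d)
    history <- rbind(history, data.frame(iteration = it, mean_rel_change = change))
    signed_changes <- c(signed_changes, signed)
    # sign-alternating mean changes for 10 consecutive iterations:
    # oscillation around the fixed point -> relax the update
    if (length(signed_changes) >= 10L) {
      last10 <- utils::tail(signed_changes, 10L)
      if (all(last10 != 0) && all(diff(sign(last10)) != 0)) lambda <- 0.5
    }
    d <- d_new
    if (change < control$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) non_convergence_error("difficulty", control$max_iter_difficulty, history)

  list(item_scales = data.frame(item_id = items,
                                difficulty = d,
                                n_presentations = n_pres,
                                stringsAsFactors = FALSE),
       rt_max = rt_max,
       iterations = it,
       history = history)
}

#' Decompose reaction times into answer time and visuo-motor delay
#'
#' Stage 2. With item difficulties held fixed, each reaction time is split
#' into a cognitive answer time `AT` and a visuo-motor delay `DT = RT - AT`.
#' The normalised answer time of a trial is `ATN = (1 - A(i)) * D(t)`, where
#' `A(i)` is the participant's ability (mean per-trial performance); then
#' `AT = ATN * (RT - floor(i))`, with `floor(i)` the participant's minimum
#' reaction time (their personal visuo-motor floor). Ability starts at 1 for
#' everyone and the recursion runs to a fixed point. Updates are synchronous:
#' all `AT`/`DT` are computed from the previous iteration's abilities, then
#' performance, then all abilities — so the result does not depend on record
#' order.
#'
#' @param trials validated trial table (see [fit_item_difficulty()]).
#' @param item_scales data.frame with `item_id` and `difficulty` covering
#'   every item in `trials`.
#' @param rt_max global RT ceiling, from stage 1 or frozen parameters.
#' @param control an [idoct_control()] list.
#' @return A list with `trial_performance` (the input rows plus `difficulty`,
#'   `performance`, `answer_time_norm`, `answer_time`, `delay_time`),
#'   `participants` (data.frame `participant_id`, `ability`,
#'   `personal_floor_ms`, `n_trials`), `iterations`, `history`.
#' @export
decompose_answer_time <- function(trials, item_scales, rt_max,
                                  control = idoct_control()) {
  trials <- check_trials(trials, require_session = FALSE)
  d_map <- stats::setNames(item_scales$difficulty, item_scales$item_id)
  unknown <- setdiff(unique(trials$item_id), names(d_map))
  if (length(unknown)) {
    stop("item(s) missing from the difficulty scale: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(trials$rt_ms > rt_max)) {
    stop("some reaction times exceed rt_max", call. = FALSE)
  }

  pid <- factor(trials$participant_id)
  participants <- levels(pid)
  d_t <- as.numeric(d_map[trials$item_id])
  floor_i <- as.numeric(tapply(trials$rt_ms, pid, min))  # personal floor DTmax(i)
  floor_t <- floor_i[as.integer(pid)]
  n_trials <- as.integer(tabulate(pid))

  # performance does not depend on the AT/DT split (AT + DT = RT), so it is
  # fixed once D is fixed; the ability recursion converges in few iterations
  perf <- trial_performance(trials$rt_ms, trials$correct, d_t, rt_max)

  a <- rep(1, length(participants))
  history <- data.frame(iteration = integer(), mean_rel_change = numeric())
  converged <- FALSE
  for (it in seq_len(control$max_iter_decomposition)) {
    atn <- (1 - a[as.integer(pid)]) * d_t
    s <- split_rt(trials$rt_ms, atn * (trials$rt_ms - floor_t))
    at <- s$at
    dt <- s$dt
    a_new <- as.numeric(tapply(perf, pid, mean))
    change <- mean_rel_change(a_new, a, control$eps)
    history <- rbind(history, data.frame(iteration = it, mean_rel_change = change))
    a <- a_new
    if (change < control$tol) {
      # recompute the split at the converged abilities
      atn <- (1 - a[as.integer(pid)]) * d_t
      s <- split_rt(trials$rt_ms, atn * (trials$rt_ms - floor_t))
      at <- s$at
      dt <- s$dt
      converged <- TRUE
      break
    }
  }
  if (!converged) non_convergence_error("decomposition", control$max_iter_decomposition, history)

  tp <- trials
  tp$difficulty <- d_t
  tp$performance <- perf
  tp$answer_time_norm <- atn
  tp$answer_time <- at
  tp$delay_time <- dt

  list(trial_performance = tp,
       participants = data.frame(participant_id = participants,
                                 ability = a,
                                 personal_floor_ms = floor_i,
                                 n_trials = n_trials,
                                 stringsAsFactors = FALSE),
       iterations = it,
       history = history)
}

#' Specific ability from delay-corrected answer times
#'
#' Stage 3. The specific performance of a correct trial is
#' `PA = (1 - AT/AT_max) * D(t)`; wrong answers score 0. Specific ability
#' `AS(i)` is the participant-wise mean of `PA`, i.e. cognitive performance
#' after the visuo-motor component of the reaction time has been removed.
#'
#' @param trial_performance per-trial table from [decompose_answer_time()]
#'   (needs `participant_id`, `correct`, `answer_time`, `difficulty`).
#' @param at_max global maximum answer time (ms), computed after the
#'   decomposition loop has converged, or taken from frozen parameters.
#' @return data.frame `participant_id`, `specific_ability`, `n_trials`.
#' @export
specific_ability <- function(trial_performance, at_max) {
  if (!is.numeric(at_max) || length(at_max) != 1L || !is.finite(at_max) || at_max <= 0) {
    stop("'at_max' must be a single positive number; a cohort in which every ",
         "answer time is 0 cannot anchor the specific-ability scale -- refit ",
         "on data with non-degenerate reaction-time variation", call. = FALSE)
  }
  tp <- trial_performance
  pid <- factor(tp$participant_id)
  pa <- tp$correct * (1 - tp$answer_time / at_max) * tp$difficulty
  data.frame(participant_id = levels(pid),
             specific_ability = as.numeric(tapply(pa, pid, mean)),
             n_trials = as.integer(tabulate(pid)),
             stringsAsFactors = FALSE)
}

#' Mean visuo-motor delay per participant
#'
#' The arithmetic mean of the per-trial delay times `DT(i,t)`.
#'
#' @param trial_performance per-trial table from [decompose_answer_time()].
#' @return data.frame `participant_id`, `mean_delay_ms`.
#' @export
participant_delay <- function(trial_performance) {
  tp <- trial_performance
  if (nrow(tp) == 0L) stop("no trials with a computed delay time", call. = FALSE)
  pid <- factor(tp$participant_id)
  data.frame(participant_id = levels(pid),
             mean_delay_ms = as.numeric(tapply(tp$delay_time, pid, mean)),
             stringsAsFactors = FALSE)
}

#' Scale item difficulty by the ability of its presentees
#'
#' Stage 4. Adaptive designs present hard items mostly to able participants,
#' so the raw data-driven difficulty of those items is biased. The scaled
#' difficulty multiplies `D(t)` by the mean specific ability of the
#' participants who completed item `t`:
#' `DS(t) = D(t) * mean(AS(i))` over those participants. With
#' `ds_rescale = "cohort-mean"` the mean is divided by the cohort-mean
#' specific ability, which keeps `DS = D` for items seen by a representative
#' slice of the cohort.
#'
#' @param item_scales data.frame from [fit_item_difficulty()].
#' @param participant_scores data.frame with `participant_id` and
#'   `specific_ability`.
#' @param trials trial table linking participants to items.
#' @param control an [idoct_control()] list (`ds_rescale` is used).
#' @return `item_scales` with a `scaled_difficulty` column added.
#' @export
scale_difficulty <- function(item_scales, participant_scores, trials,
                             control = idoct_control()) {
  trials <- check_trials(trials, require_session = FALSE)
  as_map <- stats::setNames(participant_scores$specific_ability,
                            participant_scores$participant_id)
  if (anyNA(as_map[unique(trials$participant_id)])) {
    stop("specific ability missing for some participants in 'trials'", call. = FALSE)
  }
  # each participant who completed the item counts once
  seen <- unique(trials[, c("participant_id", "item_id")])
  mean_as <- tapply(as_map[seen$participant_id], factor(seen$item_id), mean)
  mean_as <- as.numeric(mean_as[item_scales$item_id])
  if (anyNA(mean_as)) {
    stop("item(s) with no presentees: ",
         paste(item_scales$item_id[is.na(mean_as)], collapse = ", "), call. = FALSE)
  }
  scale_fac <- mean_as
  if (control$ds_rescale == "cohort-mean") {
    scale_fac <- mean_as / mean(participant_scores$specific_ability)
  }
  item_scales$scaled_difficulty <- pmin(1, item_scales$difficulty * scale_fac)
  item_scales
}

#' Fit the full iterative decomposition
#'
#' Runs the complete pipeline on a long-format trial table: (1) fixed-point
#' estimation of item difficulties, (2) decomposition of each reaction time
#' into answer time and visuo-motor delay, (3) specific ability and mean
#' delay per participant, and (4) presentee-scaled item difficulty. The
#' global maximum answer time `at_max` is computed once, after stage 2
#' converges, and frozen thereafter.
#'
#' @param trials data.frame with columns `participant_id`, `session`,
#'   `trial_index`, `item_id`, `rt_ms`, `correct` (the [read_trials()]
#'   schema). `session`/`trial_index` are carried through but not used by
#'   the estimator.
#' @param control an [idoct_control()] list.
#' @return An object of class `idoct`: a list with `item_scales`
#'   (`item_id`, `difficulty`, `scaled_difficulty`, `n_presentations`),
#'   `participants` (`participant_id`, `ability`, `specific_ability`,
#'   `mean_delay_ms`, `personal_floor_ms`, `n_trials`), `trial_performance`,
#'   `rt_max`, `at_max`, iteration counts, convergence histories, and the
#'   control echo.
#' @export
#' @examples
#' tr <- data.frame(participant_id = rep(c("p1", "p2"), each = 2),
#'                  session = "baseline", trial_index = c(1, 2, 1, 2),
#'                  item_id = c("w1", "w2", "w1", "w2"),
#'                  rt_ms = c(800, 1500, 1200, 2600),
#'                  correct = c(1, 1, 1, 0))
#' fit <- idoct(tr)
#' fit$participants
idoct <- function(trials, control = idoct_control()) {
  trials <- check_trials(trials, require_session = FALSE)

  stage1 <- fit_item_difficulty(trials, control)
  stage2 <- decompose_answer_time(trials, stage1$item_scales, stage1$rt_max, control)
  at_max <- max(stage2$trial_performance$answer_time)
  scores <- specific_ability(stage2$trial_performance, at_max)
  delays <- participant_delay(stage2$trial_performance)

  participants <- merge(stage2$participants, scores[, c("participant_id", "specific_ability")],
                        by = "participant_id", sort = TRUE)
  participants <- merge(participants, delays, by = "participant_id", sort = TRUE)
  participants <- participants[, c("participant_id", "ability", "specific_ability",
                                   "mean_delay_ms", "personal_floor_ms", "n_trials")]

  item_scales <- scale_difficulty(stage1$item_scales, participants, trials, control)
  item_scales <- item_scales[, c("item_id", "difficulty", "scaled_difficulty",
                                 "n_presentations")]

  structure(
    list(item_scales = item_scales,
         participants = participants,
         trial_performance = stage2$trial_performance,
         rt_max = stage1$rt_max,
         at_max = at_max,
         difficulty_iterations = stage1$iterations,
         decomposition_iterations = stage2$iterations,
         convergence = list(difficulty = stage1$history,
                            decomposition = stage2$history),
         control = control),
    class = "idoct"
  )
}

#' @export
print.idoct <- function(x, ...) {
  cat("IDoCT decomposition\n")
  cat(sprintf("  %d participants, %d items, %d trials\n",
              nrow(x$participants), nrow(x$item_scales),
              nrow(x$trial_performance)))
  cat(sprintf("  rt_max = %.1f ms, at_max = %.1f ms\n", x$rt_max, x$at_max))
  cat(sprintf("  difficulty loop: %d iterations; decomposition loop: %d iterations\n",
              x$difficulty_iterations, x$decomposition_iterations))
  cat(sprintf("  mean D = %.3f, mean DS = %.3f, mean AS = %.3f, mean DT = %.0f ms\n",
              mean(x$item_scales$difficulty),
              mean(x$item_scales$scaled_difficulty),
              mean(x$participants$specific_ability),
              mean(x$participants$mean_delay_ms)))
  invisible(x)
}
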