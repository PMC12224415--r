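#' Mean difficulty of presented items by ability decile and trial position
#'
#' The adaptive staircase should present increasingly hard items to able
#' participants. This view averages, within fixed ability bins, the
#' difficulty of the items presented at each position of the session, so a
#' miscalibrated scale shows up as a trajectory that plateaus or falls.
#' Bins are `[0, 0.1), [0.1, 0.2), ..., [0.9, 1]` (closed on the left, open
#' on the right, last bin closed on both ends); empty bins are simply
#' absent from the table.
#'
#' @param trials trial table with `participant_id`, `trial_index`,
#'   `item_id`.
#' @param difficulty_map named numeric vector `item_id -> difficulty`
#'   (any scale: data-driven, scaled, or the task's original labels).
#' @param ability_scores data.frame with `participant_id` and `ability` in
#'   `[0, 1]`.
#' @param n_groups number of equal-width ability bins; default 10.
#' @return data.frame of class `trajectory_table`: `ability_group` (factor
#'   `"[0.0,0.1)"`, ...), `trial_index`, `mean_difficulty`, `n`.
#' @export
difficulty_trajectories <- function(trials, difficulty_map, ability_scores,
                                    n_groups = 10L) {
  stopifnot(all(c("participant_id", "trial_index", "item_id") %in% names(trials)),
            all(c("participant_id", "ability") %in% names(ability_scores)),
            n_groups >= 1L)
  if (any(ability_scores$ability < 0 | ability_scores$ability > 1)) {
    stop("'ability' scores must lie in [0, 1]", call. = FALSE)
  }
  d <- difficulty_map[trials$item_id]
  if (anyNA(d)) {
    stop("difficulty missing for item(s): ",
         paste(unique(trials$item_id[is.na(d)]), collapse = ", "), call. = FALSE)
  }
  breaks <- seq(0, 1, length.out = n_groups + 1L)
  labels <- sprintf("[%.1f,%.1f%s", breaks[-length(breaks)], breaks[-1L],
                    c(rep(")", n_groups - 1L), "]"))
  ab <- stats::setNames(ability_scores$ability, ability_scores$participant_id)
  grp_of <- cut(ab, breaks = breaks, labels = labels,
                right = FALSE, include.lowest = TRUE)
  names(grp_of) <- names(ab)
  grp <- grp_of[trials$participant_id]
  if (anyNA(grp)) stop("ability score missing for some participants", call. = FALSE)

  agg <- stats::aggregate(d, by = list(ability_group = grp,
                                       trial_index = trials$trial_index),
                          FUN = mean, drop = TRUE)
  cnt <- stats::aggregate(d, by = list(ability_group = grp,
                                       trial_index = trials$trial_index),
                          FUN = length, drop = TRUE)
  out <- data.frame(ability_group = agg$ability_group,
                    trial_index = agg$trial_index,
                    mean_difficulty = agg$x,
                    n = cnt$x)
  out <- out[order(out$ability_group, out$trial_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trajectory_table", "data.frame")
  out
}

#' Position at which a trajectory's running maximum stops increasing
#'
#' Purely descriptive plateau onset: the index of the last strict increase
#' of the running maximum. A trajectory whose running maximum still grows at
#' its final index has not plateaued and returns that final index.
#'
#' @param x numeric trajectory (mean difficulty by trial position).
#' @return Integer index.
#' @export
#' @examples
#' plateau_onset(c(1, 2, 3, 3, 2.5))  # 3
plateau_onset <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  rm <- cummax(x)
  idx <- which(diff(rm) > 0)
  if (length(idx) == 0L) 1L else max(idx) + 1L
}

#' Estimate-versus-truth correlations for parameter recovery
#'
#' Computes Pearson and Spearman correlations between the fitted
#' decomposition and the generative truth of a simulated cohort:
#' specific ability against latent ability, mean delay against latent
#' visuo-motor delay, and item difficulty against true item difficulty
#' (restricted to items presented at least `min_presentations` times, since
#' difficulty is estimated per item from its presentees).
#'
#' @param fit an `idoct` fit of the cohort's trial table.
#' @param cohort the `pvt_cohort` the trials came from.
#' @param min_presentations minimum presentations for an item to enter the
#'   difficulty comparison; default 30.
#' @return data.frame with `quantity`, `pearson`, `spearman`, `n`.
#' @export
recovery_report <- function(fit, cohort, min_presentations = 30L) {
  stopifnot(inherits(fit, "idoct"), inherits(cohort, "pvt_cohort"))
  pp <- merge(fit$participants, cohort$truth, by = "participant_id")
  items <- merge(fit$item_scales, cohort$bank, by = "item_id")
  items <- items[items$n_presentations >= min_presentations, , drop = FALSE]
  pairs <- list(
    list(q = "specific_ability~theta", x = pp$specific_ability, y = pp$theta),
    list(q = "mean_delay~delta", x = pp$mean_delay_ms, y = pp$delta_ms),
    list(q = "difficulty~b", x = items$difficulty, y = items$b)
  )
  rows <- lapply(pairs, function(p) {
    if (length(p$x) < 3L) stop("fewer than 3 pairs for ", p$q, call. = FALSE)
    if (stats::sd(p$x) == 0 || stats::sd(p$y) == 0) {
      stop("degenerate (constant) values for ", p$q, call. = FALSE)
    }
    data.frame(quantity = p$q,
               pearson = stats::cor(p$x, p$y),
               spearman = stats::cor(p$x, p$y, method = "spearman"),
               n = length(p$x))
  })
  do.call(rbind, rows)
}

#' Moment and histogram summary of a score distribution
#'
#' Mean, standard deviation, skewness, and excess kurtosis by the standard
#' population-moment formulas (`SD = sqrt(m2)` with the `1/n` divisor, so
#' `{0, 1}` has SD 0.5; skewness `m3 / m2^{3/2}`; excess kurtosis
#' `m4 / m2^2 - 3`), plus histogram counts over fixed bins. Scores lying in
#' `[0, 1]` are binned over `[0, 1]`; otherwise over their observed range.
#' A constant vector has SD 0 and `NA` shape moments, flagged via
#' `degenerate`.
#'
#' @param x numeric vector of scores (`>= 2` finite values).
#' @param bins number of histogram bins; default 50.
#' @return list with `mean`, `sd`, `skewness`, `kurtosis_excess`, `n`,
#'   `degenerate`, `breaks`, `counts`.
#' @export
distribution_summary <- function(x, bins = 50L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need at least 2 finite values", call. = FALSE)
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  degenerate <- m2 == 0
  lo <- if (all(x >= 0 & x <= 1)) 0 else min(x)
  hi <- if (all(x >= 0 & x <= 1)) 1 else max(x)
  breaks <- seq(lo, hi, length.out = bins + 1L)
  counts <- if (hi > lo) {
    hist(x, breaks = breaks, plot = FALSE, include.lowest = TRUE)$counts
  } else {
    c(n, rep(0L, bins - 1L))
  }
  list(mean = m,
       sd = sqrt(m2),
       skewness = if (degenerate) NA_real_ else mean((x - m)^3) / m2^1.5,
       kurtosis_excess = if (degenerate) NA_real_ else mean((x - m)^4) / m2^2 - 3,
       n = n,
       degenerate = degenerate,
       breaks = breaks,
       counts = counts)
}

#' Plot difficulty trajectories by ability group
#'
#' Thin ggplot2 layer over [difficulty_trajectories()]; one line per ability
#' bin.
#'
#' @param x a `trajectory_table`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot.trajectory_table <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting needs the 'ggplot2' package", call. = FALSE)
  }
  ggplot2::ggplot(x, ggplot2::aes(x = .data$trial_index,
                                  y = .data$mean_difficulty,
                                  colour = .data$ability_group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Trial position", y = "Mean difficulty of presented items",
                  colour = "Ability bin") +
    ggplot2::theme_minimal()
}
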