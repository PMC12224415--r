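#' Synthetic item bank for an adaptive picture-vocabulary-like task
#'
#' Builds a bank of four-alternative forced-choice items with known latent
#' parameters: true difficulty `b` on the logit scale, discrimination `a`,
#' guessing floor `c`, and the *labelled* difficulty — the scale the
#' adaptive staircase believes, which may be deliberately miscalibrated to
#' emulate a task whose difficulty scale cannot discriminate among high
#' performers.
#'
#' Miscalibration modes:
#' * `"none"` — labels equal the true difficulties.
#' * `"ceiling"` — the labelled scale keeps the full intended spread, but
#'   the *true* difficulty saturates above a knee
#'   (`b = knee + squash * (labelled - knee)` for labels past the knee):
#'   the bank simply holds no genuinely harder material at the top of its
#'   scale. Able participants then answer nearly everything correctly,
#'   their ability estimates pin at the search bound, and the task's own
#'   score piles up at the ceiling — the pathology a sub-optimally
#'   calibrated vocabulary scale produces in practice.
#' * `"shuffled_top"` — labels of the top quartile are randomly permuted
#'   (sub-optimal ordering rather than compression).
#'
#' @param n_items number of items; default 340.
#' @param b_range range of true difficulty, spanned evenly; default
#'   `c(-3, 3)`.
#' @param discrimination common discrimination `a > 0`; default 1.5.
#' @param guessing guessing floor `c`; default 0.25 (four alternatives).
#' @param miscalibration one of `"none"`, `"ceiling"`, `"shuffled_top"`.
#' @param knee,squash ceiling-compression parameters (see above). The knee
#'   default of -0.5 places the end of the bank's usable difficulty range
#'   below the ability-population median, so the ceiling affects the
#'   majority of a standard-normal cohort — the regime in which an adaptive
#'   vocabulary scale produces a high, ceiling-compressed score
#'   distribution.
#' @param seed RNG seed, required for `"shuffled_top"`.
#' @return data.frame of class `pvt_bank` with columns `item_id`, `b`, `a`,
#'   `c`, `labelled`.
#' @export
#' @examples
#' bank <- pvt_bank(n_items = 50)
#' range(bank$labelled)
pvt_bank <- function(n_items = 340L,
                     b_range = c(-3, 3),
                     discrimination = 1.5,
                     guessing = 0.25,
                     miscalibration = c("none", "ceiling", "shuffled_top"),
                     knee = -0.5,
                     squash = 0.05,
                     seed = NULL) {
  miscalibration <- match.arg(miscalibration)
  stopifnot(n_items >= 2L, discrimination > 0, guessing >= 0, guessing < 1,
            length(b_range) == 2L, b_range[1] < b_range[2])
  labelled <- seq(b_range[1], b_range[2], length.out = n_items)
  b <- labelled
  if (miscalibration == "ceiling") {
    b <- ifelse(labelled <= knee, labelled, knee + squash * (labelled - knee))
  } else if (miscalibration == "shuffled_top") {
    if (is.null(seed)) stop("'shuffled_top' needs a seed", call. = FALSE)
    top <- which(labelled >= stats::quantile(labelled, 0.75))
    labelled[top] <- withr_seed(seed, sample(labelled[top]))
  }
  structure(
    data.frame(item_id = sprintf("w%03d", seq_len(n_items)),
               b = b,
               a = discrimination,
               c = guessing,
               labelled = labelled,
               stringsAsFactors = FALSE),
    class = c("pvt_bank", "data.frame"),
    miscalibration = miscalibration
  )
}

# evaluate `expr` under a local RNG seed without touching the caller's stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Probability of a correct response under the guessing-floor logistic model
#'
#' `P(correct) = c + (1 - c) * logistic(a * (theta - b))`: a three-parameter
#' logistic item-response model whose lower asymptote is the guessing floor
#' of a forced-choice design.
#'
#' @param theta latent ability (logit scale).
#' @param b item difficulty.
#' @param a discrimination (`> 0`).
#' @param c guessing floor in `[0, 1)`.
#' @return Probability in `[c, 1)`. Vectorised.
#' @export
#' @examples
#' prob_correct(0, 0)  # 0.625 at theta == b with c = 0.25
prob_correct <- function(theta, b, a = 1.5, c = 0.25) {
  if (any(!is.finite(theta))) stop("'theta' must be finite", call. = FALSE)
  c + (1 - c) * stats::plogis(a * (theta - b))
}

#' Simulation configuration for the adaptive staircase task
#'
#' Reaction times follow `rt = delta + tau * softplus(kappa * (b - theta)
#' + beta) * exp(noise)`, with `noise ~ Normal(0, sigma)`: the cognitive
#' component is non-negative, increases smoothly with the difficulty-ability
#' gap, and carries multiplicative lognormal noise, so `rt > delta` always.
#'
#' @param min_trials minimum session length; default 20.
#' @param max_trials maximum session length; default 30.
#' @param se_stop stop once the ability estimate's standard error falls
#'   below this (and `min_trials` is reached); default 0.5.
#' @param theta_bounds search bounds of the maximum-likelihood ability
#'   estimate; default `c(-4, 4)`.
#' @param tau,kappa,beta,sigma reaction-time model parameters (ms scale for
#'   `tau`); defaults 800, 1, 1, 0.3.
#' @param delta_meanlog,delta_sdlog lognormal parameters of the visuo-motor
#'   delay distribution; defaults `log(3000)` and 0.33 (mean about 3160 ms).
#' @param theta_mean,theta_sd normal parameters of the latent ability
#'   distribution; defaults 0 and 1.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(min_trials = 20L, max_trials = 30L, se_stop = 0.5,
                       theta_bounds = c(-4, 4),
                       tau = 800, kappa = 1, beta = 1, sigma = 0.3,
                       delta_meanlog = log(3000), delta_sdlog = 0.33,
                       theta_mean = 0, theta_sd = 1) {
  stopifnot(min_trials >= 1L, max_trials >= min_trials, se_stop > 0,
            length(theta_bounds) == 2L, theta_bounds[1] < theta_bounds[2],
            tau > 0, sigma >= 0, delta_sdlog >= 0, theta_sd > 0)
  structure(list(min_trials = as.integer(min_trials),
                 max_trials = as.integer(max_trials),
                 se_stop = se_stop,
                 theta_bounds = theta_bounds,
                 tau = tau, kappa = kappa, beta = beta, sigma = sigma,
                 delta_meanlog = delta_meanlog, delta_sdlog = delta_sdlog,
                 theta_mean = theta_mean, theta_sd = theta_sd),
            class = "sim_config")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Draw one simulated response (correctness and reaction time)
#'
#' Correctness is Bernoulli with probability [prob_correct()] at the item's
#' *true* difficulty; the reaction time adds the participant's visuo-motor
#' delay to a noisy cognitive time that grows with `b - theta`. Consumes the
#' current RNG stream.
#'
#' @param theta latent ability.
#' @param delta latent visuo-motor delay (ms).
#' @param item one-row slice of a [pvt_bank()].
#' @param config a [sim_config()] list.
#' @return list with `correct` (0/1) and `rt_ms` (`> delta`).
#' @export
sample_response <- function(theta, delta, item, config = sim_config()) {
  p <- prob_correct(theta, item$b, item$a, item$c)
  correct <- stats::rbinom(1L, 1L, p)
  cog <- config$tau * softplus(config$kappa * (item$b - theta) + config$beta)
  noise <- if (config$sigma > 0) exp(stats::rnorm(1L, 0, config$sigma)) else 1
  list(correct = correct, rt_ms = delta + cog * noise)
}

#' Maximum-likelihood ability estimate from a response history
#'
#' Maximises the likelihood of the guessing-floor logistic model over a
#' bounded interval; the standard error comes from the observed information
#' (negative second derivative of the log-likelihood) at the maximum. An
#' all-correct or all-wrong history has its likelihood maximised at a
#' bound, which is returned with `se = Inf` so an adaptive algorithm keeps
#' sampling extreme items.
#'
#' @param correct 0/1 response vector.
#' @param difficulty item difficulties *as believed by the scorer* (for a
#'   miscalibrated bank these are the labelled, not true, values).
#' @param a,c discrimination and guessing floor (scalars or vectors).
#' @param bounds search interval; default `c(-4, 4)`.
#' @return list with `theta_hat` and `se`.
#' @export
#' @examples
#' mle_theta(c(1, 0), c(1, -1), a = 1, c = 0)$theta_hat  # 0 by symmetry
mle_theta <- function(correct, difficulty, a = 1.5, c = 0.25,
                      bounds = c(-4, 4)) {
  n <- length(correct)
  if (n == 0L) stop("empty response history", call. = FALSE)
  stopifnot(length(difficulty) == n, all(correct %in% c(0, 1)))
  a <- rep_len(a, n); c <- rep_len(c, n)

  loglik <- function(theta) {
    p <- c + (1 - c) * stats::plogis(a * (theta - difficulty))
    sum(correct * log(p) + (1 - correct) * log1p(-p))
  }

  if (all(correct == 1)) return(list(theta_hat = bounds[2], se = Inf))
  if (all(correct == 0)) return(list(theta_hat = bounds[1], se = Inf))

  opt <- stats::optimize(loglik, interval = bounds, maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  theta_hat <- opt$maximum
  h <- 1e-4
  info <- -(loglik(theta_hat + h) - 2 * opt$objective + loglik(theta_hat - h)) / h^2
  at_bound <- min(theta_hat - bounds[1], bounds[2] - theta_hat) < 1e-6
  se <- if (info > 0 && !at_bound) 1 / sqrt(info) else Inf
  list(theta_hat = theta_hat, se = se)
}

#' Select the next staircase item
#'
#' The unadministered item whose *labelled* difficulty is nearest the
#' current ability estimate; ties go to the lowest `item_id`. Selection on
#' the labelled scale is what lets a miscalibrated bank distort sampling:
#' once the estimate sits above every label, the staircase can only serve
#' the hardest-labelled items remaining.
#'
#' @param theta_hat current ability estimate.
#' @param bank a [pvt_bank()].
#' @param administered character vector of already-used `item_id`s.
#' @return A single `item_id`.
#' @export
next_item <- function(theta_hat, bank, administered = character()) {
  cand <- bank[!(bank$item_id %in% administered), , drop = FALSE]
  if (nrow(cand) == 0L) stop("item bank exhausted", call. = FALSE)
  dist <- abs(cand$labelled - theta_hat)
  cand$item_id[order(dist, cand$item_id)][1L]
}

#' Run one adaptive staircase session
#'
#' Starts at the easiest labelled item, then alternates response sampling,
#' ability re-estimation, and nearest-labelled-difficulty item selection.
#' The session stops when at least `min_trials` items have been given and
#' the ability estimate's standard error is below `se_stop`, or at
#' `max_trials`. Items never repeat within a session.
#'
#' @param theta,delta the participant's latent ability and visuo-motor
#'   delay (ms).
#' @param bank a [pvt_bank()].
#' @param config a [sim_config()] list.
#' @return list with `trials` (data.frame `trial_index`, `item_id`, `rt_ms`,
#'   `correct`), `theta_hat`, `se`, `n_trials`.
#' @export
run_session <- function(theta, delta, bank, config = sim_config()) {
  stopifnot(nrow(bank) >= config$max_trials)
  current <- bank$item_id[order(bank$labelled, bank$item_id)][1L]
  administered <- character()
  correct <- integer()
  rt <- numeric()
  theta_hat <- NA_real_
  se <- Inf
  for (k in seq_len(config$max_trials)) {
    row <- bank[bank$item_id == current, , drop = FALSE]
    resp <- sample_response(theta, delta, row, config)
    administered <- c(administered, current)
    correct <- c(correct, resp$correct)
    rt <- c(rt, resp$rt_ms)
    believed <- bank$labelled[match(administered, bank$item_id)]
    est <- mle_theta(correct, believed,
                     a = bank$a[match(administered, bank$item_id)],
                     c = bank$c[match(administered, bank$item_id)],
                     bounds = config$theta_bounds)
    theta_hat <- est$theta_hat
    se <- est$se
    if (k >= config$min_trials && se < config$se_stop) break
    if (k < config$max_trials) current <- next_item(theta_hat, bank, administered)
  }
  list(trials = data.frame(trial_index = seq_along(administered),
                           item_id = administered,
                           rt_ms = rt,
                           correct = correct,
                           stringsAsFactors = FALSE),
       theta_hat = theta_hat, se = se, n_trials = length(administered))
}

#' Simulate an adaptive-task cohort with known latent parameters
#'
#' Draws latent abilities and visuo-motor delays, runs an independent
#' staircase session per participant, and returns the long-format trial
#' table together with the generative truth, for parameter-recovery
#' validation of the decomposition. Reproducibility uses a single master
#' seed: latent parameters and per-participant substream seeds are drawn
#' from it, then each session runs under its own substream, so any one
#' participant's session can be regenerated in isolation.
#'
#' @param n_participants cohort size.
#' @param bank a [pvt_bank()]; default the calibrated 340-item bank.
#' @param config a [sim_config()] list.
#' @param seed master RNG seed (mandatory).
#' @param theta,delta optional latent vectors to reuse (e.g. to generate a
#'   follow-up cohort for the same participants with fresh response noise);
#'   default: drawn from the config's distributions.
#' @param session session label written into the trial table; default
#'   `"baseline"`.
#' @return An object of class `pvt_cohort`: list with `trials`
#'   ([read_trials()] schema), `truth` (data.frame `participant_id`,
#'   `theta`, `delta_ms`, `theta_hat`, `se`, `ab`, `n_trials`, where `ab`
#'   is the terminal ability estimate mapped affinely onto `[0, 1]` over the
#'   search bounds — the task's own summary-score analogue), `bank`,
#'   `config`, `seed`.
#' @export
#' @examples
#' cohort <- simulate_pvt_cohort(5, pvt_bank(n_items = 40), seed = 1)
#' table(cohort$trials$participant_id)
simulate_pvt_cohort <- function(n_participants, bank = pvt_bank(),
                                config = sim_config(), seed,
                                theta = NULL, delta = NULL,
                                session = "baseline") {
  stopifnot(n_participants >= 1L, !missing(seed))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_participants)
  if (is.null(theta)) theta <- stats::rnorm(n_participants, config$theta_mean, config$theta_sd)
  if (is.null(delta)) delta <- stats::rlnorm(n_participants, config$delta_meanlog, config$delta_sdlog)
  stopifnot(length(theta) == n_participants, length(delta) == n_participants)

  ids <- sprintf("p%04d", seq_len(n_participants))
  trials <- vector("list", n_participants)
  theta_hat <- se <- numeric(n_participants)
  n_trials <- integer(n_participants)
  for (i in seq_len(n_participants)) {
    set.seed(sub_seeds[i])
    s <- run_session(theta[i], delta[i], bank, config)
    tr <- s$trials
    tr$participant_id <- ids[i]
    tr$session <- session
    trials[[i]] <- tr[, c("participant_id", "session", "trial_index",
                          "item_id", "rt_ms", "correct")]
    theta_hat[i] <- s$theta_hat
    se[i] <- s$se
    n_trials[i] <- s$n_trials
  }
  lo <- config$theta_bounds[1]; hi <- config$theta_bounds[2]
  structure(
    list(trials = do.call(rbind, trials),
         truth = data.frame(participant_id = ids,
                            theta = theta,
                            delta_ms = delta,
                            theta_hat = theta_hat,
                            se = se,
                            ab = (pmin(pmax(theta_hat, lo), hi) - lo) / (hi - lo),
                            n_trials = n_trials,
                            stringsAsFactors = FALSE),
         bank = bank,
         config = config,
         seed = seed),
    class = "pvt_cohort"
  )
}

#' @export
print.pvt_cohort <- function(x, ...) {
  cat(sprintf("Simulated adaptive-task cohort: %d participants, %d-item bank (%s), seed %d\n",
              nrow(x$truth), nrow(x$bank),
              attr(x$bank, "miscalibration") %||% "none", x$seed))
  cat(sprintf("  %d trial records; session lengths %d-%d\n",
              nrow(x$trials), min(x$truth$n_trials), max(x$truth$n_trials)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
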