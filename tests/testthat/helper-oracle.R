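# Independent brute-force oracles for the fixed-point decomposition.
# Deliberately written record-by-record with scalar loops and dense
# iteration to 1e-12 from multiple starting points, sharing no code with
# the package internals.

oracle_difficulty <- function(trials, rt_max, tol = 1e-12, starts = c(0, 0.5, 1)) {
  items <- sort(unique(trials$item_id))
  sapply(items, function(it) {
    rows <- trials[trials$item_id == it, , drop = FALSE]
    sols <- sapply(starts, function(d0) {
      d <- d0
      for (k in 1:100000) {
        ps <- numeric(nrow(rows))
        for (r in seq_len(nrow(rows))) {
          ps[r] <- if (rows$correct[r] == 1) (1 - rows$rt_ms[r] / rt_max) * d else 0
        }
        d_new <- mean(1 - ps)
        if (abs(d_new - d) < tol) return(d_new)
        d <- d_new
      }
      stop("oracle difficulty did not converge")
    })
    if (diff(range(sols)) > 1e-9) stop("oracle: multiple fixed points for item ", it)
    mean(sols)
  })
}

# closed form of the per-item fixed point d = 1 - c * d
oracle_difficulty_closed <- function(trials, rt_max) {
  items <- sort(unique(trials$item_id))
  sapply(items, function(it) {
    rows <- trials[trials$item_id == it, , drop = FALSE]
    cc <- mean(rows$correct * (1 - rows$rt_ms / rt_max))
    1 / (1 + cc)
  })
}

# dense fixed-point solve of the stage-2 mutual recursion (A, AT, DT) with
# D frozen, from several ability initialisations
oracle_decompose <- function(trials, d_map, rt_max, tol = 1e-12,
                             starts = c(0, 0.5, 1)) {
  pids <- sort(unique(trials$participant_id))
  floor_i <- sapply(pids, function(p) min(trials$rt_ms[trials$participant_id == p]))
  run <- function(a0) {
    a <- stats::setNames(rep(a0, length(pids)), pids)
    for (k in 1:100000) {
      at <- dt <- numeric(nrow(trials))
      for (r in seq_len(nrow(trials))) {
        p <- trials$participant_id[r]
        atn <- (1 - a[[p]]) * d_map[[trials$item_id[r]]]
        at[r] <- atn * (trials$rt_ms[r] - floor_i[[p]])
        dt[r] <- trials$rt_ms[r] - at[r]
      }
      a_new <- sapply(pids, function(p) {
        rows <- which(trials$participant_id == p)
        mean(sapply(rows, function(r) {
          if (trials$correct[r] == 1) {
            (1 - trials$rt_ms[r] / rt_max) * d_map[[trials$item_id[r]]]
          } else 0
        }))
      })
      if (max(abs(a_new - a)) < tol) {
        return(list(ability = a_new, answer_time = at, delay_time = dt))
      }
      a <- stats::setNames(a_new, pids)
    }
    stop("oracle decomposition did not converge")
  }
  sols <- lapply(starts, run)
  for (s in sols[-1]) {
    if (max(abs(s$ability - sols[[1]]$ability)) > 1e-9) {
      stop("oracle: decomposition fixed point not unique")
    }
  }
  sols[[1]]
}

oracle_specific_ability <- function(trials, at, d_map, at_max) {
  pids <- sort(unique(trials$participant_id))
  sapply(pids, function(p) {
    rows <- which(trials$participant_id == p)
    mean(sapply(rows, function(r) {
      if (trials$correct[r] == 1) {
        (1 - at[r] / at_max) * d_map[[trials$item_id[r]]]
      } else 0
    }))
  })
}

# seeded random toy cohort: every participant sees every item `reps` times
make_toy_cohort <- function(n_participants, n_items, seed, reps = 1L,
                            p_correct = 0.6) {
  set.seed(seed)
  grid <- expand.grid(participant_id = sprintf("p%02d", seq_len(n_participants)),
                      item_id = sprintf("w%02d", seq_len(n_items)),
                      rep = seq_len(reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(participant_id = grid$participant_id,
             item_id = grid$item_id,
             rt_ms = stats::runif(nrow(grid), 300, 5000),
             correct = stats::rbinom(nrow(grid), 1, p_correct),
             stringsAsFactors = FALSE)
}

# small simulated cohort shared across tests (lazy, cached per session)
cached_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_pvt_cohort(40, pvt_bank(n_items = 60),
                                    sim_config(), seed = 42)
    }
    cache
  }
})
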