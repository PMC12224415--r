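test_that("trial performance scores speed-weighted difficulty for correct answers only", {
  expect_equal(trial_performance(1234, 0, 0.8, 10000), 0)
  expect_equal(trial_performance(10000, 1, 0.8, 10000), 0)
  expect_equal(trial_performance(5000, 1, 0.6, 10000), 0.3)
  # vectorised, bounded by difficulty
  rt <- seq(1, 10000, length.out = 50)
  p <- trial_performance(rt, 1, 0.7, 10000)
  expect_true(all(p >= 0 & p <= 0.7))
  expect_error(trial_performance(10001, 1, 0.5, 10000), "rt_max")
  expect_error(trial_performance(-5, 1, 0.5, 10000), "rt")
  expect_error(trial_performance(50, 1, 1.2, 10000), "difficulty")
})

test_that("item difficulty converges to its analytic fixed point", {
  # all presentations wrong -> P = 0 always -> D = 1
  wrong <- data.frame(participant_id = sprintf("p%d", 1:4), item_id = "w1",
                      rt_ms = c(900, 1100, 1300, 2000), correct = 0)
  anchor <- data.frame(participant_id = "p1", item_id = "w0",
                       rt_ms = 2000, correct = 1)
  fit <- fit_item_difficulty(rbind(wrong, anchor))
  expect_equal(fit$item_scales$difficulty[fit$item_scales$item_id == "w1"], 1,
               tolerance = 1e-9)

  # all correct at rt_max / 2: fixed point of d = 1 - d/2 is 2/3
  half <- data.frame(participant_id = sprintf("p%d", 1:3), item_id = "w1",
                     rt_ms = 5000, correct = 1)
  cap <- data.frame(participant_id = "p1", item_id = "w0",
                    rt_ms = 10000, correct = 1)
  fit <- fit_item_difficulty(rbind(half, cap))
  d <- fit$item_scales$difficulty[fit$item_scales$item_id == "w1"]
  expect_equal(d, 2 / 3, tolerance = 1e-6)
  # and against the brute-force scalar solver
  expect_equal(d, unname(oracle_difficulty(rbind(half, cap), 10000)[["w1"]]),
               tolerance = 1e-6)

  # all correct with rt near rt_max: P -> 0 so D -> 1
  slow <- data.frame(participant_id = sprintf("p%d", 1:3), item_id = "w1",
                     rt_ms = 9999.99, correct = 1)
  fit <- fit_item_difficulty(rbind(slow, cap))
  expect_equal(fit$item_scales$difficulty[fit$item_scales$item_id == "w1"], 1,
               tolerance = 1e-4)

  expect_error(fit_item_difficulty(data.frame()), "non-empty")
})

test_that("difficulty iteration history is finite and ends under tolerance", {
  tr <- make_toy_cohort(4, 6, seed = 5)
  ctl <- idoct_control(tol = 1e-8)
  fit <- fit_item_difficulty(tr, ctl)
  expect_true(all(is.finite(fit$history$mean_rel_change)))
  expect_lt(tail(fit$history$mean_rel_change, 1), ctl$tol)
  expect_identical(fit$iterations, nrow(fit$history))
  # non-convergence carries the history
  err <- tryCatch(fit_item_difficulty(tr, idoct_control(max_iter_difficulty = 2)),
                  idoct_non_convergence = function(e) e)
  expect_s3_class(err, "idoct_non_convergence")
  expect_identical(nrow(err$history), 2L)
})

test_that("answer-time decomposition matches a dense brute-force fixed point", {
  for (seed in c(2, 3)) {
    tr <- make_toy_cohort(2, 2, seed = seed)
    rt_max <- max(tr$rt_ms)
    s1 <- fit_item_difficulty(tr, idoct_control(tol = 1e-10))
    s2 <- decompose_answer_time(tr, s1$item_scales, rt_max,
                                idoct_control(tol = 1e-10))
    d_map <- setNames(s1$item_scales$difficulty, s1$item_scales$item_id)
    ora <- oracle_decompose(tr[order(tr$participant_id, tr$item_id), ],
                            as.list(d_map), rt_max)
    got <- s2$participants
    expect_equal(got$ability, unname(ora$ability), tolerance = 1e-6)
    ord <- order(tr$participant_id, tr$item_id)
    expect_equal(s2$trial_performance$answer_time[ord],
                 ora$answer_time, tolerance = 1e-6)
    expect_equal(s2$trial_performance$delay_time[ord],
                 ora$delay_time, tolerance = 1e-6)
  }
})

test_that("the trial at a participant's minimum RT is pure delay", {
  tr <- make_toy_cohort(3, 4, seed = 9)
  s1 <- fit_item_difficulty(tr)
  s2 <- decompose_answer_time(tr, s1$item_scales, max(tr$rt_ms))
  tp <- s2$trial_performance
  for (p in unique(tp$participant_id)) {
    rows <- tp[tp$participant_id == p, ]
    at_min <- rows[which.min(rows$rt_ms), ]
    expect_equal(at_min$answer_time, 0)
    expect_equal(at_min$delay_time, at_min$rt_ms)
  }
})

test_that("single-participant single-trial boundary decomposes to pure delay", {
  tr <- data.frame(participant_id = "p1", item_id = "w1",
                   rt_ms = 2500, correct = 1)
  s1 <- fit_item_difficulty(tr)
  # only trial is at rt_max -> P = 0 -> D fixed point is 1
  expect_equal(s1$item_scales$difficulty, 1, tolerance = 1e-9)
  s2 <- decompose_answer_time(tr, s1$item_scales, s1$rt_max)
  expect_equal(s2$trial_performance$answer_time, 0)
  expect_equal(s2$trial_performance$delay_time, 2500)
  # degenerate cohort: every answer time 0 -> no specific-ability scale
  expect_error(idoct(tr), "cannot anchor")
})

test_that("decomposition names missing items", {
  tr <- make_toy_cohort(2, 3, seed = 1)
  scales <- fit_item_difficulty(tr)$item_scales
  expect_error(
    decompose_answer_time(tr, scales[scales$item_id != "w02", ], max(tr$rt_ms)),
    "w02")
})

test_that("specific ability handles its boundary cases", {
  tp <- data.frame(participant_id = c("a", "a", "b", "b"),
                   correct = c(0, 0, 1, 1),
                   answer_time = c(100, 200, 0, 0),
                   difficulty = c(0.5, 0.7, 0.4, 0.8))
  out <- specific_ability(tp, at_max = 500)
  expect_equal(out$specific_ability[out$participant_id == "a"], 0)
  # AT = 0 on all correct trials -> AS = mean difficulty seen
  expect_equal(out$specific_ability[out$participant_id == "b"], 0.6)
  # a correct trial at AT == at_max contributes 0
  tp2 <- data.frame(participant_id = "c", correct = 1,
                    answer_time = 500, difficulty = 0.9)
  expect_equal(specific_ability(tp2, 500)$specific_ability, 0)
  expect_error(specific_ability(tp, 0), "anchor")
})

test_that("participant delay is the arithmetic mean of trial delays", {
  tp <- data.frame(participant_id = c("a", "a", "b"),
                   delay_time = c(1000, 3000, 750))
  out <- participant_delay(tp)
  expect_equal(out$mean_delay_ms, c(2000, 750))
  expect_error(participant_delay(tp[0, ]), "no trials")
})

test_that("scaled difficulty follows the presentee-mean formula", {
  scales <- data.frame(item_id = c("w1", "w2"), difficulty = c(0.5, 0.9),
                       n_presentations = c(2L, 1L))
  scores <- data.frame(participant_id = c("a", "b"),
                       specific_ability = c(0.2, 0.6))
  tr <- data.frame(participant_id = c("a", "b", "b"),
                   item_id = c("w1", "w1", "w2"),
                   rt_ms = c(1000, 1200, 900), correct = c(1, 0, 1))
  out <- scale_difficulty(scales, scores, tr)
  expect_equal(out$scaled_difficulty, c(0.5 * 0.4, 0.9 * 0.6))
  # an item seen by a single participant with AS = 1 keeps DS = D
  scores2 <- data.frame(participant_id = c("a", "b"),
                        specific_ability = c(0.2, 1))
  out2 <- scale_difficulty(scales, scores2, tr)
  expect_equal(out2$scaled_difficulty[2], 0.9)
  # relabeling participants leaves DS unchanged
  tr_rl <- tr; tr_rl$participant_id <- chartr("ab", "zy", tr_rl$participant_id)
  scores_rl <- scores; scores_rl$participant_id <- c("z", "y")
  expect_equal(scale_difficulty(scales, scores_rl, tr_rl)$scaled_difficulty,
               out$scaled_difficulty)
})

test_that("full fit is deterministic and satisfies the score bounds", {
  co <- cached_cohort()
  fit1 <- idoct(co$trials)
  fit2 <- idoct(co$trials)
  expect_identical(fit1$participants, fit2$participants)
  expect_identical(fit1$item_scales, fit2$item_scales)

  with(fit1$item_scales, {
    expect_true(all(difficulty >= 0 & difficulty <= 1))
    expect_true(all(scaled_difficulty >= 0 & scaled_difficulty <= 1))
    expect_true(all(n_presentations >= 1))
  })
  with(fit1$participants, {
    expect_true(all(ability >= 0 & ability <= 1))
    expect_true(all(specific_ability >= 0 & specific_ability <= 1))
    expect_true(all(mean_delay_ms >= 0))
  })
  tp <- fit1$trial_performance
  expect_true(all(tp$answer_time >= 0 & tp$delay_time >= 0))
  floor_map <- setNames(fit1$participants$personal_floor_ms,
                        fit1$participants$participant_id)
  expect_true(all(tp$answer_time <=
                    tp$rt_ms - floor_map[tp$participant_id] + 1e-12))
  expect_true(fit1$rt_max >= max(tp$rt_ms))
  expect_true(fit1$at_max <= fit1$rt_max)
})

test_that("relabeling participants and items and shuffling rows changes no score", {
  co <- cached_cohort()
  tr <- co$trials
  fit <- idoct(tr)

  set.seed(7)
  pmap <- setNames(sprintf("Z%03d", seq_along(unique(tr$participant_id))),
                   sample(unique(tr$participant_id)))
  imap <- setNames(sprintf("Q%03d", seq_along(unique(tr$item_id))),
                   sample(unique(tr$item_id)))
  tr2 <- tr
  tr2$participant_id <- unname(pmap[tr$participant_id])
  tr2$item_id <- unname(imap[tr$item_id])
  set.seed(99)
  tr2 <- tr2[sample(nrow(tr2)), ]
  fit2 <- idoct(tr2)

  orig_p <- setNames(fit$participants$specific_ability,
                     pmap[fit$participants$participant_id])
  expect_equal(fit2$participants$specific_ability,
               unname(orig_p[fit2$participants$participant_id]),
               tolerance = 1e-12)
  orig_d <- setNames(fit$item_scales$scaled_difficulty,
                     imap[fit$item_scales$item_id])
  expect_equal(fit2$item_scales$scaled_difficulty,
               unname(orig_d[fit2$item_scales$item_id]),
               tolerance = 1e-12)
  expect_equal(fit2$at_max, fit$at_max, tolerance = 1e-12)
})

test_that("with frozen inputs, slower or wrong answers strictly lower specific ability", {
  base <- data.frame(participant_id = "a", correct = c(1, 1, 0),
                     answer_time = c(100, 250, 400),
                     difficulty = c(0.5, 0.7, 0.9))
  as0 <- specific_ability(base, at_max = 1000)$specific_ability
  slower <- base; slower$answer_time[2] <- 600
  expect_lt(specific_ability(slower, 1000)$specific_ability, as0)
  flipped <- base; flipped$correct[1] <- 0
  expect_lt(specific_ability(flipped, 1000)$specific_ability, as0)
})
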