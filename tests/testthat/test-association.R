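# seeded synthetic feature matrix with planted linear signal
make_features <- function(n, p_signal = 5, p_noise = 45, seed = 1,
                          beta = 0.5, noise_sd = 1) {
  set.seed(seed)
  p <- p_signal + p_noise
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%04d", seq_len(n)),
                              c(sprintf("signal%02d", seq_len(p_signal)),
                                sprintf("noise%02d", seq_len(p_noise)))))
  y <- as.numeric(x[, seq_len(p_signal), drop = FALSE] %*%
                    rep(beta, p_signal)) + rnorm(n, 0, noise_sd)
  list(x = x, y = setNames(y, rownames(x)))
}

test_that("train/test split is reproducible, disjoint, and exhaustive", {
  ids <- sprintf("s%03d", 1:100)
  sp <- split_train_test(ids, seed = 4)
  expect_identical(length(sp$train), 75L)
  expect_identical(length(sp$test), 25L)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, split_train_test(ids, seed = 4))
  expect_false(identical(sp, split_train_test(ids, seed = 5)))
  expect_error(split_train_test(ids[1:5], seed = 1), "at least 8")
})

test_that("residualisation removes the covariate and matches normal equations", {
  set.seed(6)
  n <- 80
  age <- runif(n, 45, 80)
  # column equal to the covariate vanishes
  expect_equal(residualize(age, age), rep(0, n), tolerance = 1e-10)
  # column orthogonal to the centered covariate is only de-meaned
  v <- rnorm(n)
  v_orth <- residualize(v, age)  # orthogonalise first
  out <- residualize(v_orth, age)
  expect_equal(out, v_orth - mean(v_orth), tolerance = 1e-8)
  # matrix case against the explicit normal-equation solution
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  res <- residualize(x, age)
  Z <- cbind(1, age)
  res_oracle <- x - Z %*% solve(t(Z) %*% Z, t(Z) %*% x)
  expect_equal(res, res_oracle, tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(abs(crossprod(res, age - mean(age)))), 1e-6)
  expect_error(residualize(x, rep(2, n)), "constant")
})

test_that("spearman ranking orders by |rho|, flags constants, and guards leakage", {
  set.seed(11)
  n <- 60
  y <- rnorm(n)
  x <- cbind(self = y, mono = exp(y), noise = rnorm(n), flat = rep(1, n))
  rk <- rank_by_spearman(x, y)
  expect_identical(rk$feature[1:2], c("mono", "self"))  # tied |rho| = 1, by name
  expect_equal(rk$rho[1:2], c(1, 1))
  expect_identical(rk$feature[4], "flat")
  expect_true(rk$undefined[4])
  expect_true(is.na(rk$rho[4]))

  # permuted target: near-zero correlation
  rk2 <- rank_by_spearman(x[, "noise", drop = FALSE], sample(y))
  expect_lt(abs(rk2$rho[1]), 0.35)

  x_test <- x
  attr(x_test, "idoct_split") <- "test"
  expect_error(rank_by_spearman(x_test, y), "training rows only")
})

test_that("stepwise CV recovers planted features and prefers parsimony on ties", {
  d <- make_features(400, seed = 3)
  cv <- stepwise_cv(d$x, d$y, k = 5, seed = 3)
  expect_true(all(sprintf("signal%02d", 1:5) %in% cv$chosen_features))
  expect_identical(nrow(cv$steps), ncol(d$x) - 1L)
  expect_equal(cv$steps$n_features, (ncol(d$x) - 1L):1L)

  # duplicated feature: identical fits at both steps, fewer features win
  set.seed(12)
  z <- rnorm(50)
  x <- cbind(a_dup1 = z, a_dup2 = z, b_noise = rnorm(50))
  y <- z + rnorm(50, 0, 0.1)
  cv2 <- stepwise_cv(x, y, k = 5, seed = 2)
  expect_identical(cv2$chosen_features, "a_dup1")

  # independent target: no apparent validation skill
  set.seed(13)
  y0 <- rnorm(400)
  cv3 <- stepwise_cv(d$x, setNames(y0, names(d$y)), k = 5, seed = 13)
  expect_lte(max(cv3$steps$r2_val_mean), 0.02)
})

test_that("final refit reports train and held-out R-squared honestly", {
  d <- make_features(300, seed = 8)
  sp <- split_train_test(rownames(d$x), seed = 8)
  feats <- sprintf("signal%02d", 1:5)
  fin <- final_fit_eval(d$x[sp$train, ], d$y[sp$train],
                        d$x[sp$test, ], d$y[sp$test], feats)
  expect_gt(fin$r2_test, 0)
  expect_gt(fin$r2_train, fin$r2_test - 0.2)

  # exact linear combination: train R^2 = 1
  y_exact <- as.numeric(d$x[sp$train, feats] %*% rep(1, 5))
  fin2 <- final_fit_eval(d$x[sp$train, ], y_exact,
                         d$x[sp$test, ], d$y[sp$test], feats)
  expect_equal(fin2$r2_train, 1, tolerance = 1e-10)

  # permuted test target: negative R^2 is reported as-is
  set.seed(3)
  fin3 <- final_fit_eval(d$x[sp$train, ], d$y[sp$train],
                         d$x[sp$test, ], sample(d$y[sp$test]), feats)
  expect_true(is.finite(fin3$r2_test) && fin3$r2_test <= 1)

  # collinear design errors with the offending feature named
  xc <- cbind(d$x, signal01_copy = d$x[, "signal01"])
  expect_error(final_fit_eval(xc[sp$train, ], d$y[sp$train],
                              xc[sp$test, ], d$y[sp$test],
                              c(feats, "signal01_copy")),
               "signal01_copy")
})

test_that("eta-squared matches the sequential ANOVA decomposition", {
  set.seed(14)
  n <- 120
  df <- data.frame(y = rnorm(n), f1 = rnorm(n), f2 = rnorm(n))
  df$y <- 0.8 * df$f1 + 0.4 * df$f2 + rnorm(n)
  m1 <- lm(y ~ f1, df)
  expect_equal(unname(eta_squared(m1)), summary(m1)$r.squared, ignore_attr = TRUE)

  # correlated features: compare against stats::anova type-I sums of squares
  df$f3 <- 0.6 * df$f1 + rnorm(n)
  m3 <- lm(y ~ f1 + f3 + f2, df)
  eta <- eta_squared(m3)
  a <- anova(m3)
  ss_tot <- sum(a[["Sum Sq"]])
  expect_equal(unname(eta), a[["Sum Sq"]][1:3] / ss_tot, ignore_attr = TRUE)
  expect_equal(sum(eta), summary(m3)$r.squared)
  expect_equal(attr(eta, "residual"), 1 - summary(m3)$r.squared)
  expect_true(all(eta >= 0 & eta <= 1))
})

test_that("the full selection pipeline is reproducible and reports top features", {
  d <- make_features(500, seed = 9)
  age <- setNames(runif(500, 45, 80), rownames(d$x))
  sel1 <- select_features(d$x, d$y, covariate = age, seed = 9)
  sel2 <- select_features(d$x, d$y, covariate = age, seed = 9)
  expect_identical(sel1$chosen_features, sel2$chosen_features)
  expect_identical(sel1$r2_test, sel2$r2_test)
  expect_true(all(sprintf("signal%02d", 1:5) %in% sel1$chosen_features))

  tf <- top_features(sel1, k = 5, mode = "multivariate")
  expect_true(all(grepl("^signal", tf)))
  tfu <- top_features(sel1, k = 5, mode = "univariate")
  expect_true(all(grepl("^signal", tfu)))
  big <- top_features(sel1, k = 500, mode = "univariate")
  expect_true(attr(big, "short"))
})

test_that("signal planted only in held-out rows is not selected", {
  set.seed(15)
  n <- 400
  x <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(sprintf("s%04d", 1:n),
                              sprintf("f%02d", 1:20)))
  sp <- split_train_test(rownames(x), seed = 15)
  y <- setNames(rnorm(n), rownames(x))
  # adversarial: the target equals feature f01 on the test rows only
  y[sp$test] <- 3 * x[sp$test, "f01"] + rnorm(length(sp$test), 0, 0.2)
  sel <- select_features(x, y, seed = 15)
  rk <- sel$ranking
  expect_gt(rk$rank[rk$feature == "f01"], 3)
  expect_lt(sel$r2_test, 0.2)
})
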