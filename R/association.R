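#' Reproducible train/held-out split of participant ids
#'
#' @param ids vector of participant ids (`>= 8`).
#' @param fraction train fraction; default 0.75.
#' @param seed RNG seed.
#' @return list with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
split_train_test <- function(ids, fraction = 0.75, seed) {
  stopifnot(!missing(seed), fraction > 0, fraction < 1)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("'ids' must be unique", call. = FALSE)
  if (length(ids) < 8L) stop("need at least 8 participants to split", call. = FALSE)
  n_train <- round(fraction * length(ids))
  train <- withr_seed(seed, sample(ids, n_train))
  list(train = sort(train), test = sort(setdiff(ids, train)))
}

# tag a matrix with the split role it holds; rank_by_spearman refuses
# anything flagged as containing held-out rows (leakage guard)
flag_split <- function(x, role) {
  attr(x, "idoct_split") <- role
  x
}

#' Regress a covariate out of each column
#'
#' Ordinary least-squares residuals of each column of `x` on an intercept
#' plus `covariate` (the "age-residualisation" step of the association
#' pipeline). Residuals are orthogonal to the centred covariate.
#'
#' @param x numeric vector or matrix (rows = participants).
#' @param covariate finite, non-constant numeric vector.
#' @return Residuals with the shape of `x`.
#' @export
residualize <- function(x, covariate) {
  vec <- is.null(dim(x))
  xm <- as.matrix(x)
  stopifnot(nrow(xm) == length(covariate))
  if (any(!is.finite(covariate))) stop("'covariate' must be finite", call. = FALSE)
  if (stats::sd(covariate) == 0) stop("'covariate' is constant", call. = FALSE)
  res <- stats::lm.fit(cbind(1, covariate), xm)$residuals
  if (vec) as.numeric(res) else {
    res <- as.matrix(res)
    dimnames(res) <- dimnames(xm)
    res
  }
}

#' Rank features by the magnitude of their Spearman correlation
#'
#' Bivariate Spearman correlation of every feature with the target,
#' computed on training rows only; features are ordered by descending
#' `|rho|`, ties broken by feature name. Constant features have no defined
#' correlation: they are ranked last and flagged rather than failing the
#' run. A matrix flagged as holding held-out rows is refused, to make
#' train/test leakage a hard error rather than a silent mistake.
#'
#' @param x numeric feature matrix (participants x features, named
#'   columns).
#' @param target numeric target vector.
#' @return data.frame `feature`, `rho`, `rank`, `undefined`.
#' @export
rank_by_spearman <- function(x, target) {
  role <- attr(x, "idoct_split")
  if (!is.null(role) && !identical(role, "train")) {
    stop("refusing to rank features on a matrix flagged as '", role,
         "': ranking must see training rows only", call. = FALSE)
  }
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(target), !is.null(colnames(x)))
  if (anyDuplicated(colnames(x))) stop("feature names must be unique", call. = FALSE)
  const <- apply(x, 2L, function(col) stats::sd(col) == 0)
  rho <- rep(NA_real_, ncol(x))
  rho[!const] <- suppressWarnings(
    as.numeric(stats::cor(x[, !const, drop = FALSE], target, method = "spearman"))
  )
  # descending |rho|, ties by name; constant features sink to the bottom
  key <- ifelse(const, -Inf, abs(rho))
  ord <- order(-key, colnames(x), method = "radix")
  data.frame(feature = colnames(x)[ord],
             rho = rho[ord],
             rank = seq_len(ncol(x)),
             undefined = const[ord],
             stringsAsFactors = FALSE)
}

# out-of-sample R^2: 1 - SS_res / SS_tot about the evaluation set's mean
r_squared <- function(y, yhat) 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)

# seeded plain-random fold assignment, identical across all nested models
make_folds <- function(n, k, seed) {
  stopifnot(k >= 2L, n >= k)
  withr_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Drop-lowest stepwise model search under cross-validation
#'
#' Given features ranked by correlation magnitude, evaluates the nested
#' sequence of linear models obtained by repeatedly removing the
#' lowest-ranked remaining feature — from all-but-the-lowest down to the
#' single top feature — by k-fold cross-validation with the *same* folds
#' for every model. The chosen step is the one with the highest mean
#' validation R-squared; ties go to the model with fewer features
#' (parsimony).
#'
#' @param x training feature matrix (named columns).
#' @param target training target vector.
#' @param ranking optional data.frame from [rank_by_spearman()]; computed
#'   from `x`/`target` if missing. Features flagged `undefined` are never
#'   entered.
#' @param k number of folds; default 5.
#' @param seed RNG seed for fold assignment.
#' @return An object of class `stepwise_cv`: list with `steps` (data.frame
#'   `step`, `n_features`, `r2_train_mean`, `r2_val_mean`, `r2_val_sd`),
#'   `chosen_step`, `chosen_features`, `ranking`, `k`, `seed`.
#' @export
stepwise_cv <- function(x, target, ranking = NULL, k = 5L, seed) {
  stopifnot(!missing(seed))
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n == length(target))
  if (n < k) stop("too few rows for ", k, "-fold cross-validation", call. = FALSE)
  if (is.null(ranking)) ranking <- rank_by_spearman(x, target)
  usable <- ranking$feature[!ranking$undefined]
  p <- length(usable)
  if (p < 2L) stop("need at least 2 usable features", call. = FALSE)

  folds <- make_folds(n, k, seed)
  # step s keeps the top (p - s) ranked features, s = 1 .. p-1
  sizes <- (p - 1L):1L
  r2_train_mean <- r2_val_mean <- r2_val_sd <- numeric(length(sizes))
  for (si in seq_along(sizes)) {
    feats <- usable[seq_len(sizes[si])]
    xt <- cbind(`(Intercept)` = 1, x[, feats, drop = FALSE])
    r2v <- r2t <- numeric(k)
    for (f in seq_len(k)) {
      in_val <- folds == f
      fit <- stats::lm.fit(xt[!in_val, , drop = FALSE], target[!in_val])
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      r2t[f] <- r_squared(target[!in_val], xt[!in_val, , drop = FALSE] %*% beta)
      r2v[f] <- r_squared(target[in_val], xt[in_val, , drop = FALSE] %*% beta)
    }
    r2_train_mean[si] <- mean(r2t)
    r2_val_mean[si] <- mean(r2v)
    r2_val_sd[si] <- stats::sd(r2v)
  }
  steps <- data.frame(step = seq_along(sizes) - 1L,
                      n_features = sizes,
                      r2_train_mean = r2_train_mean,
                      r2_val_mean = r2_val_mean,
                      r2_val_sd = r2_val_sd)
  # highest mean validation R^2; among ties, fewest features
  best <- steps[order(-steps$r2_val_mean, steps$n_features), ][1L, ]
  structure(
    list(steps = steps,
         chosen_step = best$step,
         chosen_features = usable[seq_len(best$n_features)],
         ranking = ranking,
         k = as.integer(k),
         seed = seed),
    class = "stepwise_cv"
  )
}

#' Refit on the full training set and evaluate on held-out data
#'
#' Ordinary least squares on the chosen features over all training rows,
#' with R-squared reported on both the training and the held-out test set.
#' A negative test R-squared is reported as-is.
#'
#' @param train_x,train_y,test_x,test_y matrices/targets for the two
#'   splits.
#' @param features character vector of chosen feature names, present in
#'   both matrices.
#' @return list with `r2_train`, `r2_test`, `coefficients`, `model` (the
#'   `lm` fit).
#' @export
final_fit_eval <- function(train_x, train_y, test_x, test_y, features) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  stopifnot(all(features %in% colnames(train_x)),
            all(features %in% colnames(test_x)))
  df <- data.frame(.target = train_y, train_x[, features, drop = FALSE],
                   check.names = FALSE)
  model <- stats::lm(.target ~ ., data = df)
  beta <- stats::coef(model)
  if (anyNA(beta)) {
    stop("rank-deficient design; collinear feature(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  }
  pred_train <- as.numeric(cbind(1, train_x[, features, drop = FALSE]) %*% beta)
  pred_test <- as.numeric(cbind(1, test_x[, features, drop = FALSE]) %*% beta)
  list(r2_train = r_squared(train_y, pred_train),
       r2_test = r_squared(test_y, pred_test),
       coefficients = beta,
       model = model)
}

#' Per-feature eta-squared from a fitted linear model
#'
#' Effect sizes `SS_effect / SS_total` under a sequential (type-I) ANOVA
#' decomposition in the model's term order: `SS_effect` for term `j` is the
#' drop in residual sum of squares when the term enters after terms
#' `1..j-1`, and `SS_total` is the total sum of squares about the mean
#' (effects + residual). Each value lies in `[0, 1]` and the values sum to
#' the model R-squared.
#'
#' @param model an `lm` fit with at least one non-intercept term.
#' @return Named numeric vector of eta-squared values, with the residual
#'   fraction in `attr(, "residual")`.
#' @export
eta_squared <- function(model) {
  stopifnot(inherits(model, "lm"))
  mf <- stats::model.frame(model)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(model)
  terms_ <- attr(stats::terms(model), "term.labels")
  if (length(terms_) == 0L) stop("model has no non-intercept terms", call. = FALSE)
  assign_ <- attr(X, "assign")
  ss_total <- sum((y - mean(y))^2)
  if (ss_total == 0) stop("degenerate model: constant response", call. = FALSE)
  rss_prev <- ss_total
  eta <- numeric(length(terms_))
  for (j in seq_along(terms_)) {
    cols <- which(assign_ <= j)
    rss_j <- sum(stats::lm.fit(X[, cols, drop = FALSE], y)$residuals^2)
    eta[j] <- (rss_prev - rss_j) / ss_total
    rss_prev <- rss_j
  }
  structure(stats::setNames(eta, terms_), residual = rss_prev / ss_total)
}

#' Full feature-selection pipeline
#'
#' Runs the complete association machine on a feature matrix and target:
#' train/held-out split, optional covariate residualisation (fitted on all
#' rows of each vector, as a fixed preprocessing step), Spearman ranking on
#' the training rows, drop-lowest stepwise search under k-fold
#' cross-validation, refit of the chosen model on the full training set,
#' held-out evaluation, sequential eta-squared attribution, per-coefficient
#' significance, and univariate Pearson correlations for the univariate
#' feature view.
#'
#' @param x numeric feature matrix with participant ids as rownames.
#' @param target named numeric target vector (names = participant ids).
#' @param covariate optional named numeric covariate (e.g. age) to regress
#'   out of every feature column and the target.
#' @param fraction train fraction; default 0.75.
#' @param k folds; default 5.
#' @param seed RNG seed driving split and folds.
#' @param alpha significance level for feature flagging; default 0.05.
#' @return An object of class `feature_selection`: list with `split`,
#'   `ranking`, `cv` (the [stepwise_cv()] object), `chosen_features`,
#'   `r2_train`, `r2_test`, `coefficients`, `eta_squared`, `p_values`
#'   (per-coefficient), `pearson` (univariate r and p on train), `alpha`,
#'   `seed`.
#' @export
select_features <- function(x, target, covariate = NULL,
                            fraction = 0.75, k = 5L, seed, alpha = 0.05) {
  stopifnot(!missing(seed))
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(names(target))) {
    stop("'x' needs participant rownames and 'target' needs matching names", call. = FALSE)
  }
  ids <- intersect(rownames(x), names(target))
  x <- x[ids, , drop = FALSE]
  target <- target[ids]
  if (anyNA(x) || anyNA(target)) stop("missing values are not allowed", call. = FALSE)

  if (!is.null(covariate)) {
    covariate <- covariate[ids]
    x <- residualize(x, covariate)
    target <- stats::setNames(residualize(target, covariate), ids)
  }

  split <- split_train_test(ids, fraction, seed)
  xtr <- flag_split(x[split$train, , drop = FALSE], "train")
  xte <- flag_split(x[split$test, , drop = FALSE], "test")
  ytr <- target[split$train]
  yte <- target[split$test]

  ranking <- rank_by_spearman(xtr, ytr)
  cv <- stepwise_cv(xtr, ytr, ranking = ranking, k = k, seed = seed)
  fit <- final_fit_eval(xtr, ytr, xte, yte, cv$chosen_features)

  sm <- summary(fit$model)$coefficients
  pvals <- sm[setdiff(rownames(sm), "(Intercept)"), "Pr(>|t|)"]
  names(pvals) <- setdiff(rownames(sm), "(Intercept)")

  pearson <- do.call(rbind, lapply(colnames(xtr), function(f) {
    ct <- suppressWarnings(stats::cor.test(xtr[, f], ytr))
    data.frame(feature = f, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))

  structure(
    list(split = split,
         ranking = ranking,
         cv = cv,
         chosen_features = cv$chosen_features,
         r2_train = fit$r2_train,
         r2_test = fit$r2_test,
         coefficients = fit$coefficients,
         eta_squared = eta_squared(fit$model),
         p_values = pvals,
         pearson = pearson,
         alpha = alpha,
         seed = seed),
    class = "feature_selection"
  )
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("Stepwise feature selection under cross-validation\n")
  cat(sprintf("  %d train / %d test participants; %d-fold CV; seed %d\n",
              length(x$split$train), length(x$split$test), x$cv$k, x$seed))
  cat(sprintf("  chosen model: %d feature(s); train R^2 = %.4f, held-out R^2 = %.4f\n",
              length(x$chosen_features), x$r2_train, x$r2_test))
  invisible(x)
}

#' Top features of a selection result
#'
#' `"multivariate"` mode ranks the significant chosen features (per-
#' coefficient t-test at `alpha`) by their eta-squared; `"univariate"` mode
#' ranks all features by the magnitude of their univariate Pearson
#' correlation on the training rows, keeping significant ones. If fewer
#' than `k` features qualify, all of them are returned with
#' `attr(, "short") = TRUE`.
#'
#' @param result a `feature_selection` object.
#' @param k number of features to return; default 15.
#' @param mode `"multivariate"` or `"univariate"`.
#' @param alpha significance level; defaults to the result's.
#' @return Character vector of feature names, best first.
#' @export
top_features <- function(result, k = 15L,
                         mode = c("multivariate", "univariate"),
                         alpha = NULL) {
  stopifnot(inherits(result, "feature_selection"))
  mode <- match.arg(mode)
  if (is.null(alpha)) alpha <- result$alpha
  if (mode == "multivariate") {
    eta <- result$eta_squared
    # coefficient names are backtick-free copies of the term labels
    sig <- names(result$p_values)[result$p_values < alpha]
    sig <- intersect(names(eta), gsub("`", "", sig))
    ranked <- sig[order(-eta[sig])]
  } else {
    pe <- result$pearson
    pe <- pe[pe$p < alpha, , drop = FALSE]
    ranked <- pe$feature[order(-abs(pe$r))]
  }
  out <- utils::head(ranked, k)
  attr(out, "short") <- length(ranked) < k
  out
}
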