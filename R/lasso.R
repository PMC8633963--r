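# Cross-validated LASSO-logistic fits, bootstrap sign-stability
# selection, and the per-drug propensity / remission model wrappers.
#
# glmnet does the penalized fitting; the selection logic around it
# (stratified folds, one-standard-error rule bookkeeping, 40-resample
# sign agreement, forced covariates, unpenalized refit) lives here.

make_stratified_folds <- function(y, folds) {
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  foldid
}

#' Cross-validated LASSO logistic regression
#'
#' Fits a LASSO-penalized logistic regression over a 100-point penalty
#' grid (log-spaced down to `1e-3` of the smallest penalty with an empty
#' support) with stratified K-fold cross-validation on binomial deviance,
#' and selects the penalty by the one-standard-error rule (default) or
#' the CV minimum.  Binary predictors share a scale, so columns are not
#' standardized by default.
#'
#' @param X numeric or sparse predictor matrix (column names required).
#' @param y binary outcome (0/1 or logical).
#' @param folds number of CV folds.
#' @param rule `"1se"` (largest penalty within one standard error of the
#'   CV minimum) or `"min"`.
#' @param seed integer seed controlling fold assignment.
#' @param penalty.factor per-column penalty multipliers (0 = always in).
#' @param standardize standardize columns before penalization.
#' @param thresh coordinate-descent convergence threshold; `1e-5` is
#'   accurate to well below the penalty grid's resolution for binary
#'   designs and roughly halves the fit time of the default.
#' @return a `cv_lasso`: list with the `cv.glmnet` fit, `lambda_path`,
#'   `cv_mean`, `cv_se`, `lambda_min`, `lambda_1se`, chosen `lambda`,
#'   `coefficients` (named, incl. intercept) at the chosen penalty, and
#'   `rule`.
#' @export
fit_cv_lasso <- function(X, y, folds = 5L, rule = c("1se", "min"), seed = 1L,
                         penalty.factor = rep(1, ncol(X)),
                         standardize = FALSE, thresh = 1e-5) {
  rule <- match.arg(rule)
  if (is.matrix(X)) X <- Matrix::Matrix(X, sparse = TRUE)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stopf("estimation error: outcome has a single class; cannot fit")
  if (min(table(y)) < folds)
    stopf("estimation error: too few cases in the rarer class for %d folds", folds)
  set.seed(seed)
  foldid <- make_stratified_folds(y, folds)
  cvfit <- glmnet::cv.glmnet(
    X, y, family = "binomial", foldid = foldid,
    standardize = standardize, penalty.factor = penalty.factor,
    nlambda = 100L, lambda.min.ratio = 1e-3,
    type.measure = "deviance", thresh = thresh
  )
  lam <- if (rule == "1se") cvfit$lambda.1se else cvfit$lambda.min
  beta <- as.numeric(coef(cvfit, s = lam))
  names(beta) <- rownames(coef(cvfit, s = lam))
  structure(list(
    fit = cvfit,
    lambda_path = cvfit$lambda,
    cv_mean = cvfit$cvm, cv_se = cvfit$cvsd,
    lambda_min = cvfit$lambda.min, lambda_1se = cvfit$lambda.1se,
    lambda = lam, rule = rule,
    coefficients = beta
  ), class = "cv_lasso")
}

#' @export
print.cv_lasso <- function(x, ...) {
  nz <- sum(x$coefficients[-1L] != 0)
  cat(sprintf("cv_lasso: rule=%s lambda=%.5g, %d non-zero coefficient(s)\n",
              x$rule, x$lambda, nz))
  invisible(x)
}

# Unpenalized logistic refit with a tiny-ridge fallback when the data are
# (quasi-)separated or the IRLS fit fails to converge.
final_refit <- function(X, y, kept) {
  if (!length(kept)) {
    g <- glm(y ~ 1, family = binomial())
    return(stats::setNames(coef(g), "(Intercept)"))
  }
  Xk <- as.matrix(X[, kept, drop = FALSE])
  sep <- FALSE
  g <- withCallingHandlers(
    glm(y ~ Xk, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (!sep && g$converged) {
    beta <- coef(g)
    names(beta) <- c("(Intercept)", kept)
    beta[is.na(beta)] <- 0
    return(beta)
  }
  rg <- glmnet::glmnet(Xk, y, family = "binomial", alpha = 0,
                       lambda = 1e-4, standardize = FALSE)
  beta <- as.numeric(coef(rg))
  stats::setNames(beta, c("(Intercept)", kept))
}

#' Bootstrap sign-stability selection
#'
#' Fits [fit_cv_lasso()] on `B` bootstrap resamples (rows drawn with
#' replacement, original size) and keeps the predictors whose coefficient
#' is non-zero *with the same sign* in at least `ceiling(stability * B)`
#' of the resamples (38 of 40 at the defaults).  Forced covariates are
#' always appended.  A final unpenalized logistic model on the kept
#' predictors provides the reported coefficients, and a full-data LASSO
#' fit provides the importance scores (absolute final LASSO coefficient).
#'
#' @inheritParams fit_cv_lasso
#' @param B number of bootstrap resamples.
#' @param stability required sign-agreement fraction in (0, 1].
#' @param forced column names always included (e.g. age, gender).
#' @param target optional label describing what is being modeled.
#' @return a `robust_feature_set`: list with `target`, `features` (kept,
#'   non-forced), `signs`, `stability` (agreement fraction per kept
#'   feature), `forced`, `final_coefs` (refit, incl. intercept),
#'   `importance` (named |final LASSO coefficient|), `B`,
#'   `stability_threshold`, and the full-data `cv_lasso` as `full_fit`.
#' @export
bootstrap_stability <- function(X, y, B = 40L, stability = 0.95, seed = 1L,
                                folds = 5L, rule = "1se",
                                forced = character(0), target = "outcome") {
  B <- check_count(B, "B")
  if (!is.numeric(stability) || stability <= 0 || stability > 1)
    stopf("validation error: 'stability' must be in (0, 1]")
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stopf("estimation error: outcome has a single class; cannot fit")
  if (is.null(colnames(X))) stopf("X must have column names")
  forced <- intersect(forced, colnames(X))
  pf <- as.numeric(!(colnames(X) %in% forced))  # forced cols unpenalized
  n <- nrow(X)
  p <- ncol(X)
  signs <- matrix(0L, nrow = B, ncol = p, dimnames = list(NULL, colnames(X)))
  set.seed(seed)
  boot_seeds <- sample.int(.Machine$integer.max, B)
  for (b in seq_len(B)) {
    set.seed(boot_seeds[b])
    for (try in 1:25) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2L && min(table(y[idx])) >= folds) break
    }
    fb <- fit_cv_lasso(X[idx, , drop = FALSE], y[idx], folds = folds,
                       rule = rule, seed = boot_seeds[b], penalty.factor = pf)
    signs[b, ] <- sign(fb$coefficients[-1L])
  }
  need <- ceiling(stability * B)
  pos <- colSums(signs > 0)
  neg <- colSums(signs < 0)
  stable <- (pos >= need) | (neg >= need)
  kept <- setdiff(colnames(X)[stable], forced)
  sign_kept <- ifelse(pos[kept] >= need, 1L, -1L)
  frac_kept <- pmax(pos[kept], neg[kept]) / B

  full <- fit_cv_lasso(X, y, folds = folds, rule = rule,
                       seed = child_seed(seed, 7L), penalty.factor = pf)
  importance <- abs(full$coefficients[-1L])
  keep_all <- c(forced, kept)
  final <- final_refit(X, y, keep_all)
  structure(list(
    target = target,
    features = kept,
    signs = sign_kept,
    stability = frac_kept,
    forced = forced,
    final_coefs = final,
    importance = importance[keep_all],
    B = B, stability_threshold = stability, need = need,
    full_fit = full
  ), class = "robust_feature_set")
}

#' @export
print.robust_feature_set <- function(x, ...) {
  cat(sprintf("robust_feature_set [%s]: %d sign-stable + %d forced predictors (>=%d/%d agreement)\n",
              x$target, length(x$features), length(x$forced), x$need, x$B))
  invisible(x)
}

# Assemble the model design: forced demographic covariates (numeric age,
# gender indicator) in front of the screened binary predictor columns.
model_design <- function(features, episodes, members, K, y) {
  scr <- safe_screen(features, y, K = K)
  X <- features$X[, scr$kept_columns, drop = FALSE]
  mem <- as.data.table(members)
  idx <- match(as.data.table(episodes)$patient_id, mem$patient_id)
  demo <- cbind(age = mem$age[idx],
                gender = as.numeric(mem$gender[idx] == "F"))
  Xm <- cbind(Matrix::Matrix(demo, sparse = TRUE), X)
  colnames(Xm) <- c("age", "gender", colnames(X))
  list(X = Xm, screen = scr)
}

#' Per-drug propensity model: who gets this antidepressant?
#'
#' One-vs-rest robust selection over all episodes: the outcome is 1 when
#' the episode's treatment is `drug`, 0 otherwise.  Predictors are
#' screened to `K` per model before selection; age and gender are always
#' included.
#'
#' @param features a `feature_matrix` from [build_features()].
#' @param episodes labeled episode table aligned with `features` rows.
#' @param members member table supplying age and gender.
#' @param drug treatment label to model.
#' @param K screening size.
#' @inheritParams bootstrap_stability
#' @return a `robust_feature_set` (target `propensity(<drug>)`).
#' @export
fit_propensity <- function(features, episodes, members, drug, K = 1000L,
                           B = 40L, stability = 0.95, folds = 5L, seed = 1L) {
  episodes <- as.data.table(episodes)
  y <- as.integer(episodes$drug_label == drug)
  if (sum(y) < 2L || sum(1L - y) < 2L)
    stopf("estimation error: fewer than 2 episodes of '%s' or of the complement", drug)
  d <- model_design(features, episodes, members, K, y)
  rfs <- bootstrap_stability(d$X, y, B = B, stability = stability,
                             seed = seed, folds = folds,
                             forced = c("age", "gender"),
                             target = sprintf("propensity(%s)", drug))
  rfs$screen <- d$screen
  rfs
}

#' Per-drug remission model among recipients
#'
#' Restricts to episodes treated with `drug` and models remission from
#' the screened history predictors, with the same robust-selection
#' settings as the propensity model.
#'
#' @inheritParams fit_propensity
#' @return a `robust_feature_set` (target `remission(<drug>)`).
#' @export
fit_remission <- function(features, episodes, members, drug, K = 1000L,
                          B = 40L, stability = 0.95, folds = 5L, seed = 1L) {
  episodes <- as.data.table(episodes)
  sel <- which(episodes$drug_label == drug)
  y <- as.integer(episodes$remission[sel])
  if (sum(y) < 2L || sum(1L - y) < 2L)
    stopf("estimation error: degenerate remission outcome for '%s'", drug)
  sub <- structure(list(X = features$X[sel, , drop = FALSE],
                        meta = features$meta, window = features$window),
                   class = "feature_matrix")
  d <- model_design(sub, episodes[sel], members, K, y)
  rfs <- bootstrap_stability(d$X, y, B = B, stability = stability,
                             seed = seed, folds = folds,
                             forced = c("age", "gender"),
                             target = sprintf("remission(%s)", drug))
  rfs$screen <- d$screen
  rfs$rows <- sel
  rfs
}

#' Area under the ROC curve by the rank statistic
#'
#' `aroc()` computes the Mann-Whitney form of the AUC from scores and a
#' binary outcome.  `evaluate_aroc()` refits the robust set's final
#' logistic model under a 10% holdout or K-fold cross-validation scheme
#' and returns the out-of-sample AROC.
#'
#' @param scores numeric risk scores.
#' @param y binary outcome.
#' @return AROC in \[0, 1\].
#' @export
aroc <- function(scores, y) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stopf("estimation error: AROC undefined for a single-class outcome")
  r <- rank(scores, ties.method = "average")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname aroc
#' @param rfs a `robust_feature_set`.
#' @param X design matrix containing the set's kept columns.
#' @param scheme `"holdout"` (10% test split) or `"cv"` (K-fold,
#'   out-of-fold scores pooled).
#' @param folds folds for the CV scheme.
#' @param holdout_frac test fraction for the holdout scheme.
#' @param seed split seed.
#' @export
evaluate_aroc <- function(rfs, X, y, scheme = c("holdout", "cv"),
                          folds = 5L, holdout_frac = 0.1, seed = 1L) {
  scheme <- match.arg(scheme)
  y <- as.integer(y)
  keep <- c(rfs$forced, rfs$features)
  missing_cols <- setdiff(keep, colnames(X))
  if (length(missing_cols))
    stopf("prediction error: design lacks columns: %s",
          paste(missing_cols, collapse = ", "))
  Xk <- as.matrix(X[, keep, drop = FALSE])
  set.seed(seed)
  score_lp <- function(beta, M) drop(cbind(1, M) %*% beta)
  if (scheme == "holdout") {
    n <- length(y)
    test <- sample.int(n, max(1L, round(holdout_frac * n)))
    beta <- final_refit(Xk[-test, , drop = FALSE], y[-test], keep)
    aroc(score_lp(beta, Xk[test, , drop = FALSE]), y[test])
  } else {
    foldid <- make_stratified_folds(y, folds)
    sc <- numeric(length(y))
    for (f in seq_len(folds)) {
      tr <- foldid != f
      beta <- final_refit(Xk[tr, , drop = FALSE], y[tr], keep)
      sc[!tr] <- score_lp(beta, Xk[!tr, , drop = FALSE])
    }
    aroc(sc, y)
  }
}
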