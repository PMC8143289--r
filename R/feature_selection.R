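# Reduction of the 84 radiomic features to one uncorrelated, maximally
# discriminant feature couple: min-max + z-score normalization, LASSO
# (10-fold CV, minimum-deviance rule), |Pearson rho| < 0.15 pair filter,
# Wilcoxon rank-sum per couple with Holm-Bonferroni correction.

#' Normalize and standardize a feature matrix
#'
#' Per feature: min-max scaling to `[0, 1]` followed by z-scoring. Both
#' sets of parameters are learned on the training rows only and applied
#' unchanged to the remaining rows, so no test information leaks into the
#' transform. Features constant on the training rows are dropped with a
#' warning.
#'
#' @param X Numeric matrix (patients x features) with column names.
#' @param train_idx Indices (or logical vector) of training rows;
#'   defaults to all rows.
#' @return List with `X` (transformed matrix, possibly fewer columns) and
#'   `params` (per-feature min, max, mean and SD of the scaled training
#'   values; SD is the sample standard deviation).
#' @export
normalize_standardize <- function(X, train_idx = seq_len(nrow(X))) {
  Xtr <- X[train_idx, , drop = FALSE]
  if (nrow(Xtr) < 2L)
    abort("need at least two training rows", "config_error")
  mins <- apply(Xtr, 2, min)
  maxs <- apply(Xtr, 2, max)
  keep <- maxs > mins
  if (!all(keep)) {
    warning(sprintf("dropping %d constant feature(s): %s", sum(!keep),
                    paste(colnames(X)[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
    mins <- mins[keep]; maxs <- maxs[keep]
  }
  Xs <- sweep(sweep(X, 2, mins), 2, maxs - mins, "/")
  mu <- colMeans(Xs[train_idx, , drop = FALSE])
  sd_ <- apply(Xs[train_idx, , drop = FALSE], 2, stats::sd)
  degenerate <- sd_ <= 0
  if (any(degenerate))
    abort("zero-variance feature after scaling", "config_error")
  Xz <- sweep(sweep(Xs, 2, mu), 2, sd_, "/")
  list(X = Xz,
       params = data.frame(feature = colnames(X), min = mins, max = maxs,
                           scaled_mean = mu, scaled_sd = sd_,
                           row.names = NULL, stringsAsFactors = FALSE))
}

#' Apply stored normalization parameters to new rows
#'
#' @param X Numeric matrix with (at least) the features in `params`.
#' @param params The `params` data frame from [normalize_standardize()].
#' @return Transformed matrix restricted to the parameterized features.
#' @export
apply_normalization <- function(X, params) {
  X <- X[, params$feature, drop = FALSE]
  Xs <- sweep(sweep(X, 2, params$min), 2, params$max - params$min, "/")
  sweep(sweep(Xs, 2, params$scaled_mean), 2, params$scaled_sd, "/")
}

# Stratified fold ids: shuffles within each class, then deals fold labels
# round-robin so class proportions are as equal as the counts allow.
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    members <- sample(which(y == cl))
    fold[members] <- rep_len(seq_len(n_folds), length(members))
  }
  fold
}

#' Rank features by L1-penalized logistic regression
#'
#' Fits a LASSO logistic regression over a 100-value log-spaced lambda
#' grid (down to `1e-4 * lambda_max`), picks the lambda minimizing the
#' mean cross-validated binomial deviance over seeded stratified folds,
#' and returns the nonzero coefficients at that lambda ranked by absolute
#' value, largest first.
#'
#' @param X Standardized feature matrix (training rows).
#' @param y Binary 0/1 labels.
#' @param n_folds CV folds (default 10); reduced with a warning when a
#'   class has fewer members than folds.
#' @param seed Integer seed for the fold assignment.
#' @return Named numeric vector of nonzero coefficients (may be empty).
#' @export
lasso_rank <- function(X, y, n_folds = 10, seed = 1) {
  if (!all(y %in% c(0, 1)) || length(unique(y)) != 2L)
    abort("y must contain both binary classes", "config_error")
  min_class <- min(table(y))
  if (min_class < n_folds) {
    warning(sprintf("reducing CV folds from %d to %d (smallest class size)",
                    n_folds, min_class))
    n_folds <- min_class
  }
  set.seed(seed)
  foldid <- stratified_folds(y, n_folds)
  cv <- glmnet::cv.glmnet(X, y, family = "binomial",
                          type.measure = "deviance", foldid = foldid,
                          nlambda = 100, lambda.min.ratio = 1e-4,
                          standardize = FALSE, maxit = 1e6)
  beta <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
  beta <- beta[beta != 0]
  beta[order(abs(beta), decreasing = TRUE)]
}

#' Uncorrelated feature pairs
#'
#' All unordered pairs of the given features whose absolute Pearson
#' correlation on the supplied rows is below `rho_max`.
#'
#' @param X Feature matrix (training rows).
#' @param features Character vector of candidate feature names (>= 2).
#' @param rho_max Correlation threshold (default 0.15); pairs with
#'   `|rho| >= rho_max` are discarded.
#' @return Data frame with columns `f1`, `f2`, `rho` (possibly 0 rows).
#' @export
uncorrelated_pairs <- function(X, features, rho_max = 0.15) {
  if (length(features) < 2L)
    abort("need at least two features", "config_error")
  C <- stats::cor(X[, features, drop = FALSE])
  pairs <- which(upper.tri(C), arr.ind = TRUE)
  out <- data.frame(f1 = features[pairs[, 1]], f2 = features[pairs[, 2]],
                    rho = C[pairs], stringsAsFactors = FALSE)
  out[abs(out$rho) < rho_max, , drop = FALSE]
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact permutation p-value when the smaller group has at most 10
#' observations and the pooled data are tie-free; otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y Numeric samples from the two groups (both nonempty).
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    abort("both groups must be nonempty", "validation_error")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && min(length(x), length(y)) <= 10
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the p-values ascending and rejects while
#' `p(i) <= alpha / (m - i + 1)`; the first failure stops all later
#' rejections.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return List with `rejected` (logical, original order) and
#'   `thresholds` (`alpha / (m - i + 1)` for ranks `i = 1..m`).
#' @export
holm_bonferroni <- function(pvalues, alpha = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    abort("p-values must lie in [0, 1]", "validation_error")
  m <- length(pvalues)
  thresholds <- alpha / (m - seq_len(m) + 1)
  ord <- order(pvalues)
  rejected_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (pvalues[ord[i]] <= thresholds[i]) rejected_sorted[i] <- TRUE else break
  }
  rejected <- logical(m)
  rejected[ord] <- rejected_sorted
  list(rejected = rejected, thresholds = thresholds)
}

#' Select the most discriminant uncorrelated feature couple
#'
#' Candidate couples are the uncorrelated pairs of LASSO-selected
#' features. Each member feature gets a two-sided Wilcoxon rank-sum
#' p-value; a couple's p-value is the maximum of its members' (both
#' members must discriminate). Holm-Bonferroni is applied over the
#' candidate couples and the significant couple with the smallest
#' p-value is returned; ties are broken by larger summed absolute LASSO
#' coefficient, then lexicographically.
#'
#' @param X Standardized feature matrix (training rows only).
#' @param y Binary 0/1 labels for those rows.
#' @param lasso_coefficients Named coefficients from [lasso_rank()].
#' @param rho_max Pairwise correlation threshold (default 0.15).
#' @param alpha Family-wise error rate for Holm (default 0.05).
#' @return List of class `selection_result`: `lasso_coefficients`,
#'   `feature_pvalues`, `uncorrelated_couples`, `couple_pvalues`,
#'   `holm_thresholds`, `significant_couples`, `selected_couple`.
#' @export
select_couple <- function(X, y, lasso_coefficients, rho_max = 0.15, alpha = 0.05) {
  features <- names(lasso_coefficients)
  if (length(features) < 2L)
    abort("fewer than two LASSO-selected features", "selection_error")
  pairs <- uncorrelated_pairs(X, features, rho_max)
  if (nrow(pairs) == 0L)
    abort("no uncorrelated couple below the correlation threshold",
          "selection_error")
  fpv <- vapply(unique(c(pairs$f1, pairs$f2)), function(f)
    wilcoxon_rank_sum(X[y == 1, f], X[y == 0, f]), numeric(1))
  pairs$p <- pmax(fpv[pairs$f1], fpv[pairs$f2])
  holm <- holm_bonferroni(pairs$p, alpha)
  if (!any(holm$rejected)) {
    abort(paste0("no couple significant after Holm-Bonferroni; smallest ",
                 sprintf("couple p-values: %s",
                         paste(signif(sort(pairs$p)[seq_len(min(5, nrow(pairs)))], 3),
                               collapse = ", "))),
          "selection_error")
  }
  sig <- pairs[holm$rejected, , drop = FALSE]
  strength <- abs(lasso_coefficients[sig$f1]) + abs(lasso_coefficients[sig$f2])
  key <- order(sig$p, -strength, paste(sig$f1, sig$f2))
  best <- sig[key[1], ]
  structure(list(
    lasso_coefficients = lasso_coefficients,
    feature_pvalues = fpv,
    uncorrelated_couples = pairs[, c("f1", "f2", "rho")],
    couple_pvalues = stats::setNames(pairs$p, paste(pairs$f1, pairs$f2, sep = "|")),
    holm_thresholds = holm$thresholds,
    significant_couples = sig[, c("f1", "f2", "p")],
    selected_couple = c(best$f1, best$f2),
    selected_pvalue = best$p,
    alpha = alpha, rho_max = rho_max),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d LASSO features, %d uncorrelated couples, %d significant\n",
              length(x$lasso_coefficients), nrow(x$uncorrelated_couples),
              nrow(x$significant_couples)))
  cat(sprintf("selected couple: %s + %s (p = %.3g)\n",
              x$selected_couple[1], x$selected_couple[2], x$selected_pvalue))
  invisible(x)
}
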