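# Class-weighted linear SVM workflow: support-vector-candidate training-set
# construction, repeated stratified 3-fold CV over a (C, gamma) grid with
# F2-based inner selection, an overfitting filter cascade, and a logistic
# calibration mapping decision values to the radiomic probability score.

default_C_grid <- function() 10^seq(-2, 3, length.out = 13)
default_gamma_grid <- function() 10^seq(-1, 1, length.out = 9)

# Linear SVM with kernel scale gamma realized as input scaling x / gamma,
# and the misclassification cost of each class scaled by its own prior
# probability in the fitted data.
fit_wsvm <- function(X, y, C, gamma) {
  yf <- factor(y, levels = c(0, 1))
  pri <- as.numeric(table(yf)) / length(yf)
  e1071::svm(X / gamma, yf, kernel = "linear", cost = C, scale = FALSE,
             class.weights = c("0" = pri[1], "1" = pri[2]))
}

# Decision values oriented so that larger = more likely class 1, plus
# hard predicted labels.
svm_decision <- function(model, X, gamma) {
  pr <- stats::predict(model, X / gamma, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  d <- as.numeric(dv)
  if (colnames(dv)[1] == "0/1") d <- -d
  list(d = d, pred = as.integer(as.character(pr)))
}

# Oriented effective weights/bias on the unscaled (normalized-feature)
# input: decision = X %*% weights + bias.
svm_linear_weights <- function(model, gamma) {
  w <- as.numeric(t(model$coefs) %*% model$SV) / gamma
  b <- -model$rho
  first <- colnames(model$decision.values)[1]
  if (identical(first, "0/1")) {
    w <- -w; b <- -b
  }
  list(weights = w, bias = b)
}

f2_from_labels <- function(pred, y) {
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  if (tp + fp == 0 || tp + fn == 0) return(0)
  ppv <- tp / (tp + fp)
  se <- tp / (tp + fn)
  if (ppv + se == 0) return(0)
  5 * ppv * se / (4 * ppv + se)
}

#' Build the training/test split from support-vector candidates
#'
#' Fits a preliminary class-weighted linear SVM (C = 1, gamma = 1) on all
#' standardized rows and ranks patients within each class by ascending
#' absolute decision value, i.e. by their proximity to the separating
#' hyperplane. The patients closest to the hyperplane -- the candidates
#' for becoming support vectors -- form the training set; the remainder
#' is the holdout test set.
#'
#' @param X Standardized feature matrix for all patients (row names =
#'   patient ids).
#' @param y Binary 0/1 labels.
#' @param train_sizes Named or ordered pair `c(ncs, cs)`: training
#'   patients per class (default `c(18, 30)`).
#' @return List of class `split_plan` with `train_ids`, `test_ids` and
#'   the per-class counts.
#' @export
build_training_set <- function(X, y, train_sizes = c(ncs = 18, cs = 30)) {
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  if (n0 < train_sizes[1] || n1 < train_sizes[2])
    abort("a class is smaller than its requested training size", "config_error")
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  m <- fit_wsvm(X, y, C = 1, gamma = 1)
  d <- svm_decision(m, X, gamma = 1)$d
  train <- character(0)
  for (cl in c(0, 1)) {
    members <- which(y == cl)
    ranked <- members[order(abs(d[members]))]
    train <- c(train, ids[ranked[seq_len(train_sizes[cl + 1])]])
  }
  structure(list(train_ids = train, test_ids = setdiff(ids, train),
                 n_train = stats::setNames(as.integer(train_sizes), c("ncs", "cs")),
                 n_test = c(ncs = n0 - as.integer(train_sizes[1]),
                            cs = n1 - as.integer(train_sizes[2]))),
            class = "split_plan")
}

#' Repeated stratified fold assignments
#'
#' Stratified `n_folds`-fold assignments of the training patients,
#' re-randomized independently for each repetition under one seed. With
#' the default 18 + 30 training set and 3 folds, every fold holds 6
#' non-significant and 10 significant patients. Counts that do not divide
#' evenly are dealt round-robin to the nearest-balanced assignment with a
#' warning.
#'
#' @param plan A `split_plan` from [build_training_set()].
#' @param y_train Binary labels of the training patients, in
#'   `plan$train_ids` order.
#' @param n_reps Number of repetitions (default 100).
#' @param n_folds Folds per repetition (default 3).
#' @param seed Integer seed.
#' @return List of length `n_reps`; each element is an integer fold id
#'   per training patient.
#' @export
make_folds <- function(plan, y_train, n_reps = 100, n_folds = 3, seed = 1) {
  if (any(table(y_train) %% n_folds != 0))
    warning("class counts not divisible by fold count; using nearest-balanced folds")
  set.seed(seed)
  lapply(seq_len(n_reps), function(r) stratified_folds(y_train, n_folds))
}

#' Tune SVM candidates by repeated cross-validation
#'
#' For each repetition, grid-searches `(C, gamma)` by the mean F2-score
#' on the held-out folds, refits the repetition's best combination on the
#' full training set, and attaches a logistic (binomial logit)
#' calibration fitted on the training decision values. Train metrics are
#' computed on the full training set; validation metrics are the means
#' over the held-out folds at the chosen combination. Repetitions with a
#' degenerate (single-class) fold are skipped with a warning.
#'
#' @param X2 Normalized matrix of the two selected features, training
#'   rows in `plan$train_ids` order.
#' @param y_train Binary labels in the same order.
#' @param folds Fold assignments from [make_folds()].
#' @param C_grid,gamma_grid Hyperparameter grids (defaults: 13 log steps
#'   over `10^-2..10^3` and 9 over `10^-1..10^1`).
#' @return List of candidate models, one per usable repetition.
#' @export
tune_candidates <- function(X2, y_train, folds,
                            C_grid = default_C_grid(),
                            gamma_grid = default_gamma_grid()) {
  grid <- expand.grid(C = C_grid, gamma = gamma_grid)
  grid <- grid[order(grid$C, grid$gamma), ]
  candidates <- list()
  n_skipped <- 0L
  for (r in seq_along(folds)) {
    fold <- folds[[r]]
    if (any(vapply(unique(fold), function(f)
      length(unique(y_train[fold == f])) < 2L, logical(1)))) {
      n_skipped <- n_skipped + 1L
      next
    }
    val_f2 <- val_auc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      f2s <- aucs <- numeric(0)
      for (f in unique(fold)) {
        tr <- fold != f
        m <- fit_wsvm(X2[tr, , drop = FALSE], y_train[tr],
                      grid$C[g], grid$gamma[g])
        out <- svm_decision(m, X2[!tr, , drop = FALSE], grid$gamma[g])
        f2s <- c(f2s, f2_from_labels(out$pred, y_train[!tr]))
        aucs <- c(aucs, roc_auc(out$d, y_train[!tr])$auc)
      }
      val_f2[g] <- mean(f2s)
      val_auc[g] <- mean(aucs)
    }
    # ties on validation F2 (frequent on small folds) broken by validation
    # AUC, then by the smallest cost at or above 1: sub-unit costs are the
    # overfit-prone region the later filter cascade discards anyway
    best <- order(-val_f2, -val_auc, grid$C < 1, grid$C, grid$gamma)[1]
    m <- fit_wsvm(X2, y_train, grid$C[best], grid$gamma[best])
    fit <- svm_decision(m, X2, grid$gamma[best])
    cal <- suppressWarnings(
      stats::glm(y_train ~ fit$d, family = stats::binomial()))
    lin <- svm_linear_weights(m, grid$gamma[best])
    candidates[[length(candidates) + 1L]] <- list(
      rep = r, C = grid$C[best], gamma = grid$gamma[best],
      weights = lin$weights, bias = lin$bias,
      train_auc = roc_auc(fit$d, y_train)$auc,
      train_f2 = f2_from_labels(fit$pred, y_train),
      val_auc = val_auc[best], val_f2 = val_f2[best],
      calibration = list(intercept = unname(stats::coef(cal)[1]),
                         slope = unname(stats::coef(cal)[2])))
  }
  if (n_skipped > 0)
    warning(sprintf("%d repetition(s) skipped (degenerate fold)", n_skipped))
  candidates
}

#' Filter the candidate models and select the survivor
#'
#' The cascade drops, in order: (1) candidates whose validation AUC
#' exceeds their training AUC (overfitting-prone), (2) candidates with
#' `C < 1`, (3) candidates with training F2 below `min_train_f2`. Among
#' the survivors the one with the highest validation F2 wins; ties go to
#' the higher training F2, then the smaller C.
#'
#' @param candidates List from [tune_candidates()].
#' @param min_train_f2 Training F2 floor (default 0.80).
#' @param couple Character pair naming the selected features (metadata).
#' @param normalization Normalization parameter table (metadata).
#' @param seed Master seed (metadata).
#' @return List of class `locrad_model`: the surviving candidate plus
#'   `couple`, `normalization`, `filter_log` and `seed`.
#' @export
filter_and_select <- function(candidates, min_train_f2 = 0.80,
                              couple = NULL, normalization = NULL, seed = NULL) {
  if (length(candidates) == 0L)
    abort("no candidate models", "selection_error")
  n0 <- length(candidates)
  s1 <- Filter(function(m) m$val_auc <= m$train_auc, candidates)
  s2 <- Filter(function(m) m$C >= 1, s1)
  s3 <- Filter(function(m) m$train_f2 >= min_train_f2, s2)
  log <- c(candidates = n0, after_overfit_filter = length(s1),
           after_C_filter = length(s2), after_f2_filter = length(s3))
  if (length(s3) == 0L)
    abort(sprintf(
      "no model survived the filter cascade (candidates %d -> overfit %d -> C %d -> F2 %d)",
      n0, length(s1), length(s2), length(s3)), "selection_error")
  key <- order(-vapply(s3, `[[`, numeric(1), "val_f2"),
               -vapply(s3, `[[`, numeric(1), "train_f2"),
               vapply(s3, `[[`, numeric(1), "C"))
  best <- s3[[key[1]]]
  structure(c(best,
              list(couple = couple, normalization = normalization,
                   filter_log = as.list(log), seed = seed)),
            class = "locrad_model")
}

#' @export
print.locrad_model <- function(x, ...) {
  cat(sprintf("locrad_model: couple %s, C = %.3g, gamma = %.3g\n",
              if (is.null(x$couple)) "<unset>" else paste(x$couple, collapse = " + "),
              x$C, x$gamma))
  cat(sprintf("  train AUC %.3f / F2 %.3f; validation AUC %.3f / F2 %.3f\n",
              x$train_auc, x$train_f2, x$val_auc, x$val_f2))
  invisible(x)
}

#' Radiomic probability score
#'
#' Maps rows of the normalized two-feature matrix through the fitted
#' linear decision function and the logistic calibration, giving a
#' probability in (0, 1); monotone increasing along the weight direction.
#'
#' @param model A `locrad_model` from [filter_and_select()].
#' @param X2 Normalized matrix (or single row) of the selected couple.
#' @return Numeric vector of probability scores.
#' @export
radiomic_score <- function(model, X2) {
  X2 <- rbind(X2)
  d <- as.numeric(X2 %*% model$weights) + model$bias
  stats::plogis(model$calibration$intercept + model$calibration$slope * d)
}
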