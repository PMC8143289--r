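make_two_cluster_data <- function(n0, n1, sep = 4, sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n0 * 2, -sep / 2, sd), n0, 2),
             matrix(rnorm(n1 * 2, sep / 2, sd), n1, 2))
  colnames(X) <- c("u", "v")
  rownames(X) <- sprintf("P%03d", seq_len(n0 + n1))
  list(X = X, y = rep(c(0L, 1L), c(n0, n1)))
}

test_that("support-vector-candidate split reproduces the cohort partition", {
  d <- make_two_cluster_data(26, 50, sep = 2, sd = 1, seed = 2)
  plan <- build_training_set(d$X, d$y, train_sizes = c(ncs = 18, cs = 30))
  expect_length(plan$train_ids, 48)
  expect_length(plan$test_ids, 28)
  y_by_id <- stats::setNames(d$y, rownames(d$X))
  expect_identical(as.integer(table(y_by_id[plan$test_ids])), c(8L, 20L))
  expect_identical(as.integer(table(y_by_id[plan$train_ids])), c(18L, 30L))

  plan2 <- build_training_set(d$X, d$y, train_sizes = c(ncs = 18, cs = 30))
  expect_identical(plan, plan2)

  expect_error(build_training_set(d$X, d$y, train_sizes = c(27, 30)),
               class = "locrad_config_error")
})

test_that("far-from-margin points land in the test set", {
  set.seed(4)
  X <- rbind(matrix(rnorm(10 * 2, -1, 0.2), 10, 2),
             matrix(c(-50, -50), 1, 2),          # extreme negative
             matrix(rnorm(10 * 2, 1, 0.2), 10, 2),
             matrix(c(50, 50), 1, 2))            # extreme positive
  rownames(X) <- sprintf("P%03d", 1:22)
  y <- rep(c(0L, 1L), each = 11)
  plan <- build_training_set(X, y, train_sizes = c(8, 8))
  expect_true(all(c("P011", "P022") %in% plan$test_ids))
})

test_that("repeated stratified folds have the printed class structure", {
  d <- make_two_cluster_data(26, 50, seed = 3)
  plan <- build_training_set(d$X, d$y, train_sizes = c(ncs = 18, cs = 30))
  y_by_id <- stats::setNames(d$y, rownames(d$X))
  y_train <- unname(y_by_id[plan$train_ids])
  folds <- make_folds(plan, y_train, n_reps = 100, n_folds = 3, seed = 5)
  expect_length(folds, 100)
  for (r in c(1, 50, 100)) {
    for (f in 1:3) {
      expect_identical(sum(folds[[r]] == f), 16L)
      expect_identical(sum(folds[[r]] == f & y_train == 0), 6L)
      expect_identical(sum(folds[[r]] == f & y_train == 1), 10L)
    }
  }
  expect_gt(length(unique(vapply(folds, paste, character(1), collapse = ""))), 90)
  folds2 <- make_folds(plan, y_train, n_reps = 100, n_folds = 3, seed = 5)
  expect_identical(folds, folds2)
})

test_that("tuning yields calibrated candidates that separate separable data", {
  d <- make_two_cluster_data(18, 30, seed = 6)
  folds <- make_folds(NULL, d$y, n_reps = 4, n_folds = 3, seed = 7)
  cands <- tune_candidates(d$X, d$y, folds,
                           C_grid = c(0.1, 1, 10), gamma_grid = c(0.5, 2))
  expect_lte(length(cands), 4L)
  expect_gte(length(cands), 1L)
  expect_true(any(vapply(cands, `[[`, numeric(1), "val_f2") == 1))
  m <- cands[[1]]
  # calibrated scores live in (0,1) and increase along the weight direction
  steps <- seq(-3, 3, length.out = 11)
  line <- outer(steps, m$weights / sqrt(sum(m$weights^2)))
  sc <- radiomic_score(m, line)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_true(all(diff(sc) >= 0))  # scores may saturate numerically far out
  expect_lt(sc[1], sc[11])
})

test_that("the filter cascade keeps compliant models and reports attrition", {
  base <- list(rep = 1, C = 10, gamma = 1, weights = c(1, 1), bias = 0,
               train_auc = 0.9, val_auc = 0.85, train_f2 = 0.9, val_f2 = 0.82,
               calibration = list(intercept = 0, slope = 1))
  good <- base
  overfit <- modifyList(base, list(val_auc = 0.95))
  lowC <- modifyList(base, list(C = 0.5))
  lowF2 <- modifyList(base, list(train_f2 = 0.7))
  model <- filter_and_select(list(good, overfit, lowC, lowF2),
                             couple = c("a", "b"))
  expect_identical(model$C, 10)
  expect_identical(model$filter_log$candidates, 4L)
  expect_identical(model$filter_log$after_f2_filter, 1L)

  expect_error(filter_and_select(list(lowC, modifyList(lowC, list(C = 0.9)))),
               class = "locrad_selection_error")
  expect_error(filter_and_select(list()), class = "locrad_selection_error")

  # ties on validation F2 resolved by train F2 then smaller C
  tie1 <- modifyList(base, list(train_f2 = 0.92, C = 100))
  tie2 <- modifyList(base, list(train_f2 = 0.92, C = 2))
  expect_identical(filter_and_select(list(good, tie1, tie2))$C, 2)
})

test_that("the radiomic score is the calibrated logit of the decision value", {
  model <- structure(list(weights = c(2, -1), bias = 0.5,
                          calibration = list(intercept = 0.3, slope = 2)),
                     class = "locrad_model")
  # a row on the separating hyperplane scores at the calibration midpoint
  row_on_plane <- c(0.25, 1)   # 2*0.25 - 1*1 + 0.5 = 0
  expect_equal(radiomic_score(model, row_on_plane), plogis(0.3))
  expect_gt(radiomic_score(model, c(1, 0)), radiomic_score(model, c(0, 0)))
})

test_that("tuning skips repetitions with a degenerate fold", {
  d <- make_two_cluster_data(6, 6, seed = 8)
  degenerate <- list(c(1, 1, 1, 2, 2, 2, 2, 2, 2, 1, 1, 1),
                     c(1, 2, 1, 2, 1, 2, 2, 1, 2, 1, 2, 1),
                     c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2))
  expect_warning(
    cands <- tune_candidates(d$X, d$y, degenerate,
                             C_grid = c(1, 10), gamma_grid = 1),
    "skipped")
  expect_length(cands, 2L)
})
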