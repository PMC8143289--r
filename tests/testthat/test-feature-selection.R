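test_that("min-max plus z-score normalization matches hand arithmetic", {
  X <- cbind(a = c(2, 4, 6), b = c(1, 1, 2))
  out <- normalize_standardize(X)
  expect_equal(unname(out$X[, "a"]), c(-1, 0, 1))

  # train-only parameters applied to a test row equal to the train max
  X4 <- rbind(X, c(6, 1.5))
  out2 <- normalize_standardize(X4, train_idx = 1:3)
  pa <- out2$params[out2$params$feature == "a", ]
  expect_equal(unname(out2$X[4, "a"]), (1 - pa$scaled_mean) / pa$scaled_sd)
  expect_equal(unname(out2$X[4, "a"]), unname(out2$X[3, "a"]))

  # constant training column dropped with a warning
  Xc <- cbind(a = c(2, 4, 6), const = c(5, 5, 5))
  expect_warning(res <- normalize_standardize(Xc), "constant")
  expect_identical(colnames(res$X), "a")

  expect_equal(apply_normalization(rbind(c(a = 6, b = 2)), out$params)[1, "a"],
               c(a = 1))
})

test_that("LASSO keeps planted signal and zeroes pure noise", {
  hits_signal <- hits_noise_zero <- 0L
  for (s in 1:5) {
    set.seed(300 + s)
    n <- 200
    signal <- rnorm(n)
    X <- cbind(signal = signal, matrix(rnorm(n * 5), n, 5,
                                       dimnames = list(NULL, paste0("noise", 1:5))))
    X <- scale(X)
    y <- rbinom(n, 1, plogis(2 * signal))
    beta <- lasso_rank(X, y, seed = s)
    if ("signal" %in% names(beta)) hits_signal <- hits_signal + 1L
    if (!"noise1" %in% names(beta)) hits_noise_zero <- hits_noise_zero + 1L
  }
  expect_gte(hits_signal, 4L)
  expect_gte(hits_noise_zero, 4L)
})

test_that("LASSO ranking is deterministic under a fixed seed and reduces folds", {
  set.seed(9)
  X <- scale(matrix(rnorm(40 * 6), 40, 6,
                    dimnames = list(NULL, paste0("f", 1:6))))
  y <- rep(c(0, 1), each = 20)
  b1 <- lasso_rank(X, y, seed = 42)
  b2 <- lasso_rank(X, y, seed = 42)
  expect_identical(b1, b2)

  ysmall <- rep(c(0, 1), c(5, 35))
  expect_warning(lasso_rank(X, ysmall, n_folds = 10, seed = 1), "reducing")
})

test_that("correlation filter keeps only weakly correlated pairs", {
  set.seed(21)
  n <- 1e4
  X <- cbind(a = rnorm(n), b = rnorm(n))
  X <- cbind(X, dup = X[, "a"])
  pairs <- uncorrelated_pairs(X, c("a", "b", "dup"), rho_max = 0.15)
  expect_false(any(pairs$f1 == "a" & pairs$f2 == "dup"))
  expect_true(any((pairs$f1 == "a" & pairs$f2 == "b") |
                  (pairs$f1 == "b" & pairs$f2 == "a")))

  X10 <- matrix(rnorm(50 * 10), 50, 10, dimnames = list(NULL, paste0("f", 1:10)))
  expect_lte(nrow(uncorrelated_pairs(X10, colnames(X10), rho_max = 1)), 45L)
})

test_that("Wilcoxon rank-sum honours exact and approximate branches", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3)
  x <- c(1.5, 2.5, 3.5, 4.5)
  expect_equal(wilcoxon_rank_sum(x, x), 1)
  set.seed(8)
  a <- rnorm(30); b <- rnorm(30) + 2
  expect_lt(wilcoxon_rank_sum(a, b), 1e-4)

  # invariance to strictly monotone transforms of the pooled data
  set.seed(9)
  u <- runif(12); v <- runif(15) + 0.3
  expect_equal(wilcoxon_rank_sum(u, v),
               wilcoxon_rank_sum(exp(3 * u), exp(3 * v)))
  u2 <- rnorm(25); v2 <- rnorm(25) + 1
  expect_equal(wilcoxon_rank_sum(u2, v2),
               wilcoxon_rank_sum(qlogis(pnorm(u2)), qlogis(pnorm(v2))))
})

test_that("Holm step-down matches its definition and nests Bonferroni", {
  hb <- holm_bonferroni(runif(14))
  expect_equal(hb$thresholds[11], 0.0125)
  expect_equal(holm_bonferroni(0.03)$thresholds, 0.05)
  expect_true(holm_bonferroni(0.04)$rejected)

  set.seed(17)
  for (i in 1:20) {
    m <- sample(1:25, 1)
    p <- round(runif(m), sample(1:3, 1))  # rounding forces ties
    hb <- holm_bonferroni(p, alpha = 0.05)
    expect_identical(hb$rejected, holm_reference(p, 0.05))
    bonf <- p <= 0.05 / m
    unadj <- p <= 0.05
    expect_true(all(hb$rejected[bonf]))   # Holm rejects all Bonferroni rejections
    expect_true(all(unadj[hb$rejected]))  # and only unadjusted rejections
  }
})

test_that("couple selection picks the significant pair and fails cleanly on noise", {
  set.seed(31)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  # anticorrelated noise keeps the two discriminant features mutually
  # uncorrelated (cov = var(y) - var(e) = 0) while both separate the classes
  e <- rnorm(n, 0, 0.5)
  X <- cbind(f1 = y + e,
             f2 = y - e + rnorm(n, 0, 0.1),
             f3 = rnorm(n))
  coefs <- c(f1 = 1, f2 = 0.5, f3 = 0.1)
  sel <- select_couple(X, y, coefs)
  expect_setequal(sel$selected_couple, c("f1", "f2"))
  expect_lt(sel$selected_pvalue, 0.01)
  expect_true(all(abs(sel$uncorrelated_couples$rho) < 0.15))

  # selection consults only the rows it is given
  sel2 <- select_couple(X, y, coefs)
  expect_identical(sel$selected_couple, sel2$selected_couple)

  # all-noise cohorts abort with a selection error
  for (s in 1:3) {
    set.seed(500 + s)
    Xn <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("g", 1:6)))
    cn <- stats::setNames(runif(6, 0.1, 1), colnames(Xn))
    expect_error(select_couple(Xn, y, cn), class = "locrad_selection_error")
  }

  # perfectly correlated candidates leave no couple
  Xdup <- cbind(h1 = X[, "f1"], h2 = X[, "f1"])
  expect_error(select_couple(Xdup, y, c(h1 = 1, h2 = 1)),
               class = "locrad_selection_error")
})
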