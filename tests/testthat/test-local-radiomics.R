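test_that("patch side follows the spacing rule with clamping", {
  expect_identical(window_side_from_spacing(1.41), 7L)
  expect_identical(window_side_from_spacing(1.67), 5L)
  expect_identical(window_side_from_spacing(5.0), 3L)
  expect_error(window_side_from_spacing(0), class = "locrad_config_error")
  expect_error(window_side_from_spacing(-1), class = "locrad_config_error")
})

test_that("local statistics match hand-computed values and degenerate conventions", {
  # constant patch: dispersion-free conventions
  st <- local_first_order_stats(rep(3.5, 25))
  expect_equal(unname(st), c(3.5, 3.5, 0, 0, 0, 0, 0))

  # patch 1..9: symmetric, so mean = median = 5, skewness 0; the other
  # values were frozen from an independent evaluation of the estimator
  # formulas (population moments, type-7 quantiles, 16-bin entropy)
  st <- local_first_order_stats(1:9)
  expect_equal(st[["m"]], 5)
  expect_equal(st[["M"]], 5)
  expect_equal(st[["s"]], 0)
  expect_equal(st[["iqr"]], 4)
  expect_equal(st[["cv"]], 0.516397779494322)
  expect_equal(st[["k"]], -1.23)
  expect_equal(st[["e"]], log2(9))

  expect_error(local_first_order_stats(numeric(0)),
               class = "locrad_contract_violation")
})

test_that("patch sweep counts ROI voxels and matches the naive reference", {
  # single-voxel mask
  vol <- image_volume(array(rnorm(5 * 9 * 9), dim = c(5, 9, 9)), 1.5)
  m <- array(0, dim = c(5, 9, 9)); m[3, 5, 5] <- 1
  maps <- sweep_patches(vol, lesion_mask(m), 5)
  expect_identical(nrow(maps$stats), 1L)

  # constant image: every local map constant per convention
  volc <- image_volume(array(7, dim = c(3, 9, 9)), 1.5)
  mall <- array(1, dim = c(3, 9, 9))
  maps <- sweep_patches(volc, lesion_mask(mall), 3)
  expect_true(all(maps$stats[, "m"] == 7))
  expect_true(all(maps$stats[, c("s", "k", "iqr", "cv", "e")] == 0))

  # planted bright block, including border-truncated windows
  set.seed(41)
  a <- array(rnorm(1 * 11 * 11), dim = c(1, 11, 11))
  a[1, 5:7, 5:7] <- a[1, 5:7, 5:7] + 50
  vol <- image_volume(a, 1.5)
  msk <- lesion_mask(array(1, dim = c(1, 11, 11)))
  maps <- sweep_patches(vol, msk, 5)
  expect_equal(maps$stats, naive_sweep(vol, msk, 5), tolerance = 1e-12)

  expect_error(sweep_patches(vol, lesion_mask(array(0, dim = c(1, 11, 11))), 5),
               class = "locrad_validation_error")
  expect_error(sweep_patches(vol, msk, 4), class = "locrad_config_error")
})

test_that("patch sweep equals the naive per-voxel reference on random volumes", {
  set.seed(99)
  for (case in 1:10) {
    d <- c(sample(1:3, 1), sample(8:20, 1), sample(8:20, 1))
    vol <- image_volume(array(rnorm(prod(d), 100, 20), dim = d), 1.5)
    m <- array(rbinom(prod(d), 1, 0.3), dim = d)
    if (sum(m) == 0) m[1] <- 1
    msk <- lesion_mask(m)
    side <- sample(c(3, 5, 7), 1)
    got <- sweep_patches(vol, msk, side)$stats
    ref <- naive_sweep(vol, msk, side)
    expect_lt(max(abs(got - ref) / pmax(abs(ref), 1)), 1e-10)
  }
})

test_that("global summaries give 84 named features with the last-decile convention", {
  p <- toy_patient(1)
  maps <- sweep_patches(p$volume, p$mask, 5)
  fv <- summarize_global(maps)
  expect_length(fv, 84)
  expect_identical(names(fv), radiomic_feature_names())
  expect_true(all(c("M_CV", "k_iqr", "m_sigma", "s_M90th") %in% names(fv)))
  expect_true(all(is.finite(fv)))

  # 20-value toy distribution: the last decile is the top-2 values
  v <- c(4, 18, 1, 12, 7, 9, 15, 3, 11, 6, 19, 2, 14, 8, 10, 5, 17, 13, 16, 40)
  maps20 <- structure(list(coords = NULL,
                           stats = matrix(v, 20, 7,
                                          dimnames = list(NULL, c("m", "M", "s", "k", "iqr", "cv", "e")))),
                      class = "local_stat_maps")
  fv20 <- summarize_global(maps20)
  expect_equal(fv20[["m_m90th"]], mean(c(19, 40)))
  expect_equal(fv20[["m_M90th"]], stats::median(c(19, 40)))
  expect_equal(fv20[["m_max"]], 40)

  # constant maps: location summaries agree, dispersion summaries vanish
  mapsc <- structure(list(coords = NULL,
                          stats = matrix(2, 15, 7,
                                         dimnames = list(NULL, c("m", "M", "s", "k", "iqr", "cv", "e")))),
                     class = "local_stat_maps")
  fvc <- summarize_global(mapsc)
  expect_equal(fvc[["m_mean"]], fvc[["m_max"]])
  expect_equal(fvc[["m_mean"]], fvc[["m_M"]])
  expect_equal(unname(fvc[c("m_sigma", "m_mad", "m_iqr")]), c(0, 0, 0))
})

test_that("feature extraction is deterministic and translation invariant", {
  p <- toy_patient(7)
  f1 <- extract_features(p$volume, p$mask)
  f2 <- extract_features(p$volume, p$mask)
  expect_identical(f1, f2)

  # shift image and mask by whole voxels, away from borders
  shift <- function(a, dr, dc) {
    out <- array(0, dim = dim(a))
    out[, (1 + dr):dim(a)[2], (1 + dc):dim(a)[3]] <-
      a[, 1:(dim(a)[2] - dr), 1:(dim(a)[3] - dc)]
    out
  }
  vol2 <- image_volume(shift(p$volume$voxels, 2, 3), p$volume$pixel_spacing_mm)
  msk2 <- lesion_mask(shift(p$mask$voxels, 2, 3))
  expect_equal(extract_features(vol2, msk2), f1, tolerance = 1e-12)
})

test_that("intensity shift moves location features, fixes scale features, shrinks CV", {
  p <- toy_patient(3)
  f0 <- extract_features(p$volume, p$mask)
  cshift <- 25
  volp <- image_volume(p$volume$voxels + cshift, p$volume$pixel_spacing_mm)
  f1 <- extract_features(volp, p$mask)
  expect_equal(f1[["m_mean"]], f0[["m_mean"]] + cshift, tolerance = 1e-10)
  expect_equal(f1[["M_M"]], f0[["M_M"]] + cshift, tolerance = 1e-10)
  expect_equal(f1[["m_sigma"]], f0[["m_sigma"]], tolerance = 1e-10)
  expect_equal(f1[["m_iqr"]], f0[["m_iqr"]], tolerance = 1e-10)
  expect_equal(f1[["iqr_mean"]], f0[["iqr_mean"]], tolerance = 1e-10)
  expect_equal(f1[["s_mean"]], f0[["s_mean"]], tolerance = 1e-10)
  expect_equal(f1[["e_mean"]], f0[["e_mean"]], tolerance = 1e-10)
  expect_lt(f1[["m_CV"]], f0[["m_CV"]])
  expect_lt(f1[["M_CV"]], f0[["M_CV"]])
})

test_that("higher planted heterogeneity increases the m_sigma feature", {
  # monotone response over effect levels, checked by Spearman correlation
  levels_ <- c(0, 8, 16, 24, 32)
  reps <- 12
  # expectation estimated by averaging replicate phantoms per effect level
  level_means <- sapply(levels_, function(h) {
    mean(sapply(seq_len(reps), function(r) {
      cfg <- cohort_config(n_ncs = 1, n_cs = 1, seed = 1000 * r + h,
                           heterogeneity_effect = h, asymmetry_effect = 0)
      p <- generate_cohort(cfg)[[2]]
      extract_features(p$volume, p$mask)[["m_sigma"]]
    }))
  })
  rho <- stats::cor(levels_, level_means, method = "spearman")
  expect_gt(rho, 0.9)
})
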