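# Local first-order radiomics: per-pixel statistics over a spacing-derived
# square in-slice patch, then twelve global summaries of each local
# distribution, giving 84 features per patient.

LOCAL_STATS <- c("m", "M", "s", "k", "iqr", "cv", "e")
GLOBAL_STATS <- c("mean", "M", "s", "k", "iqr", "CV", "e",
                  "max", "sigma", "mad", "m90th", "M90th")
N_ENTROPY_BINS <- 16L

#' Canonical radiomic feature names
#'
#' Feature names are `<local>_<global>`, local-statistic major. Local
#' statistics (computed per ROI pixel over its patch): `m` mean, `M`
#' median, `s` skewness, `k` excess kurtosis, `iqr` interquartile range,
#' `cv` coefficient of variation, `e` Shannon entropy. Global summaries of
#' each local distribution: `mean`, `M` (median), `s`, `k`, `iqr`, `CV`,
#' `e`, `max`, `sigma` (standard deviation), `mad` (median absolute
#' deviation), `m90th`/`M90th` (mean/median of the last decile, i.e. of
#' the values at or above the empirical 90th percentile). The names
#' `M_CV`, `k_iqr`, `m_sigma` and `s_M90th` follow the field's subscript
#' notation (sigma rendered in ASCII).
#'
#' @return Character vector of the 84 feature names.
#' @export
radiomic_feature_names <- function() {
  as.vector(t(outer(LOCAL_STATS, GLOBAL_STATS, paste, sep = "_")))
}

#' Patch side from pixel spacing
#'
#' The patch explores a minimum in-plane distance of 0.5 cm from the
#' central pixel along rows and columns, i.e. `side = 2 * floor(5 /
#' spacing_mm) + 1`, clamped to at least 3. At the spacings typical of
#' prostate DWI (1.41-1.67 mm) this gives sides of 7 and 5 pixels.
#'
#' @param pixel_spacing_mm In-plane pixel spacing in mm (> 0).
#' @return Odd integer patch side.
#' @export
window_side_from_spacing <- function(pixel_spacing_mm) {
  if (!is_scalar_num(pixel_spacing_mm) || pixel_spacing_mm <= 0)
    abort("pixel spacing must be a positive scalar", "config_error")
  max(3L, 2L * as.integer(floor(5 / pixel_spacing_mm)) + 1L)
}

# Linear-interpolation empirical quantile (R type 7) of a sorted vector.
sorted_quantile <- function(xs, p) {
  n <- length(xs)
  h <- 1 + (n - 1) * p
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[pmin(lo + 1, n)] - xs[lo])
}

#' Seven local first-order statistics of a patch
#'
#' Estimator conventions: arithmetic mean; linear-interpolation empirical
#' median; bias-uncorrected Fisher-Pearson skewness g1; excess kurtosis
#' g2 (normal -> 0); IQR = q75 - q25; CV = population SD / mean; Shannon
#' entropy (base 2) of a 16-bin histogram over the patch's own min-max
#' range. A zero-variance patch returns skewness = kurtosis = CV =
#' entropy = 0 by convention; a zero mean with nonzero variance gives
#' CV = 0 (callers may count these via the `"cv_zero_mean"` attribute).
#'
#' @param patch Nonempty numeric vector of patch intensities.
#' @return Named numeric vector `(m, M, s, k, iqr, cv, e)`.
#' @export
local_first_order_stats <- function(patch) {
  if (length(patch) == 0L)
    abort("empty patch", "contract_violation")
  n <- length(patch)
  mu <- mean(patch)
  d <- patch - mu
  m2 <- mean(d^2)
  if (m2 <= 0) {
    out <- c(m = mu, M = mu, s = 0, k = 0, iqr = 0, cv = 0, e = 0)
    return(out)
  }
  xs <- sort(patch)
  q <- sorted_quantile(xs, c(0.25, 0.5, 0.75))
  sk <- mean(d^3) / m2^1.5
  ku <- mean(d^4) / m2^2 - 3
  cv <- if (mu == 0) 0 else sqrt(m2) / mu
  rng <- xs[n] - xs[1]
  bins <- pmin(floor((patch - xs[1]) / rng * N_ENTROPY_BINS) + 1, N_ENTROPY_BINS)
  p <- tabulate(bins, N_ENTROPY_BINS) / n
  p <- p[p > 0]
  ent <- -sum(p * log2(p))
  out <- c(m = mu, M = q[2], s = sk, k = ku, iqr = q[3] - q[1], cv = cv, e = ent)
  if (mu == 0) attr(out, "cv_zero_mean") <- TRUE
  out
}

# Vectorized column-wise version of local_first_order_stats for a matrix
# of full patches (one patch per column, no NAs). Same conventions.
patch_stats_columns <- function(W) {
  n <- nrow(W)
  k <- ncol(W)
  mu <- colMeans(W)
  Xc <- W - rep(mu, each = n)
  m2 <- colMeans(Xc^2)
  m3 <- colMeans(Xc^3)
  m4 <- colMeans(Xc^4)
  Ws <- matrix(W[order(rep(seq_len(k), each = n), W)], nrow = n)
  qs <- function(p) {
    h <- 1 + (n - 1) * p
    lo <- floor(h)
    hi <- min(lo + 1, n)
    Ws[lo, ] + (h - lo) * (Ws[hi, ] - Ws[lo, ])
  }
  q25 <- qs(0.25); q50 <- qs(0.5); q75 <- qs(0.75)
  nd <- m2 > 0
  sk <- ku <- cv <- ent <- numeric(k)
  sk[nd] <- m3[nd] / m2[nd]^1.5
  ku[nd] <- m4[nd] / m2[nd]^2 - 3
  okcv <- nd & mu != 0
  cv[okcv] <- sqrt(m2[okcv]) / mu[okcv]
  if (any(nd)) {
    lo <- Ws[1, nd]
    rng <- Ws[n, nd] - lo
    B <- pmin(floor((W[, nd, drop = FALSE] - rep(lo, each = n)) /
                      rep(rng, each = n) * N_ENTROPY_BINS) + 1, N_ENTROPY_BINS)
    cnt <- matrix(tabulate(as.vector(B) + N_ENTROPY_BINS * rep(seq_len(sum(nd)) - 1L, each = n),
                           N_ENTROPY_BINS * sum(nd)), nrow = N_ENTROPY_BINS)
    P <- cnt / n
    L <- P * log2(P)
    L[P == 0] <- 0
    ent[nd] <- -colSums(L)
  }
  res <- cbind(m = mu, M = q50, s = sk, k = ku, iqr = q75 - q25, cv = cv, e = ent)
  attr(res, "n_cv_zero_mean") <- sum(nd & mu == 0)
  res
}

#' Sweep local patches over all ROI voxels
#'
#' For every in-mask voxel, computes the seven local statistics of the
#' `side` x `side` in-slice window centred on it. Windows are truncated
#' at image borders; window membership is not mask-restricted, so
#' out-of-mask context pixels contribute to each patch.
#'
#' @param volume An [image_volume()].
#' @param mask A congruent [lesion_mask()] with at least one ROI voxel.
#' @param side Odd window side, >= 3.
#' @return An object of class `local_stat_maps`: a list with `coords`
#'   (ROI voxel indices, columns slice/row/col) and `stats` (matrix, one
#'   row per ROI voxel, columns `m, M, s, k, iqr, cv, e`).
#' @export
sweep_patches <- function(volume, mask, side) {
  check_congruent(volume, mask)
  if (!is_count(side) || side < 3 || side %% 2 == 0)
    abort("side must be an odd integer >= 3", "config_error")
  idx <- which(mask$voxels == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    abort("empty mask", "validation_error")
  colnames(idx) <- c("slice", "row", "col")
  half <- (side - 1L) / 2L
  d <- dim(volume$voxels)
  nr <- d[2]; nc <- d[3]
  stats <- matrix(NA_real_, nrow(idx), length(LOCAL_STATS),
                  dimnames = list(NULL, LOCAL_STATS))
  n_zero_mean <- 0L
  for (sl in unique(idx[, "slice"])) {
    I <- volume$voxels[sl, , ]
    sel <- which(idx[, "slice"] == sl)
    r <- idx[sel, "row"]; cc <- idx[sel, "col"]
    full <- r > half & r <= nr - half & cc > half & cc <= nc - half
    if (any(full)) {
      rs <- r[full]; cs <- cc[full]
      offs <- expand.grid(dr = -half:half, dc = -half:half)
      W <- matrix(0, side * side, length(rs))
      for (j in seq_len(nrow(offs))) {
        W[j, ] <- I[cbind(rs + offs$dr[j], cs + offs$dc[j])]
      }
      st <- patch_stats_columns(W)
      n_zero_mean <- n_zero_mean + attr(st, "n_cv_zero_mean")
      stats[sel[full], ] <- st
    }
    for (j in which(!full)) {
      rr <- max(1, r[j] - half):min(nr, r[j] + half)
      rc <- max(1, cc[j] - half):min(nc, cc[j] + half)
      st <- local_first_order_stats(as.vector(I[rr, rc]))
      if (isTRUE(attr(st, "cv_zero_mean"))) n_zero_mean <- n_zero_mean + 1L
      stats[sel[j], ] <- st
    }
  }
  if (n_zero_mean > 0)
    warning(sprintf("CV set to 0 at %d patch(es) with zero mean", n_zero_mean))
  structure(list(coords = idx, stats = stats), class = "local_stat_maps")
}

#' @export
print.local_stat_maps <- function(x, ...) {
  cat(sprintf("local_stat_maps: %d ROI voxels x %d local statistics\n",
              nrow(x$stats), ncol(x$stats)))
  invisible(x)
}

# Twelve global summaries of one pooled local-statistic distribution.
global_summaries <- function(v) {
  fo <- local_first_order_stats(v)
  xs <- sort(v)
  q90 <- sorted_quantile(xs, 0.9)
  top <- xs[xs >= q90]
  med <- fo[["M"]]
  c(mean = fo[["m"]], M = med, s = fo[["s"]], k = fo[["k"]],
    iqr = fo[["iqr"]], CV = fo[["cv"]], e = fo[["e"]],
    max = xs[length(xs)], sigma = sqrt(mean((v - fo[["m"]])^2)),
    mad = stats::median(abs(v - med)),
    m90th = mean(top), M90th = stats::median(top))
}

#' Summarize local-statistic maps into the 84-feature vector
#'
#' Local distributions are pooled over all ROI voxels of all slices (and
#' all lesions) of the patient before summarization, so a patient with
#' multiple lesions still yields a single feature vector.
#'
#' @param maps A `local_stat_maps` object from [sweep_patches()].
#' @return Named numeric vector of the 84 features
#'   (see [radiomic_feature_names()]).
#' @export
summarize_global <- function(maps) {
  if (!inherits(maps, "local_stat_maps") || nrow(maps$stats) == 0L)
    abort("maps must be a nonempty local_stat_maps", "validation_error")
  out <- unlist(lapply(LOCAL_STATS, function(l) {
    g <- global_summaries(maps$stats[, l])
    names(g) <- paste(l, GLOBAL_STATS, sep = "_")
    g
  }))
  out[radiomic_feature_names()]
}

#' Extract the 84 radiomic features for one patient
#'
#' Composes [window_side_from_spacing()], [sweep_patches()] and
#' [summarize_global()]. Deterministic: the same volume/mask pair always
#' yields the same vector.
#'
#' @param volume An [image_volume()].
#' @param mask A congruent [lesion_mask()].
#' @param window_side Optional odd integer overriding the spacing-derived
#'   patch side.
#' @return Named numeric vector of 84 features.
#' @export
extract_features <- function(volume, mask, window_side = NULL) {
  side <- if (is.null(window_side)) {
    window_side_from_spacing(volume$pixel_spacing_mm[1])
  } else window_side
  summarize_global(sweep_patches(volume, mask, side))
}

#' Extract features for a whole cohort
#'
#' @param patients List of phantom patients (from [generate_cohort()]) or
#'   a manifest data frame with columns `patient_id`, `label`, `image`,
#'   `mask` (as written by [write_cohort()]).
#' @param window_side Optional odd integer override.
#' @return A [cohort_table()] with one row per patient.
#' @export
extract_cohort_features <- function(patients, window_side = NULL) {
  if (is.data.frame(patients)) {
    patients <- lapply(seq_len(nrow(patients)), function(i) {
      p <- read_patient(patients$image[i], patients$mask[i])
      list(volume = p$volume, mask = p$mask,
           label = patients$label[i], patient_id = patients$patient_id[i])
    })
  }
  feats <- t(vapply(patients,
                    function(p) extract_features(p$volume, p$mask, window_side),
                    numeric(84L)))
  cohort_table(vapply(patients, `[[`, character(1), "patient_id"),
               vapply(patients, `[[`, numeric(1), "label"),
               feats)
}

# Feature matrix / label helpers shared by downstream modules.
feature_matrix <- function(table) {
  X <- as.matrix(as.data.frame(table)[, radiomic_feature_names(), drop = FALSE])
  rownames(X) <- table$patient_id
  X
}
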