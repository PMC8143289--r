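# Phantom cohort generator. Two classes of lesions on a noisy background:
# non-significant lesions have a flat mean and symmetric noise; significant
# lesions add (a) a smooth random mean field (local-mean heterogeneity) and
# (b) right-skewed voxel noise (local-skewness asymmetry) -- the two tissue
# contrasts the downstream features m_sigma and s_M90th are designed to read.

#' Configuration of a synthetic phantom cohort
#'
#' Defaults emulate the acquisition geometry of 3T prostate DWI (in-plane
#' spacing within 1.41-1.67 mm, 3 mm slices). The default class effects
#' are sized so that the phantom reproduces the statistical structure the
#' downstream analysis assumes: single features separate the classes
#' markedly, yet uncorrelated discriminant feature couples still exist
#' (much stronger effects push the pooled correlation of every pair of
#' discriminant features above typical correlation-filter ceilings).
#' Signal values are arbitrary units with a background mean of 100.
#'
#' @param n_ncs,n_cs Number of non-significant / significant patients.
#' @param seed Integer seed; the same config and seed reproduce the cohort
#'   bit-exactly.
#' @param pixel_spacing_mm In-plane pixel spacing (isotropic), in
#'   `[1.41, 1.67]` mm.
#' @param slice_thickness_mm Slice thickness (mm).
#' @param slices_per_lesion Integer range `(min, max)` of lesion slices.
#' @param lesion_axes_mm Range the per-slice ellipse semi-axes are drawn
#'   from (mm).
#' @param background_mean,background_sd Background signal mean and SD.
#' @param lesion_mean Baseline lesion signal (hyperintense on high
#'   b-value DWI).
#' @param noise_sd SD of the lesion voxel noise.
#' @param heterogeneity_effect SD of the smooth spatially varying lesion
#'   mean field, added in the significant class only (>= 0).
#' @param asymmetry_effect Skewness of the lesion voxel noise in the
#'   significant class (>= 0; 0 = Gaussian).
#' @param grid_size In-plane grid side in pixels.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_ncs = 26, n_cs = 50, seed = 1,
                          pixel_spacing_mm = 1.5,
                          slice_thickness_mm = 3,
                          slices_per_lesion = c(3, 6),
                          lesion_axes_mm = c(4, 9),
                          background_mean = 100, background_sd = 10,
                          lesion_mean = 160, noise_sd = 15,
                          heterogeneity_effect = 15,
                          asymmetry_effect = 1.2,
                          grid_size = 48) {
  if (!is_count(n_ncs) || !is_count(n_cs))
    abort("n_ncs and n_cs must be positive integers", "config_error")
  if (!is_scalar_num(pixel_spacing_mm) || pixel_spacing_mm <= 0 ||
      !is_scalar_num(slice_thickness_mm) || slice_thickness_mm <= 0)
    abort("spatial parameters must be strictly positive", "config_error")
  if (length(slices_per_lesion) != 2L || any(slices_per_lesion < 1) ||
      slices_per_lesion[1] > slices_per_lesion[2])
    abort("slices_per_lesion must be an increasing positive range", "config_error")
  if (length(lesion_axes_mm) != 2L || any(lesion_axes_mm <= 0) ||
      lesion_axes_mm[1] > lesion_axes_mm[2])
    abort("lesion_axes_mm must be an increasing positive range", "config_error")
  if (heterogeneity_effect < 0 || asymmetry_effect < 0)
    abort("effects must be >= 0", "config_error")
  if (background_sd <= 0 || noise_sd <= 0)
    abort("noise parameters must be strictly positive", "config_error")
  if (!is_count(grid_size) || grid_size < 16)
    abort("grid_size must be an integer >= 16", "config_error")
  max_px <- lesion_axes_mm[2] / pixel_spacing_mm
  if (2 * max_px + 4 > grid_size)
    abort("lesion does not fit the grid: degenerate geometry", "config_error")
  structure(list(n_ncs = n_ncs, n_cs = n_cs, seed = as.integer(seed),
                 pixel_spacing_mm = pixel_spacing_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 slices_per_lesion = as.integer(slices_per_lesion),
                 lesion_axes_mm = lesion_axes_mm,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 lesion_mean = lesion_mean, noise_sd = noise_sd,
                 heterogeneity_effect = heterogeneity_effect,
                 asymmetry_effect = asymmetry_effect,
                 grid_size = as.integer(grid_size)),
            class = "cohort_config")
}

#' Zero-mean right-skewed noise (shifted log-normal)
#'
#' Samples from a log-normal shifted and scaled to have mean 0, standard
#' deviation `sd` and skewness `skewness`; `skewness = 0` falls back to a
#' Gaussian. Used for the lesion noise of the significant class.
#'
#' @param n Number of draws.
#' @param sd Target standard deviation.
#' @param skewness Target skewness (>= 0).
#' @return Numeric vector of length `n`.
#' @export
rskewnorm <- function(n, sd, skewness = 0) {
  if (skewness == 0) return(stats::rnorm(n, 0, sd))
  # lognormal skewness (w + 2) * sqrt(w - 1) with w = exp(sigma^2);
  # substituting t = sqrt(w - 1) gives the monotone cubic t^3 + 3 t.
  t <- stats::uniroot(function(t) t^3 + 3 * t - skewness,
                      c(0, max(2, skewness)), tol = 1e-12)$root
  w <- 1 + t^2
  sigma <- sqrt(log(w))
  scale <- sd / sqrt(w * (w - 1))
  scale * (exp(sigma * stats::rnorm(n)) - sqrt(w))
}

# Unit-variance smooth Gaussian random field on an nr x nc grid: white
# noise convolved with a separable Gaussian kernel of unit L2 norm, so the
# marginal variance stays exactly 1 while the correlation length is set by
# sigma_px.
smooth_gaussian_field <- function(nr, nc, sigma_px) {
  p <- max(1L, as.integer(ceiling(3 * sigma_px)))
  k <- stats::dnorm(-p:p, sd = sigma_px)
  k <- k / sqrt(sum(k^2))
  W <- matrix(stats::rnorm((nr + 2 * p) * (nc + 2 * p)), nr + 2 * p, nc + 2 * p)
  H <- matrix(0, nr, nc + 2 * p)
  for (j in seq_along(k))
    H <- H + k[j] * W[j:(j + nr - 1), , drop = FALSE]
  F_ <- matrix(0, nr, nc)
  for (j in seq_along(k))
    F_ <- F_ + k[j] * H[, j:(j + nc - 1), drop = FALSE]
  F_
}

# Per-slice elliptical ROI, shrinking toward the lesion's first/last slice.
lesion_mask_array <- function(config, n_slices, lesion_slices, center_rc, axes_px) {
  g <- config$grid_size
  m <- array(0, dim = c(n_slices, g, g))
  S <- length(lesion_slices)
  for (i in seq_len(S)) {
    u <- if (S == 1) 0 else (2 * i - S - 1) / S
    scl <- max(0.35, sqrt(max(0, 1 - u^2)))
    a <- max(0.71, axes_px[1] * scl)
    b <- max(0.71, axes_px[2] * scl)
    rr <- matrix(seq_len(g), g, g)
    cc <- matrix(seq_len(g), g, g, byrow = TRUE)
    inside <- ((rr - center_rc[1]) / a)^2 + ((cc - center_rc[2]) / b)^2 <= 1
    m[lesion_slices[i], , ] <- m[lesion_slices[i], , ] + inside
  }
  (m > 0) * 1
}

#' Generate a synthetic phantom cohort
#'
#' Returns `n_ncs + n_cs` phantom patients, non-significant first. Each
#' patient is one lesion spanning several slices of a noisy background
#' volume. Lesion voxels of the non-significant class are i.i.d. Gaussian
#' around a constant lesion mean; the significant class adds a smooth
#' random mean field with SD `heterogeneity_effect` (correlation length
#' about 5 mm, so the heterogeneity survives patch averaging) and replaces
#' the Gaussian noise with right-skewed noise of skewness
#' `asymmetry_effect`.
#'
#' @param config A [cohort_config()].
#' @return List of phantom patients, each a list with `volume`, `mask`,
#'   `label` (0 = non-significant, 1 = significant) and `patient_id`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    abort("config must be a cohort_config", "config_error")
  set.seed(config$seed)
  labels <- c(rep(0L, config$n_ncs), rep(1L, config$n_cs))
  sp <- config$pixel_spacing_mm
  sigma_field_px <- 2.5 / sp  # ~5 mm correlation length after convolution
  lapply(seq_along(labels), function(i) {
    lab <- labels[i]
    S <- sample(seq(config$slices_per_lesion[1], config$slices_per_lesion[2]), 1)
    n_slices <- S + 4L
    g <- config$grid_size
    vox <- array(stats::rnorm(n_slices * g * g, config$background_mean,
                              config$background_sd),
                 dim = c(n_slices, g, g))
    axes_px <- sort(stats::runif(2, config$lesion_axes_mm[1],
                                 config$lesion_axes_mm[2])) / sp
    center <- g / 2 + stats::runif(2, -2, 2)
    lesion_slices <- seq(3L, 2L + S)
    msk <- lesion_mask_array(config, n_slices, lesion_slices, center, axes_px)
    idx <- which(msk == 1, arr.ind = TRUE)
    nvox <- nrow(idx)
    vals <- config$lesion_mean + if (lab == 0L) {
      stats::rnorm(nvox, 0, config$noise_sd)
    } else {
      field <- numeric(nvox)
      if (config$heterogeneity_effect > 0) {
        for (sl in lesion_slices) {
          Fsl <- smooth_gaussian_field(g, g, sigma_field_px)
          here <- idx[, 1] == sl
          field[here] <- config$heterogeneity_effect *
            Fsl[idx[here, 2:3, drop = FALSE]]
        }
      }
      field + rskewnorm(nvox, config$noise_sd, config$asymmetry_effect)
    }
    vox[idx] <- vals
    list(volume = image_volume(vox, sp, config$slice_thickness_mm),
         mask = lesion_mask(msk),
         label = lab,
         patient_id = sprintf("P%03d", i))
  })
}

#' Write a phantom cohort to disk
#'
#' Writes one NIfTI image and one NIfTI mask per patient plus a CSV
#' manifest with header `patient_id,label,image,mask,spacing_mm`.
#'
#' @param patients List of phantom patients from [generate_cohort()].
#' @param directory Output directory (created if absent).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(patients, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(patients, function(p) {
    img <- file.path(directory, paste0(p$patient_id, "_image.nii.gz"))
    msk <- file.path(directory, paste0(p$patient_id, "_mask.nii.gz"))
    write_volume(p$volume, img)
    write_volume(p$mask, msk, geometry_from = p$volume)
    data.frame(patient_id = p$patient_id, label = p$label,
               image = img, mask = msk,
               spacing_mm = p$volume$pixel_spacing_mm[1],
               stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(patient_id = character(), label = integer(),
               image = character(), mask = character(),
               spacing_mm = numeric(), stringsAsFactors = FALSE)
  }
  path <- file.path(directory, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' @param path Manifest CSV written by [write_cohort()].
#' @return Data frame with columns `patient_id,label,image,mask,spacing_mm`.
#' @export
read_cohort_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "label", "image", "mask", "spacing_mm")
  if (!all(need %in% names(m)))
    abort("manifest lacks required columns", "schema_error")
  m
}
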