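#' Image volume container
#'
#' A minimal container for a scalar 3D image: a voxel array indexed as
#' `(slice, row, col)` plus in-plane pixel spacing and slice thickness in
#' millimetres. Signal values are kept in native units; no rescaling is
#' applied on construction.
#'
#' @param voxels 3D numeric array, indexed `(slice, row, col)`.
#' @param pixel_spacing_mm In-plane pixel spacing in mm; a single value
#'   (isotropic) or a pair `(row, col)`.
#' @param slice_thickness_mm Slice thickness in mm.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, pixel_spacing_mm, slice_thickness_mm = 3) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    abort("voxels must be a 3D array indexed (slice, row, col)", "geometry_error")
  if (!all(is.finite(voxels)))
    abort("voxels must be finite", "format_error")
  if (length(pixel_spacing_mm) == 1L)
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  if (length(pixel_spacing_mm) != 2L || any(!is.finite(pixel_spacing_mm)) ||
      any(pixel_spacing_mm <= 0))
    abort("pixel_spacing_mm must be positive", "config_error")
  if (!is_scalar_num(slice_thickness_mm) || slice_thickness_mm <= 0)
    abort("slice_thickness_mm must be a positive scalar", "config_error")
  structure(
    list(voxels = voxels,
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         slice_thickness_mm = as.numeric(slice_thickness_mm)),
    class = "image_volume")
}

#' Binary lesion mask aligned to an image volume
#'
#' @param voxels 3D array congruent with its parent [image_volume()]; any
#'   nonzero value is treated as inside the ROI.
#' @return An object of class `lesion_mask` with values in \{0, 1\}.
#' @export
lesion_mask <- function(voxels) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    abort("mask must be a 3D array indexed (slice, row, col)", "geometry_error")
  v <- array(as.numeric(voxels != 0), dim = dim(voxels))
  structure(list(voxels = v), class = "lesion_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_volume: %d slices x %d x %d, spacing %.3g x %.3g mm, thickness %.3g mm\n",
              d[1], d[2], d[3], x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              x$slice_thickness_mm))
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("lesion_mask: %d slices x %d x %d, %d ROI voxels\n",
              d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

check_congruent <- function(volume, mask) {
  if (!identical(dim(volume$voxels), dim(mask$voxels)))
    abort(sprintf("mask shape (%s) does not match image shape (%s)",
                  paste(dim(mask$voxels), collapse = "x"),
                  paste(dim(volume$voxels), collapse = "x")),
          "geometry_error")
  invisible(TRUE)
}

# internal (slice,row,col) <-> NIfTI (x=row, y=col, z=slice)
vol_to_nifti_array <- function(a) aperm(a, c(2, 3, 1))
nifti_to_vol_array <- function(a) aperm(a, c(3, 1, 2))

#' Write an image volume as NIfTI
#'
#' @param volume An [image_volume()] or [lesion_mask()] (masks are written
#'   with the geometry of `geometry_from`).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param geometry_from Optional `image_volume` supplying spacing when
#'   `volume` is a mask.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, geometry_from = NULL) {
  if (inherits(volume, "lesion_mask")) {
    if (is.null(geometry_from))
      abort("writing a mask requires geometry_from", "config_error")
    spacing <- geometry_from$pixel_spacing_mm
    thick <- geometry_from$slice_thickness_mm
    a <- volume$voxels
  } else {
    spacing <- volume$pixel_spacing_mm
    thick <- volume$slice_thickness_mm
    a <- volume$voxels
  }
  img <- RNifti::asNifti(vol_to_nifti_array(a))
  RNifti::pixdim(img) <- c(spacing[1], spacing[2], thick)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a patient's image and lesion mask
#'
#' Loads a NIfTI image/mask pair, checks geometric congruence and
#' binarizes the mask (any value > 0 becomes 1).
#'
#' @param image_path,mask_path NIfTI file paths.
#' @return A list with elements `volume` ([image_volume()]) and `mask`
#'   ([lesion_mask()]).
#' @export
read_patient <- function(image_path, mask_path) {
  img <- tryCatch(RNifti::readNifti(image_path),
                  error = function(e) abort(
                    sprintf("cannot read image '%s': %s", image_path, conditionMessage(e)),
                    "format_error"))
  msk <- tryCatch(RNifti::readNifti(mask_path),
                  error = function(e) abort(
                    sprintf("cannot read mask '%s': %s", mask_path, conditionMessage(e)),
                    "format_error"))
  pd_i <- RNifti::pixdim(img)
  pd_m <- RNifti::pixdim(msk)
  if (!identical(dim(img), dim(msk)))
    abort("image and mask have different shapes", "geometry_error")
  if (any(abs(pd_i - pd_m) > 1e-6))
    abort("image and mask have different voxel spacings", "geometry_error")
  volume <- image_volume(nifti_to_vol_array(as.array(img)),
                         pixel_spacing_mm = pd_i[1:2],
                         slice_thickness_mm = pd_i[3])
  mask <- lesion_mask(nifti_to_vol_array(as.array(msk)))
  check_congruent(volume, mask)
  list(volume = volume, mask = mask)
}

#' Assemble a cohort feature table
#'
#' One row per patient: `patient_id`, binary `label` (1 = clinically
#' significant), optional `partition` (`"train"`/`"test"`), then the 84
#' radiomic features in canonical column order.
#'
#' @param patient_id Character vector of unique ids.
#' @param label Integer 0/1 labels.
#' @param features Numeric matrix or data frame with the 84 feature
#'   columns named as in [radiomic_feature_names()].
#' @param partition Optional character vector (`"train"`/`"test"`, or NA).
#' @return A `data.frame` of class `cohort_table`.
#' @export
cohort_table <- function(patient_id, label, features, partition = NA_character_) {
  patient_id <- as.character(patient_id)
  if (anyDuplicated(patient_id))
    abort("duplicate patient_id", "validation_error")
  if (!all(label %in% c(0, 1)))
    abort("labels must be 0/1", "validation_error")
  features <- as.data.frame(features)
  missing <- setdiff(radiomic_feature_names(), names(features))
  if (length(missing))
    abort(sprintf("missing feature columns: %s", paste(missing, collapse = ", ")),
          "schema_error")
  partition <- rep_len(as.character(partition), length(patient_id))
  tab <- data.frame(patient_id = patient_id, label = as.integer(label),
                    partition = partition,
                    features[, radiomic_feature_names(), drop = FALSE],
                    stringsAsFactors = FALSE, check.names = FALSE)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Write / read a cohort feature table as CSV
#'
#' Values round-trip losslessly to at least 12 significant digits.
#'
#' @param table A [cohort_table()].
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a `cohort_table`.
#' @export
write_feature_table <- function(table, path) {
  out <- as.data.frame(table)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.15g", x))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("patient_id", "label"))
    if (!col %in% names(raw))
      abort(sprintf("feature table lacks column '%s'", col), "schema_error")
  if (!"partition" %in% names(raw)) raw$partition <- NA_character_
  raw$partition[raw$partition %in% c("", "NA")] <- NA_character_
  missing <- setdiff(radiomic_feature_names(), names(raw))
  if (length(missing))
    abort(sprintf("missing feature columns: %s", paste(missing, collapse = ", ")),
          "schema_error")
  cohort_table(raw$patient_id, raw$label,
               raw[, radiomic_feature_names(), drop = FALSE],
               partition = raw$partition)
}

#' Serialize fitted models and evaluation reports as JSON
#'
#' @param x A fitted model (from [filter_and_select()]) or an evaluation
#'   report (from [evaluate_scores()]).
#' @param path JSON path.
#' @return `path` invisibly; readers return the restored object.
#' @export
write_model_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$weights <- as.numeric(m$weights)
  class(m) <- "locrad_model"
  m
}

#' @rdname write_model_json
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_report_json <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(r) <- "locrad_report"
  r
}
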