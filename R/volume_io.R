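# Core volume data types and file I/O (NIfTI volumes/masks, CSV feature
# tables, JSON reports).

#' Construct an SUV volume
#'
#' An `suv_volume` holds a 3D scalar field of standardized uptake values
#' together with its voxel dimensions in millimetres. The third array index
#' is the axial (slice) axis throughout the package.
#'
#' @param values Numeric 3D array of SUVs; all values must be finite and
#'   non-negative.
#' @param voxel_size Numeric vector of length 3, voxel edge lengths in mm
#'   (x, y, z); all components must be positive.
#' @return An object of class `suv_volume` with elements `values` and
#'   `voxel_size`.
#' @export
suv_volume <- function(values, voxel_size = c(4, 4, 4)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array (x, y, axial slice)")
  if (any(!is.finite(values)))
    stop("SUV values must all be finite")
  if (any(values < 0))
    stop("SUV values must be non-negative")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive lengths (mm)")
  d <- dim(values)
  if (d[3] < 1L || d[1] < 2L || d[2] < 2L)
    stop("volume needs at least 1 axial slice of at least 2x2 voxels")
  structure(list(values = values, voxel_size = voxel_size),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("SUV volume: %d x %d x %d voxels (%g x %g x %g mm), SUV range [%g, %g]\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], min(x$values), max(x$values)))
  invisible(x)
}

#' Read an SUV volume from a NIfTI file
#'
#' Voxel dimensions are taken from the NIfTI header (`pixdim`). The data
#' must be 3D; the third axis is interpreted as axial.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An [suv_volume()].
#' @export
read_suv_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("NIfTI data must be 3D, got ", length(d), " dimensions in ", path)
  vox <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(vox)) || any(vox <= 0))
    stop("NIfTI header has non-positive voxel size in ", path)
  vals <- array(as.numeric(img), dim = d)
  suv_volume(vals, vox)
}

#' Write an SUV volume to a NIfTI file
#'
#' @param volume An [suv_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_suv_volume <- function(volume, path) {
  stopifnot(inherits(volume, "suv_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from a NIfTI file
#'
#' Any nonzero voxel reads as `TRUE`. If `reference` is supplied, the mask
#' shape is checked against the companion volume.
#'
#' @param path Path to a `.nii`/`.nii.gz` mask (stored as 0/1 integers).
#' @param reference Optional [suv_volume()] whose shape the mask must match.
#' @return A logical 3D array.
#' @export
read_mask <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("mask NIfTI data must be 3D, got ", length(d), " dimensions")
  m <- array(as.numeric(img) != 0, dim = d)
  if (!is.null(reference) && !identical(dim(m), dim(reference$values)))
    stop("mask shape does not match companion volume")
  m
}

#' Write a binary mask to a NIfTI file
#'
#' @param mask Logical 3D array.
#' @param path Output path.
#' @param voxel_size Voxel dimensions in mm written to the header.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, voxel_size = c(4, 4, 4)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Bundle a study's volume, masks and acquisition mode
#'
#' A study fixture bundles the per-study inputs of the pipeline: the SUV
#' volume, the reference gross tumour volume (GTV) mask, a background-region
#' mask used by the contrast-oriented baseline, and the acquisition mode.
#'
#' @param volume An [suv_volume()].
#' @param gtv Logical 3D array, the GTV mask (must be non-empty).
#' @param background Logical 3D array, the background-region mask (must be
#'   disjoint from `gtv`).
#' @param mode `"gated"` or `"free_breathing"`.
#' @param study_id Character study identifier.
#' @param truth Optional list of ground-truth generation parameters (set by
#'   the phantom generator).
#' @return An object of class `study_fixture`.
#' @export
study_fixture <- function(volume, gtv, background, mode = c("gated", "free_breathing"),
                          study_id = "study", truth = NULL) {
  stopifnot(inherits(volume, "suv_volume"))
  mode <- match.arg(mode)
  if (!identical(dim(gtv), dim(volume$values)))
    stop("GTV mask shape does not match volume")
  if (!identical(dim(background), dim(volume$values)))
    stop("background mask shape does not match volume")
  if (!any(gtv)) stop("GTV mask is empty")
  if (any(gtv & background))
    stop("GTV and background masks must be disjoint")
  structure(list(volume = volume, gtv = gtv, background = background,
                 mode = mode, study_id = study_id, truth = truth),
            class = "study_fixture")
}

#' @export
print.study_fixture <- function(x, ...) {
  cat(sprintf("Study '%s' (%s): %d GTV voxels, %d background voxels\n",
              x$study_id, x$mode, sum(x$gtv), sum(x$background)))
  print(x$volume)
  invisible(x)
}

# canonical feature-table column order
.feature_cols <- c("area_010", "mean_010", "area_015", "mean_015",
                   "area_020", "mean_020")
.table_cols <- c("study_id", "slice_index", "is_tumour", .feature_cols,
                 "reference_threshold", "slice_max", "best_jaccard")

#' Write a labelled-slice feature table to CSV
#'
#' One row per selected slice: study id, slice index, tumour flag, the six
#' attributes in canonical order (`area_010, mean_010, area_015, mean_015,
#' area_020, mean_020`), the reference threshold, plus the slice maximum SUV
#' and the best Jaccard achieved during labelling (diagnostics).
#'
#' @param records Data frame of slice records, e.g. from
#'   [build_labelled_instances()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a non-empty data frame of slice records")
  missing_cols <- setdiff(.table_cols, names(records))
  if (length(missing_cols))
    stop("records lack columns: ", paste(missing_cols, collapse = ", "))
  if (length(unique(records$study_id)) != 1L)
    stop("all records must come from a single study")
  utils::write.csv(records[, .table_cols], path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a labelled-slice feature table from CSV
#'
#' @param path CSV path written by [write_feature_table()].
#' @return Data frame with the canonical columns.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(.table_cols, names(df))
  if (length(missing_cols))
    stop("feature table lacks columns: ", paste(missing_cols, collapse = ", "))
  df$is_tumour <- as.logical(df$is_tumour)
  df[, .table_cols]
}

#' Write a study evaluation report to JSON
#'
#' Serializes a `study_report` (see [evaluate_study()]) losslessly: numbers
#' are written at full precision so metric fields survive a round-trip.
#'
#' @param report A `study_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a study evaluation report from JSON
#'
#' @param path JSON path written by [write_report()].
#' @return A `study_report` list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  structure(rep, class = "study_report")
}

#' Save a trained threshold model
#'
#' Writes the model as an opaque RDS blob plus a human-readable JSON sidecar
#' (`<path>.json`) with the selected hyperparameters, feature-scaling
#' statistics, training-set size and CV score.
#'
#' @param model A `threshold_model` from [train_threshold_model()].
#' @param path Output path for the model blob.
#' @return `path`, invisibly.
#' @export
save_threshold_model <- function(model, path) {
  stopifnot(inherits(model, "threshold_model"))
  saveRDS(model, path)
  sidecar <- list(nu = model$nu, cost = model$cost, gamma = model$gamma,
                  cv_mse = model$cv_mse, n_train = model$n_train,
                  constant = model$constant,
                  feature_mean = as.list(model$center),
                  feature_sd = as.list(model$scale))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a trained threshold model
#' @param path Path written by [save_threshold_model()].
#' @return A `threshold_model`.
#' @export
load_threshold_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "threshold_model"))
  model
}
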