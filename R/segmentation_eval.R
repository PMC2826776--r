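# Evaluation: Jaccard overlap, Pearson correlation of thresholds, the
# contrast-oriented baseline, repeated 75/25 random-split evaluation.

#' Jaccard similarity of two voxel sets
#'
#' `J = |R intersect A| / |R union A|`: 1 when the regions match perfectly,
#' 0 when they share no voxel. Conventions for degenerate inputs: both
#' empty gives 1 (two empty contours agree), exactly one empty gives 0.
#'
#' @param r,a Logical arrays of identical shape.
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard <- function(r, a) {
  if (!identical(dim(r), dim(a)))
    stop("region shapes differ")
  uni <- sum(r | a)
  if (uni == 0L) return(1)
  sum(r & a) / uni
}

#' Pearson correlation between reference and predicted thresholds
#'
#' @param ref,pred Numeric vectors of equal length (at least 2). A constant
#'   vector on either side makes the correlation undefined and is reported
#'   as an error rather than silently coerced to 0.
#' @return Sample Pearson correlation coefficient.
#' @export
pearson_correlation <- function(ref, pred) {
  if (length(ref) != length(pred) || length(ref) < 2L)
    stop("need two equal-length vectors with at least 2 entries")
  if (stats::sd(ref) < .Machine$double.eps ||
      stats::sd(pred) < .Machine$double.eps)
    stop("undefined correlation: constant input vector")
  stats::cor(ref, pred)
}

#' Contrast-oriented baseline threshold
#'
#' The published contrast-oriented rule: threshold = mean background SUV
#' + 0.15 x SUV_70. It is constant across the slices of a study — the
#' structural contrast with the per-slice learned thresholds.
#'
#' @param suv70 Study-level SUV_70 (positive).
#' @param mean_background Mean SUV over the background region
#'   (non-negative).
#' @return The baseline SUV threshold.
#' @export
contrast_oriented_threshold <- function(suv70, mean_background) {
  if (!is.finite(suv70) || suv70 <= 0) stop("suv70 must be positive")
  if (!is.finite(mean_background) || mean_background < 0)
    stop("mean_background must be non-negative")
  mean_background + 0.15 * suv70
}

#' Random 75/25 train/test split of slice records
#'
#' A seeded uniform random permutation; the training set takes
#' `floor(train_fraction * N)` records and the remainder forms the test
#' set. Both sides must be non-empty.
#'
#' @param records Data frame of slice records (at least 2 rows).
#' @param train_fraction Fraction assigned to training (default 0.75).
#' @param seed Integer seed.
#' @return List with integer row-index vectors `train` and `test`.
#' @export
random_split <- function(records, train_fraction = 0.75, seed = 1L) {
  n <- nrow(records)
  if (is.null(n) || n < 2L) stop("need at least 2 records to split")
  n_train <- floor(train_fraction * n)
  if (n_train < 1L || n_train >= n)
    stop("split would leave an empty training or test set")
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[(n_train + 1L):n]))
}

# Pooled 3D region over the test slices: contour each test slice at its
# per-slice threshold and stack.
.pooled_region <- function(volume, slice_index, thresholds) {
  d <- dim(volume$values)
  reg <- array(FALSE, c(d[1], d[2], length(slice_index)))
  for (i in seq_along(slice_index))
    reg[, , i] <- threshold_region(volume$values[, , slice_index[i]],
                                   thresholds[i])
  reg
}

#' Repeated random-split evaluation of a study
#'
#' The full intra-study experiment: the labelled slices are split 75/25 at
#' random; the nu-SVR is trained on the training part and predicts SUV
#' thresholds for the test slices; test slices are contoured at the
#' predicted, reference and contrast-oriented baseline thresholds. Per
#' split, the report records the Pearson correlation between reference and
#' predicted thresholds and the pooled Jaccard (union of test-slice
#' reference regions against the union of predicted regions, and likewise
#' for the baseline), plus per-slice mean Jaccards as secondary metrics.
#' The split/train/evaluate cycle is repeated `n_repeats` times (per-repeat
#' seeds are `seed + split_id`) and the metrics averaged.
#'
#' If the reference thresholds of a test set are constant, that split's
#' correlation is undefined: it is recorded as `NA`, excluded from the
#' average, and a warning is raised.
#'
#' @param study A [study_fixture()].
#' @param config A [learner_config()].
#' @param n_repeats Number of random splits (default 5).
#' @param seed Master integer seed; per-repeat seeds derive from it.
#' @param n_free Number of adjacent tumour-free slices (default 8).
#' @param include_tumour_free Include tumour-free test slices in the
#'   Jaccard pooling (default `TRUE`; they enter under the empty-region
#'   conventions of [jaccard()]).
#' @param records Optional precomputed labelled instances (skips
#'   relabelling).
#' @param predictor Optional override for testing: a
#'   `function(train_records, test_records)` returning predicted
#'   thresholds for the test records in place of the trained model.
#' @return A `study_report` with per-split results and averages.
#' @export
evaluate_study <- function(study, config = learner_config(), n_repeats = 5L,
                           seed = 1L, n_free = 8L,
                           include_tumour_free = TRUE,
                           records = NULL, predictor = NULL) {
  stopifnot(inherits(study, "study_fixture"))
  if (is.null(records))
    records <- build_labelled_instances(study, n_free = n_free)
  stats <- global_uptake_stats(study$volume)
  mean_bg <- mean(study$volume$values[study$background])
  t_base <- contrast_oriented_threshold(stats$suv70, mean_bg)

  splits <- vector("list", n_repeats)
  for (s in seq_len(n_repeats)) {
    rs <- seed + s
    sp <- random_split(records, seed = rs)
    train <- records[sp$train, , drop = FALSE]
    test <- records[sp$test, , drop = FALSE]
    if (is.null(predictor)) {
      cfg <- config; cfg$seed <- rs
      model <- train_threshold_model(train, cfg)
      pred <- predict_threshold(model, test, test$slice_max)
    } else {
      pred <- pmin(pmax(predictor(train, test), 0), test$slice_max)
    }
    r <- tryCatch(pearson_correlation(test$reference_threshold, pred),
                  error = function(e) {
                    warning("split ", s, ": ", conditionMessage(e))
                    NA_real_
                  })
    keep <- if (include_tumour_free) rep(TRUE, nrow(test)) else test$is_tumour
    ti <- test$slice_index[keep]
    ref_reg <- .pooled_region(study$volume, ti, test$reference_threshold[keep])
    svm_reg <- .pooled_region(study$volume, ti, pred[keep])
    bas_reg <- .pooled_region(study$volume, ti, rep(t_base, sum(keep)))
    j_slice_svm <- vapply(seq_len(dim(ref_reg)[3]), function(i)
      jaccard(ref_reg[, , i], svm_reg[, , i]), numeric(1))
    j_slice_bas <- vapply(seq_len(dim(ref_reg)[3]), function(i)
      jaccard(ref_reg[, , i], bas_reg[, , i]), numeric(1))
    splits[[s]] <- list(
      split_id = s,
      train_indices = records$slice_index[sp$train],
      test_indices = records$slice_index[sp$test],
      pearson_r = r,
      jaccard_svm = jaccard(ref_reg, svm_reg),
      jaccard_baseline = jaccard(ref_reg, bas_reg),
      jaccard_svm_slice_mean = mean(j_slice_svm),
      jaccard_baseline_slice_mean = mean(j_slice_bas),
      predicted = as.numeric(pred),
      reference = as.numeric(test$reference_threshold))
  }
  get_num <- function(field) vapply(splits, `[[`, numeric(1), field)
  r_all <- get_num("pearson_r")
  structure(list(
    study_id = study$study_id,
    mode = study$mode,
    n_slices = nrow(records),
    n_tumour = sum(records$is_tumour),
    suv_max = stats$suv_max,
    suv70 = stats$suv70,
    mean_background = mean_bg,
    baseline_threshold = t_base,
    splits = splits,
    pearson_r = mean(r_all[!is.na(r_all)]),
    jaccard_svm = mean(get_num("jaccard_svm")),
    jaccard_baseline = mean(get_num("jaccard_baseline")),
    jaccard_svm_slice_mean = mean(get_num("jaccard_svm_slice_mean")),
    jaccard_baseline_slice_mean = mean(get_num("jaccard_baseline_slice_mean")),
    config = unclass(config),
    n_repeats = n_repeats,
    include_tumour_free = include_tumour_free,
    seed = seed), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study '%s' (%s): %d slices (%d tumour), %d random splits\n",
              x$study_id, x$mode, x$n_slices, x$n_tumour,
              length(x$splits)))
  cat(sprintf("  correlation (ref vs svm):   %.3f\n", x$pearson_r))
  cat(sprintf("  Jaccard     (ref vs svm):   %.3f\n", x$jaccard_svm))
  cat(sprintf("  Jaccard     (ref vs baseline): %.3f\n", x$jaccard_baseline))
  invisible(x)
}
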