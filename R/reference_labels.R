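# Reference threshold (label) assignment: best-Jaccard threshold search for
# tumour slices, slice maximum for tumour-free slices.

#' Best-matching SUV threshold for a tumour slice
#'
#' Finds the threshold whose superlevel-set region most closely matches the
#' GTV cross-section on this slice, measured by the Jaccard index. The
#' default candidate set is the sorted unique positive voxel values of the
#' slice, which covers every distinct superlevel set the slice admits, so
#' the returned threshold is globally optimal over all thresholds. Ties are
#' broken toward the smallest threshold (the more inclusive contour).
#'
#' This purely geometric optimum is the reproducible surrogate for a
#' clinician-chosen reference threshold; the achieved Jaccard is returned
#' as a diagnostic (a low value flags a cross-section no superlevel set can
#' approximate well).
#'
#' @param slice Numeric matrix of SUVs with at least one positive voxel.
#' @param gtv_slice Logical matrix, the (non-empty) GTV cross-section.
#' @param candidates Optional numeric vector of candidate thresholds;
#'   default: sorted unique positive slice values.
#' @return List with `threshold` (SUV) and `jaccard` (achieved overlap).
#' @export
best_threshold <- function(slice, gtv_slice, candidates = NULL) {
  if (!identical(dim(slice), dim(gtv_slice)))
    stop("slice and GTV slice shapes differ")
  n_gtv <- sum(gtv_slice)
  if (n_gtv == 0L)
    stop("empty GTV cross-section: slice should not be labelled as tumour")
  if (max(slice) <= 0)
    stop("slice has no positive voxel")
  if (is.null(candidates)) {
    # Sort voxels descending once; as the threshold sweeps down through the
    # unique values, the region grows by the tied block at each value, so
    # region size and GTV intersection are running prefix statistics.
    ord <- order(slice, decreasing = TRUE)
    v <- slice[ord]
    g <- cumsum(gtv_slice[ord])
    sz <- seq_along(v)
    last <- rev(!duplicated(rev(v)))        # last position of each tied block
    keep <- last & v > 0
    t_cand <- v[keep]
    inter <- g[keep]
    size <- sz[keep]
    jac <- inter / (size + n_gtv - inter)
  } else {
    candidates <- sort(unique(as.numeric(candidates)))
    t_cand <- candidates
    jac <- vapply(candidates, function(t)
      jaccard(threshold_region(slice, t), gtv_slice), numeric(1))
  }
  best <- max(jac)
  # among maximizers, smallest threshold
  thr <- min(t_cand[jac >= best - 1e-12 * max(1, best)])
  i <- which(t_cand == thr)[1]
  list(threshold = thr, jaccard = jac[i])
}

#' Reference threshold for a tumour-free slice
#'
#' The slice maximum SUV: contouring the slice at this threshold keeps only
#' the hottest voxel(s), the most nearly empty region the inclusive
#' comparator admits.
#'
#' @param slice Numeric matrix of SUVs.
#' @return The maximum SUV of the slice.
#' @export
reference_threshold_free <- function(slice) {
  if (length(slice) == 0L) stop("empty slice")
  max(slice)
}

#' Build the labelled slice instances for a study
#'
#' Runs slice selection, attribute extraction and label assignment for one
#' study: each selected slice yields a row holding the six attributes
#' (feature vector) and the reference SUV threshold (label). Tumour slices
#' are labelled by [best_threshold()] against the GTV cross-section;
#' tumour-free slices by [reference_threshold_free()].
#'
#' @param study A [study_fixture()].
#' @param n_free Number of adjacent tumour-free slices (default 8).
#' @param candidates Optional candidate threshold vector passed to
#'   [best_threshold()].
#' @return Data frame ordered by slice index with columns `study_id`,
#'   `slice_index`, `is_tumour`, the six attributes, `reference_threshold`,
#'   `slice_max` and `best_jaccard` (`NA` for tumour-free slices).
#' @export
build_labelled_instances <- function(study, n_free = 8L, candidates = NULL) {
  stopifnot(inherits(study, "study_fixture"))
  vol <- study$volume
  stats <- global_uptake_stats(vol)
  sel <- select_slices(study$gtv, n_free = n_free)
  sel <- sel[order(sel$slice_index), , drop = FALSE]
  rows <- lapply(seq_len(nrow(sel)), function(i) {
    k <- sel$slice_index[i]
    sl <- vol$values[, , k]
    att <- slice_attributes(sl, stats, vol$voxel_size)
    if (sel$is_tumour[i]) {
      lab <- best_threshold(sl, study$gtv[, , k], candidates = candidates)
      thr <- lab$threshold; bj <- lab$jaccard
    } else {
      thr <- reference_threshold_free(sl); bj <- NA_real_
    }
    data.frame(study_id = study$study_id, slice_index = k,
               is_tumour = sel$is_tumour[i], as.data.frame(att),
               reference_threshold = thr, slice_max = max(sl),
               best_jaccard = bj)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
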