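# Global uptake statistics, superlevel-set regions, the six per-slice
# attributes, and slice selection.

#' Global uptake statistics: SUV_max and SUV_70
#'
#' `SUV_max` is the maximum SUV over the full 3D volume. `SUV_70` is the
#' mean SUV of all voxels at or above 70% of `SUV_max` — the "70% SUV_max
#' 3D contour", taken globally over the study with no connectivity
#' restriction. SUV_70 drives the attribute contours because it is less
#' noise-sensitive than the single hottest voxel.
#'
#' @param volume An [suv_volume()] with at least one positive voxel.
#' @return List with elements `suv_max` and `suv70`.
#' @export
global_uptake_stats <- function(volume) {
  stopifnot(inherits(volume, "suv_volume"))
  v <- volume$values
  suv_max <- max(v)
  if (suv_max <= 0)
    stop("degenerate input: volume has no positive voxel")
  suv70 <- mean(v[v >= 0.7 * suv_max])
  list(suv_max = suv_max, suv70 = suv70)
}

#' Superlevel-set region of a slice at a threshold
#'
#' The region at threshold `t` is the set of voxels whose SUV is greater
#' than or equal to `t` (inclusive comparator). No connected-component
#' filtering is applied: a region may consist of several disjoint contours.
#'
#' @param slice Numeric 2D matrix of SUVs.
#' @param t Non-negative SUV threshold.
#' @return Logical matrix of the same shape.
#' @export
threshold_region <- function(slice, t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("'t' must be a single non-negative SUV")
  slice >= t
}

#' Area of a 2D region in mm^2
#'
#' @param mask Logical matrix.
#' @param voxel_size Voxel dimensions in mm; the first two (in-plane)
#'   components are used. Pass `c(1, 1, 1)` for an area in voxel counts.
#' @return Area in mm^2 (count of true voxels times in-plane voxel area).
#' @export
region_area <- function(mask, voxel_size = c(4, 4, 4)) {
  sum(mask) * voxel_size[1] * voxel_size[2]
}

#' Mean SUV inside a 2D region
#'
#' Returns 0 for an empty region (sentinel convention): tumour-free slices
#' far from the tumour then still yield a complete six-attribute vector.
#'
#' @param slice Numeric matrix of SUVs.
#' @param mask Logical matrix of the same shape.
#' @return Mean SUV over the region, or 0 if the region is empty.
#' @export
region_mean <- function(slice, mask) {
  if (!identical(dim(slice), dim(mask)))
    stop("slice and mask shapes differ")
  n <- sum(mask)
  if (n == 0L) return(0)
  sum(slice[mask]) / n
}

#' The six per-slice uptake attributes
#'
#' For each fraction f in {0.10, 0.15, 0.20}, the area (mm^2) and mean SUV
#' inside the superlevel-set region at threshold f x SUV_70. The three
#' contours describe, roughly, the tumour plus surroundings (0.10), the
#' tumour (0.15), and the hottest tumour core (0.20), so together they
#' capture the interplay between uptake level and cross-section size.
#'
#' @param slice Numeric matrix, one axial PET slice.
#' @param stats Global stats from [global_uptake_stats()] of the same study.
#' @param voxel_size Voxel dimensions in mm.
#' @return Named list `area_010, mean_010, area_015, mean_015, area_020,
#'   mean_020`.
#' @export
slice_attributes <- function(slice, stats, voxel_size = c(4, 4, 4)) {
  out <- list()
  for (f in c(0.10, 0.15, 0.20)) {
    m <- threshold_region(slice, f * stats$suv70)
    tag <- sprintf("%03d", round(f * 100))
    out[[paste0("area_", tag)]] <- region_area(m, voxel_size)
    out[[paste0("mean_", tag)]] <- region_mean(slice, m)
  }
  out[c("area_010", "mean_010", "area_015", "mean_015",
        "area_020", "mean_020")]
}

#' Select the axial slices entering the dataset
#'
#' All slices intersecting the GTV are selected and flagged as tumour
#' slices, together with `n_free` adjacent tumour-free slices split as
#' evenly as possible between the inferior and superior sides (default
#' 4 + 4). When the tumour touches a volume end, the shortfall is taken
#' from the other side (with a warning).
#'
#' @param gtv Logical 3D array, the GTV mask (third axis = axial).
#' @param n_free Number of adjacent tumour-free slices to add (default 8).
#' @return Data frame with columns `slice_index` (1-based, ascending) and
#'   `is_tumour`.
#' @export
select_slices <- function(gtv, n_free = 8L) {
  stopifnot(is.array(gtv), length(dim(gtv)) == 3L)
  n_free <- as.integer(n_free)
  tum <- which(apply(gtv, 3, any))
  if (length(tum) == 0L) stop("GTV mask is empty")
  lo <- min(tum); hi <- max(tum)
  nz <- dim(gtv)[3]
  avail_inf <- lo - 1L
  avail_sup <- nz - hi
  if (avail_inf + avail_sup < n_free)
    stop("volume has fewer than ", n_free, " tumour-free slices adjacent to the GTV")
  want_inf <- n_free %/% 2L
  want_sup <- n_free - want_inf
  take_inf <- min(want_inf, avail_inf)
  take_sup <- min(want_sup, avail_sup)
  short <- n_free - take_inf - take_sup
  if (short > 0L) {
    warning("tumour touches a volume end; taking ", short,
            " extra tumour-free slice(s) from the other side")
    if (take_inf < want_inf) take_sup <- take_sup + short
    else take_inf <- take_inf + short
  }
  idx <- c(seq.int(lo - take_inf, lo - 1L, length.out = take_inf),
           tum,
           seq.int(hi + 1L, hi + take_sup, length.out = take_sup))
  idx <- as.integer(idx)
  data.frame(slice_index = idx,
             is_tumour = idx %in% tum)
}
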