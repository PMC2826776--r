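# Shared fixtures built in code: a small, fast phantom and synthetic
# labelled-record tables for learner tests.

# 24^3 grid, 4 mm voxels, 9 tumour slices: every pipeline stage runs in
# well under a second on it.
small_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(grid_shape = c(24, 24, 24),
               tumour = list(tumour_component(centre = c(46, 46, 46),
                                              semi_axes = c(14, 14, 18))),
               seed = seed, ...)
}

# labelled records whose label is a known function of the attributes
make_records <- function(n, label_fn, seed = 1L, study_id = "synthetic") {
  set.seed(seed)
  area15 <- runif(n, 100, 2000)
  df <- data.frame(
    study_id = study_id,
    slice_index = seq_len(n),
    is_tumour = rep(c(TRUE, FALSE), length.out = n),
    area_010 = area15 * 1.5 + runif(n, 0, 50),
    mean_010 = runif(n, 1, 2),
    area_015 = area15,
    mean_015 = runif(n, 2, 3),
    area_020 = area15 * 0.5,
    mean_020 = runif(n, 3, 4))
  df$reference_threshold <- label_fn(df)
  df$slice_max <- pmax(df$reference_threshold, 5) + 1
  df$best_jaccard <- ifelse(df$is_tumour, 1, NA_real_)
  df
}

# random SUV slice with a hot blob, for oracle comparisons
random_blob_slice <- function(nx = 12, ny = 12, seed = 1L) {
  set.seed(seed)
  cx <- runif(1, 4, nx - 3); cy <- runif(1, 4, ny - 3)
  r <- runif(1, 2, 4)
  d <- outer(seq_len(nx), seq_len(ny),
             function(i, j) sqrt((i - cx)^2 + (j - cy)^2))
  pmax(5 * exp(-(d / r)^2) + matrix(rnorm(nx * ny, 0.5, 0.15), nx), 0)
}
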