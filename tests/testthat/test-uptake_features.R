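test_that("global uptake statistics match hand enumerations", {
  # uniform field: both statistics equal the constant
  expect_equal(global_uptake_stats(suv_volume(array(5, c(4, 4, 2)))),
               list(suv_max = 5, suv70 = 5))
  # one hot voxel at 10 among 1s: only the hot voxel passes 7
  v <- array(1, c(4, 4, 2)); v[2, 3, 1] <- 10
  expect_equal(global_uptake_stats(suv_volume(v)),
               list(suv_max = 10, suv70 = 10))
  # 8 voxels {10..3}: threshold 7, members {10,9,8,7}, mean 8.5
  v8 <- array(c(10, 9, 8, 7, 6, 5, 4, 3), c(2, 2, 2))
  expect_equal(global_uptake_stats(suv_volume(v8)),
               list(suv_max = 10, suv70 = 8.5))
  expect_error(global_uptake_stats(suv_volume(array(0, c(4, 4, 2)))),
               "degenerate")
})

test_that("global uptake statistics agree with a brute-force two-pass loop", {
  for (s in 1:20) {
    set.seed(s)
    d <- sample(4:16, 3, replace = TRUE)
    v <- array(runif(prod(d), 0, 12), d)
    st <- global_uptake_stats(suv_volume(v))
    # independent oracle: explicit loops over every voxel
    mx <- -Inf
    for (val in v) if (val > mx) mx <- val
    tot <- 0; n <- 0
    for (val in v) if (val >= 0.7 * mx) { tot <- tot + val; n <- n + 1 }
    expect_equal(st$suv_max, mx)
    expect_equal(st$suv70, tot / n)
    expect_gte(st$suv70, 0.7 * st$suv_max)
    expect_lte(st$suv70, st$suv_max)
  }
})

test_that("threshold regions are inclusive superlevel sets and nest monotonely", {
  sl <- matrix(runif(64, 0.1, 5), 8)
  expect_true(all(threshold_region(sl, 0)))
  expect_false(any(threshold_region(sl, max(sl) + 1)))
  expect_error(threshold_region(sl, -1), "non-negative")
  # voxels exactly at the threshold are included
  sl2 <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(sum(threshold_region(sl2, 3)), 2L)
  for (s in 1:25) {
    sl <- random_blob_slice(10, 10, seed = s)
    t1 <- runif(1, 0, max(sl)); t2 <- runif(1, t1, max(sl) + 0.5)
    r1 <- threshold_region(sl, t1); r2 <- threshold_region(sl, t2)
    expect_true(all(r1[r2]))  # region(t2) subset of region(t1)
  }
})

test_that("region area and mean match direct arithmetic", {
  m <- matrix(FALSE, 10, 10); m[1:4, 1:5] <- TRUE
  expect_equal(region_area(m, c(4, 4, 4)), 20 * 16)
  expect_equal(region_area(matrix(FALSE, 5, 5)), 0)
  expect_equal(region_area(matrix(TRUE, 144, 144), c(4, 4, 4)), 331776)
  sl <- matrix(c(2, 2, 1, 1), 2)
  expect_equal(region_mean(sl, matrix(TRUE, 2, 2)), 1.5)
  expect_equal(region_mean(sl, matrix(FALSE, 2, 2)), 0)
  expect_error(region_mean(sl, matrix(TRUE, 3, 3)), "differ")
  for (s in 1:25) {
    sl <- random_blob_slice(9, 11, seed = s)
    msk <- matrix(runif(99) > 0.6, 9, 11)
    tot <- 0; n <- 0
    for (i in 1:9) for (j in 1:11) if (msk[i, j]) { tot <- tot + sl[i, j]; n <- n + 1 }
    expect_equal(region_mean(sl, msk), if (n) tot / n else 0)
  }
})

test_that("slice attributes follow hand-enumerated contours in canonical order", {
  # single-level disk: all three thresholds fall below the disk value
  sl <- matrix(0, 10, 10); sl[3:6, 3:7] <- 5
  att <- slice_attributes(sl, list(suv_max = 10, suv70 = 8.5), c(4, 4, 4))
  expect_equal(unlist(att),
               c(area_010 = 320, mean_010 = 5, area_015 = 320, mean_015 = 5,
                 area_020 = 320, mean_020 = 5))
  # two-level object: inner 4 voxels at 2 inside a ring of 12 at 1, suv70 10
  sl2 <- matrix(0, 8, 8); sl2[3:6, 3:6] <- 1; sl2[4:5, 4:5] <- 2
  att2 <- slice_attributes(sl2, list(suv_max = 12, suv70 = 10), c(4, 4, 4))
  expect_equal(unlist(att2),
               c(area_010 = 256, mean_010 = 1.25, area_015 = 64, mean_015 = 2,
                 area_020 = 64, mean_020 = 2))
  # all-zero slice: empty contours, sentinel means
  att0 <- slice_attributes(matrix(0, 6, 6), list(suv_max = 10, suv70 = 9))
  expect_equal(unname(unlist(att0)), rep(0, 6))
  expect_named(att0, c("area_010", "mean_010", "area_015", "mean_015",
                       "area_020", "mean_020"))
})

test_that("attribute nesting and mean monotonicity hold on phantom slices", {
  st <- generate_study(small_phantom_spec(seed = 11))
  stats <- global_uptake_stats(st$volume)
  for (k in seq_len(dim(st$volume$values)[3])) {
    att <- slice_attributes(st$volume$values[, , k], stats,
                            st$volume$voxel_size)
    expect_lte(att$area_020, att$area_015)
    expect_lte(att$area_015, att$area_010)
    if (att$area_020 > 0) {
      expect_lte(att$mean_010, att$mean_015)
      expect_lte(att$mean_015, att$mean_020)
    }
  }
})

test_that("slice selection takes tumour slices plus 4+4 adjacent free slices", {
  mk_gtv <- function(nz, slices) {
    g <- array(FALSE, c(4, 4, nz)); g[2, 2, slices] <- TRUE; g
  }
  sel <- select_slices(mk_gtv(40, 11:21))
  expect_equal(sel$slice_index, 7:25)
  expect_equal(sel$slice_index[sel$is_tumour], 11:21)
  expect_equal(sum(!sel$is_tumour), 8L)
  # tumour at the volume start: all free slices taken superiorly
  expect_warning(sel2 <- select_slices(mk_gtv(40, 1:6)), "end")
  expect_equal(sel2$slice_index, 1:14)
  expect_equal(sum(!sel2$is_tumour), 8L)
  expect_error(select_slices(mk_gtv(10, 2:9)), "tumour-free")
  # bookkeeping: N = N+ + 8 as in every study
  expect_equal(nrow(sel), sum(sel$is_tumour) + 8L)
})
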