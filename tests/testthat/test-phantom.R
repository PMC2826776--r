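test_that("sphere rasterization matches brute-force voxel-in-sphere counting", {
  # radius 12 mm on 4 mm voxels: discrete ball of radius 3 voxels under
  # centre-inclusion; oracle enumerates all voxel centres
  spec <- phantom_spec(grid_shape = c(16, 16, 16),
                       tumour = list(tumour_component(centre = c(30, 30, 30),
                                                      semi_axes = c(12, 12, 12))),
                       psf_fwhm = 0, noise_sd = 0)
  st <- generate_study(spec)
  cnt <- 0
  for (i in 1:16) for (j in 1:16) for (k in 1:16) {
    d2 <- ((i - 0.5) * 4 - 30)^2 + ((j - 0.5) * 4 - 30)^2 + ((k - 0.5) * 4 - 30)^2
    if (d2 <= 144) cnt <- cnt + 1
  }
  expect_equal(sum(st$gtv), cnt)
  expect_gt(cnt, 0)
})

test_that("generated studies satisfy fixture invariants and are reproducible", {
  spec <- small_phantom_spec(seed = 42)
  st1 <- generate_study(spec)
  st2 <- generate_study(spec)
  expect_identical(st1$volume$values, st2$volume$values)  # bit-identical
  expect_false(any(st1$gtv & st1$background))
  expect_true(all(is.finite(st1$volume$values)))
  expect_true(all(st1$volume$values >= 0))
  st3 <- generate_study(small_phantom_spec(seed = 43))
  expect_false(identical(st1$volume$values, st3$volume$values))
})

test_that("background shell sits 2-4 voxels outside the GTV", {
  st <- generate_study(small_phantom_spec(seed = 1))
  # no background voxel touches the GTV (distance >= 2) and the shell is
  # non-empty so the baseline has a region to average
  grown <- st$gtv
  d <- dim(grown)
  touch <- grown
  touch[-1, , ] <- touch[-1, , ] | grown[-d[1], , ]
  touch[-d[1], , ] <- touch[-d[1], , ] | grown[-1, , ]
  touch[, -1, ] <- touch[, -1, ] | grown[, -d[2], ]
  touch[, -d[2], ] <- touch[, -d[2], ] | grown[, -1, ]
  touch[, , -1] <- touch[, , -1] | grown[, , -d[3]]
  touch[, , -d[3]] <- touch[, , -d[3]] | grown[, , -1]
  expect_false(any(st$background & touch))
  expect_gt(sum(st$background), 0)
})

test_that("paired modes share geometry and motion dilutes the peak", {
  pm <- paired_modes(small_phantom_spec(seed = 3))
  expect_identical(pm$gated$gtv, pm$free_breathing$gtv)
  expect_equal(pm$gated$mode, "gated")
  expect_equal(pm$free_breathing$mode, "free_breathing")
  # noiseless: motion averaging strictly dilutes the hottest voxel
  pm0 <- paired_modes(small_phantom_spec(seed = 3, noise_sd = 0))
  expect_lt(max(pm0$free_breathing$volume$values),
            max(pm0$gated$volume$values))
  # with noise the ordering holds in the mean over seeds
  dmax <- vapply(1:6, function(s) {
    p <- paired_modes(small_phantom_spec(seed = s))
    max(p$gated$volume$values) - max(p$free_breathing$volume$values)
  }, numeric(1))
  expect_gt(mean(dmax), 0)
})

test_that("free-breathing reference thresholds spread wider than gated", {
  wins <- 0L
  for (s in 1:5) {
    pm <- paired_modes(phantom_spec(seed = s))
    rg <- build_labelled_instances(pm$gated)
    rf <- build_labelled_instances(pm$free_breathing)
    iq_g <- stats::IQR(rg$reference_threshold[rg$is_tumour])
    iq_f <- stats::IQR(rf$reference_threshold[rf$is_tumour])
    wins <- wins + (iq_f > iq_g)
  }
  expect_gte(wins, 4L)
})

test_that("the default suite mirrors the two-patient two-mode bookkeeping", {
  suite <- default_patient_suite(seed = 1)
  expect_named(suite, c("patient1_gated", "patient1_free_breathing",
                        "patient2_gated", "patient2_free_breathing"))
  n_tum <- vapply(suite, function(st) sum(apply(st$gtv, 3, any)), numeric(1))
  expect_equal(unname(n_tum), c(24, 24, 33, 33))
  for (st in suite) {
    expect_s3_class(st, "study_fixture")        # invariants checked inside
    sel <- select_slices(st$gtv)
    expect_equal(nrow(sel), sum(sel$is_tumour) + 8L)
  }
  expect_equal(nrow(select_slices(suite$patient2_gated$gtv)), 41L)
  expect_equal(nrow(select_slices(suite$patient1_gated$gtv)), 32L)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(tumour = list(tumour_component(
    centre = c(126, 126, 94), semi_axes = c(22, 22, 64), peak_uptake = 0.5))),
    "exceed")
  spec_out <- phantom_spec(grid_shape = c(16, 16, 16),
                           tumour = list(tumour_component(
                             centre = c(500, 500, 500),
                             semi_axes = c(10, 10, 10))))
  expect_error(generate_study(spec_out), "outside")
  spec_tight <- phantom_spec(grid_shape = c(16, 16, 10),
                             tumour = list(tumour_component(
                               centre = c(30, 30, 20),
                               semi_axes = c(10, 10, 18))))
  expect_error(generate_study(spec_tight), "slices")
})
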