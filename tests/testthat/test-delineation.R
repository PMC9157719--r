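test_that("SUVpeak of a homogeneous volume equals the constant", {
  vol <- suv_volume(array(5, dim = c(12, 12, 12)), voxel_size_mm = 4)
  expect_equal(suv_peak(vol, interior_seed(vol, 3)), 5)
  # a seed touching the boundary clips the sphere, with a warning
  expect_warning(pk <- suv_peak(vol, whole_seed(vol)), "clipped")
  expect_equal(pk, 5)
})

test_that("SUVpeak of a single hot voxel matches sphere-mask enumeration and is below SUVmax", {
  dims <- c(11, 11, 11)
  vals <- array(0, dim = dims)
  vals[6, 6, 6] <- 10
  vol <- suv_volume(vals, voxel_size_mm = 4)

  # oracle: enumerate all candidate centres and all voxel centres within
  # the 1 mL sphere radius by pairwise distances
  r <- (3 * 1000 / (4 * pi))^(1 / 3)
  co <- as.matrix(expand.grid(x = 1:11, y = 1:11, z = 1:11)) * 4
  best <- max(vapply(seq_len(nrow(co)), function(i) {
    d <- sqrt(colSums((t(co) - co[i, ])^2))
    mean(vals[d <= r])
  }, numeric(1)))

  pk <- suppressWarnings(suv_peak(vol, whole_seed(vol)))
  expect_equal(pk, best)
  expect_lt(pk, 10)
  # at 4 mm spacing the 1 mL sphere holds 19 voxel centres
  expect_equal(pk, 10 / 19)
})

test_that("delineation results are invariant to whole-voxel translation", {
  dims <- c(20, 20, 20)
  base <- ball_volume(3.2, dims, suv_in = 9, suv_out = 1)
  shifted <- array(1, dim = dims)
  shifted[4:20, 3:20, 2:20] <- base$values[1:17, 1:18, 1:19]
  vol2 <- suv_volume(shifted, voxel_size_mm = 4)
  d1 <- delineate_threshold(base, whole_seed(base), "PCT40")
  d2 <- delineate_threshold(vol2, whole_seed(vol2), "PCT40")
  expect_equal(d1$n_voxels, d2$n_voxels)
  expect_equal(d1$threshold_used, d2$threshold_used)
  expect_equal(suv_peak(base, interior_seed(base, 4)),
               suv_peak(vol2, interior_seed(vol2, 4)))
})

test_that("PCT40 threshold is 40% of SUVmax and every masked voxel reaches it", {
  set.seed(4)
  design <- study_design(n_patients = 1, grid_shape = c(32, 32, 32),
                         rng_seed = 4)
  spec <- lesion_spec(rep(64, 3), rep(13, 3), peak_suv = 10,
                      heterogeneity_amplitude = 0.4, trt_noise_cv = 0)
  vol <- generate_lesion(spec, design)
  seed <- whole_seed(vol)
  d <- delineate_threshold(vol, seed, "PCT40")
  expect_equal(d$threshold_used, 0.4 * max(vol$values))
  expect_gte(min(vol$values[d$mask]), d$threshold_used)
})

test_that("SUV4 recovers a homogeneous sphere over a cold background", {
  vol <- ball_volume(4.2, c(21, 21, 21), suv_in = 5, suv_out = 1)
  d <- delineate_threshold(vol, whole_seed(vol), "SUV4")
  expect_equal(d$threshold_used, 4)
  expect_identical(array(d$mask, dim(vol$values)), vol$values == 5)
  expect_true(d$qualifies)
})

test_that("SUV4 on a lesion below 4 g/mL gives a degenerate non-qualifying result", {
  vol <- ball_volume(3, c(15, 15, 15), suv_in = 3.5, suv_out = 1)
  d <- delineate_threshold(vol, whole_seed(vol), "SUV4")
  expect_null(d$mask)
  expect_false(d$qualifies)
  expect_equal(d$n_voxels, 0L)
})

test_that("raising the threshold never adds voxels and masks stay 26-connected", {
  design <- study_design(n_patients = 1, grid_shape = c(32, 32, 32),
                         rng_seed = 8)
  spec <- lesion_spec(rep(64, 3), c(12, 14, 16), peak_suv = 9,
                      heterogeneity_amplitude = 0.5, trt_noise_cv = 0)
  vol <- generate_lesion(spec, design)
  seed <- whole_seed(vol)
  prev <- NULL
  for (thr in c(2, 3, 4, 5, 6)) {
    d <- delineate_threshold(vol, seed, "SUV4", suv_threshold = thr)
    if (is.null(d$mask)) break
    m <- which(d$mask)
    if (!is.null(prev)) expect_true(all(m %in% prev))
    prev <- m
    labs <- dtpradiomics:::cpp_label_zones(
      integer(length(d$mask)), as.logical(d$mask), as.integer(dim(vol$values)))
    expect_equal(max(labs), 1L)
  }
})

test_that("the background shell recovers a uniform background and ignores hot voxels", {
  vol <- ball_volume(2.6, c(27, 27, 27), suv_in = 8, suv_out = 1)
  expect_equal(background_shell_mean(vol, whole_seed(vol)), 1)

  # contaminate part of the shell with SUV 5: excluded by the > 4 rule
  vals <- vol$values
  vals[20:24, 10:18, 10:18] <- 5
  vol2 <- suv_volume(vals, voxel_size_mm = 4)
  expect_equal(background_shell_mean(vol2, whole_seed(vol2)), 1)
})

test_that("shell membership matches a brute-force pairwise-distance oracle", {
  vol <- ball_volume(2.2, c(19, 19, 19), suv_in = 8, suv_out = 1)
  dims <- dim(vol$values)
  core <- vol$values >= 0.7 * max(vol$values)
  dsq <- dtpradiomics:::cpp_edt_sq(as.logical(core), as.integer(dims),
                                   as.numeric(vol$voxel_size_mm))
  d_impl <- sqrt(dsq)
  idx <- which(core, arr.ind = TRUE)
  co <- as.matrix(expand.grid(x = 1:dims[1], y = 1:dims[2], z = 1:dims[3]))
  d_brute <- vapply(seq_len(nrow(co)), function(i)
    sqrt(min(colSums((t(idx) - co[i, ])^2 * vol$voxel_size_mm^2))),
    numeric(1))
  expect_equal(as.numeric(d_impl), d_brute, tolerance = 1e-10)
  pitch <- min(vol$voxel_size_mm)
  expect_identical(d_impl >= 20 & d_impl < 20 + pitch,
                   d_brute >= 20 & d_brute < 20 + pitch)
})

test_that("contrast threshold is 0.5 x SUVpeak + background", {
  # ball large enough that the 1 mL sphere fits inside: SUVpeak = 8
  vol <- ball_volume(4.5, c(27, 27, 27), suv_in = 8, suv_out = 1)
  d <- delineate_contrast(vol, interior_seed(vol))
  expect_equal(d$suv_peak, 8)
  expect_equal(d$background_suv, 1)
  expect_equal(d$threshold_used, 0.5 * 8 + 1)
  expect_identical(array(d$mask, dim(vol$values)), vol$values == 8)
})

test_that("with zero background the contrast mask coincides with SUV4 and scales with intensity", {
  vol <- ball_volume(4.5, c(27, 27, 27), suv_in = 8, suv_out = 0)
  dc <- delineate_contrast(vol, interior_seed(vol))
  d4 <- delineate_threshold(vol, whole_seed(vol), "SUV4")
  expect_equal(dc$threshold_used, 4)
  expect_identical(dc$mask, d4$mask)

  vol2 <- suv_volume(2 * vol$values, voxel_size_mm = 4)
  dc2 <- delineate_contrast(vol2, interior_seed(vol2))
  expect_equal(dc2$threshold_used, 2 * dc$threshold_used)
})

test_that("qualification is exactly the 64-voxel rule", {
  vals <- array(0, dim = c(16, 16, 16))
  vals[2:8, 2:4, 2:4] <- 10   # 7 x 3 x 3 = 63 voxels
  v63 <- suv_volume(vals, voxel_size_mm = 4)
  d63 <- delineate_threshold(v63, whole_seed(v63), "SUV4")
  expect_equal(d63$n_voxels, 63L)
  expect_false(d63$qualifies)

  vals[9, 2, 2] <- 10         # 64th voxel
  v64 <- suv_volume(vals, voxel_size_mm = 4)
  d64 <- delineate_threshold(v64, whole_seed(v64), "SUV4")
  expect_equal(d64$n_voxels, 64L)
  expect_true(d64$qualifies)
})

test_that("delineation summaries tabulate method, threshold and qualification", {
  vol <- ball_volume(4.2, c(21, 21, 21), suv_in = 5, suv_out = 1)
  d4 <- delineate_threshold(vol, whole_seed(vol, "a"), "SUV4")
  dp <- delineate_threshold(vol, whole_seed(vol, "a"), "PCT40")
  f <- withr::local_tempfile(fileext = ".csv")
  tab <- delineation_summary(list(d4, dp), f)
  expect_equal(tab$method, c("SUV4", "PCT40"))
  expect_equal(tab$threshold_suv, c(4, 2))
  expect_true(all(tab$qualifies))
  expect_equal(nrow(read.csv(f)), 2)
})
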