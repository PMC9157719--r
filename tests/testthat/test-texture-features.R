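# a reproducible qualifying lesion + PCT40 delineation used by several tests
fixture_lesion <- function(seed = 4, amplitude = 0.4) {
  design <- study_design(n_patients = 1, grid_shape = c(32, 32, 32),
                         rng_seed = seed)
  spec <- lesion_spec(rep(64, 3), c(13, 14, 16), peak_suv = 10,
                      heterogeneity_amplitude = amplitude, trt_noise_cv = 0)
  vol <- generate_lesion(spec, design)
  list(vol = vol, delin = delineate_threshold(vol, interior_seed(vol), "PCT40"))
}

test_that("fixed bin width maps SUV to levels by floor with clamping", {
  cfg <- binning_config("FBW")
  expect_equal(discretize(0.30, cfg)$levels, 2L)   # floor(0.30/0.25)+1
  expect_equal(discretize(0, cfg)$levels, 1L)
  expect_equal(discretize(0.24, cfg)$levels, 1L)
  expect_equal(discretize(59.99, cfg)$levels, 240L)
  expect_equal(discretize(1, cfg)$G, 240L)
  expect_warning(d <- discretize(c(1, 75), cfg), "clamped")
  expect_equal(d$levels[2], 240L)
})

test_that("fixed bin number maps the lesion range onto 1..N", {
  cfg <- binning_config("FBN", n_bins = 64)
  suv <- c(2, 3.7, 5, 8, 11)
  d <- discretize(suv, cfg)
  expect_equal(d$levels[suv == min(suv)], 1L)
  expect_equal(d$levels[suv == max(suv)], 64L)
  expect_equal(d$G, 64L)
  # uniform ROI: degenerate rule
  du <- discretize(rep(3, 10), cfg)
  expect_true(all(du$levels == 1L))
  expect_equal(du$G, 1L)
})

test_that("GLCM of a homogeneous ROI is a single diagonal entry", {
  lev <- array(1L, dim = c(3, 3, 3))
  mask <- array(TRUE, dim = c(3, 3, 3))
  f <- glcm_features(lev, mask, G = 1)
  expect_equal(unname(f["GLCM_contrast"]), 0)
  expect_equal(unname(f["GLCM_dissimilarity"]), 0)
  expect_equal(unname(f["GLCM_energy"]), 1)
  expect_equal(unname(f["GLCM_entropy_log2"]), 0)
  expect_equal(unname(f["GLCM_homogeneity"]), 1)
})

test_that("GLCM of a single axial pair is the hand-enumerated two-cell matrix", {
  lev <- array(c(1L, 2L), dim = c(1, 1, 2))
  mask <- array(TRUE, dim = c(1, 1, 2))
  counts <- dtpradiomics:::cpp_glcm_counts(as.integer(lev), as.logical(mask),
                                           c(1L, 1L, 2L), 2L)
  expect_equal(matrix(as.numeric(counts), 2, 2),
               matrix(c(0, 1, 1, 0), 2, 2))
  f <- glcm_features(lev, mask, G = 2)
  expect_equal(unname(f["GLCM_contrast"]), 1)
  expect_equal(unname(f["GLCM_dissimilarity"]), 1)
})

test_that("GLCM requires two voxels", {
  expect_error(glcm_features(array(1L, c(1, 1, 1)), array(TRUE, c(1, 1, 1)),
                             G = 1), "at least 2")
})

test_that("pooled GLCM is symmetric and normalizes to 1", {
  set.seed(10)
  for (i in 1:5) {
    roi <- rand_roi(c(5, 5, 5), G = 6)
    counts <- dtpradiomics:::cpp_glcm_counts(
      as.integer(roi$lev), as.logical(roi$mask), as.integer(dim(roi$mask)), 6L)
    P <- counts / sum(counts)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(as.numeric(P), as.numeric(t(P)))
  }
})

test_that("GLRLM of simple lines matches hand enumeration", {
  # homogeneous 1x1x4 line: one run of 4 along the axis, 4 unit runs in
  # each of the other 12 directions
  lev <- array(1L, dim = c(1, 1, 4))
  mask <- array(TRUE, dim = c(1, 1, 4))
  counts <- dtpradiomics:::cpp_glrlm_counts(as.integer(lev),
                                            as.logical(mask),
                                            c(1L, 1L, 4L), 1L)
  expect_equal(counts[1, 4], 1)
  expect_equal(counts[1, 1], 48)
  f <- glrlm_features(lev, mask, G = 1)
  expect_equal(unname(f["GLRLM_RP"]), 49 / (13 * 4))

  # alternating levels: every run has length 1, SRE = 1
  lev2 <- array(c(1L, 2L, 1L, 2L), dim = c(1, 1, 4))
  f2 <- glrlm_features(lev2, mask, G = 2)
  expect_equal(unname(f2["GLRLM_SRE"]), 1)
  expect_equal(unname(f2["GLRLM_LRE"]), 1)
})

test_that("GLRLM and GLZLM conserve voxel counts", {
  set.seed(11)
  for (i in 1:5) {
    roi <- rand_roi(c(6, 5, 4), G = 4)
    nv <- sum(roi$mask)
    counts <- dtpradiomics:::cpp_glrlm_counts(
      as.integer(roi$lev), as.logical(roi$mask), as.integer(dim(roi$mask)), 4L)
    expect_equal(sum(t(counts) * seq_len(ncol(counts))), 13 * nv)
    labs <- dtpradiomics:::cpp_label_zones(
      as.integer(roi$lev), as.logical(roi$mask), as.integer(dim(roi$mask)))
    expect_equal(sum(tabulate(labs[labs > 0])), nv)
  }
})

test_that("GLZLM sees one zone in a homogeneous ROI and two in split blobs", {
  lev <- array(1L, dim = c(3, 3, 3))
  mask <- array(TRUE, dim = c(3, 3, 3))
  f <- glzlm_features(lev, mask, G = 1)
  expect_equal(unname(f["GLZLM_ZP"]), 1 / 27)
  expect_equal(unname(f["GLZLM_LZE"]), 27^2)

  # two blobs of the same level, separated by an unmasked plane
  mask2 <- array(TRUE, dim = c(5, 3, 3))
  mask2[3, , ] <- FALSE
  f2 <- glzlm_features(array(1L, dim = c(5, 3, 3)), mask2, G = 1)
  expect_equal(unname(f2["GLZLM_ZP"]), 2 / 36)
})

test_that("NGLDM degenerate cases follow the capped conventions", {
  lev <- array(1L, dim = c(3, 3, 3))
  mask <- array(TRUE, dim = c(3, 3, 3))
  f <- ngldm_features(lev, mask, G = 1)
  expect_equal(unname(f["NGLDM_contrast"]), 0)
  expect_equal(unname(f["NGLDM_busyness"]), 0)
  expect_equal(unname(f["NGLDM_coarseness"]), 1e6)
  expect_error(ngldm_features(array(1L, c(1, 1, 1)),
                              array(TRUE, c(1, 1, 1)), G = 1),
               "neighbourless")
})

test_that("histogram features obey the closed forms", {
  # uniform histogram over G levels
  G <- 8
  lev <- rep(1:G, each = 5)
  f <- histogram_features(lev, G)
  expect_equal(unname(f["HIST_entropy_log2"]), log2(G))
  expect_equal(unname(f["HIST_energy"]), 1 / G)
  expect_equal(unname(f["HIST_excess_kurtosis"]),
               unname(f["HIST_kurtosis"]) - 3)

  # single level: degenerate moments
  f1 <- histogram_features(rep(3L, 10), 4)
  expect_equal(unname(f1["HIST_entropy_log10"]), 0)
  expect_equal(unname(f1["HIST_energy"]), 1)
  expect_equal(unname(f1["HIST_skewness"]), 0)
  expect_equal(unname(f1["HIST_kurtosis"]), 0)

  # change of base holds for arbitrary histograms
  set.seed(3)
  lev2 <- sample(1:5, 40, TRUE)
  f2 <- histogram_features(lev2, 5)
  expect_equal(unname(f2["HIST_entropy_log10"] / f2["HIST_entropy_log2"]),
               log10(2))
})

test_that("conventional metrics follow their defining arithmetic", {
  vol <- suv_volume(array(5, dim = c(10, 10, 10)), voxel_size_mm = 4)
  mask <- array(FALSE, dim = c(10, 10, 10))
  mask[2:6, 2:6, 2:5] <- TRUE   # 100 voxels
  delin <- list(suv_peak = 5, seed = interior_seed(vol, 2))
  f <- conventional_shape_features(vol, mask, delin)
  expect_equal(unname(f["CONV_SUVmean"]), 5)
  expect_equal(unname(f["CONV_SUVstd"]), 0)
  expect_equal(unname(f["SHAPE_volume_mL"]), 100 * 64 / 1000)
  expect_equal(unname(f["CONV_TLG"]), 5 * 6.4)
  expect_equal(unname(f["SHAPE_volume_voxels"]), 100)
})

test_that("a large digitized ball has sphericity in (0.95, 1.05]", {
  dims <- c(23, 23, 23)
  ctr <- (dims + 1) / 2
  g <- expand.grid(x = 1:dims[1], y = 1:dims[2], z = 1:dims[3])
  r2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
  mask <- array(r2 <= 8.5^2, dim = dims)
  vol <- suv_volume(array(5, dim = dims) * (1 + array(0, dims)),
                    voxel_size_mm = 4)
  delin <- list(suv_peak = 5, seed = interior_seed(vol))
  f <- conventional_shape_features(vol, mask, delin)
  expect_gt(unname(f["SHAPE_sphericity"]), 0.95)
  expect_lte(unname(f["SHAPE_sphericity"]), 1.05)
  # compacity consistency: A^(3/2) / V in mm units
  A <- unname(f["SHAPE_surface_mm2"])
  V <- unname(f["SHAPE_volume_mL"]) * 1000
  expect_equal(unname(f["SHAPE_compacity"]), A^1.5 / V)
})

test_that("the panel has 49 features with the pinned class cardinalities", {
  panel <- feature_panel()
  expect_equal(nrow(panel), 49)
  expect_equal(as.integer(table(panel$class)[c("conventional", "shape",
                                               "histogram", "glcm", "glrlm",
                                               "glzlm", "ngldm")]),
               c(6L, 5L, 6L, 7L, 11L, 11L, 3L))
})

test_that("all 49 features are finite on a qualifying lesion and invariant to translation", {
  fx <- fixture_lesion()
  fv <- extract_features(fx$vol, fx$delin)
  expect_length(fv, 49)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), feature_panel()$feature)

  # translate volume by whole voxels and re-extract
  dims <- dim(fx$vol$values)
  sh <- c(2, 1, 3)
  vals <- array(fx$vol$values[1], dim = dims)
  vals[(1 + sh[1]):dims[1], (1 + sh[2]):dims[2], (1 + sh[3]):dims[3]] <-
    fx$vol$values[1:(dims[1] - sh[1]), 1:(dims[2] - sh[2]),
                  1:(dims[3] - sh[3])]
  vol2 <- suv_volume(vals, voxel_size_mm = fx$vol$voxel_size_mm)
  fv2 <- extract_features(vol2, delineate_threshold(vol2, interior_seed(vol2),
                                                    "PCT40"))
  expect_equal(fv2, fv, tolerance = 1e-9)
})

test_that("FBN texture features are invariant to affine intensity rescaling; FBW features are not", {
  fx <- fixture_lesion()
  texture_names <- grep("^(HIST|GLCM|GLRLM|GLZLM|NGLDM)_",
                        feature_panel()$feature, value = TRUE)
  vol2 <- suv_volume(1.7 * fx$vol$values + 0.9,
                     voxel_size_mm = fx$vol$voxel_size_mm)

  fbn1 <- extract_features(fx$vol, fx$delin, binning_config("FBN"))
  fbn2 <- extract_features(vol2, fx$delin, binning_config("FBN"))
  expect_equal(fbn2[texture_names], fbn1[texture_names], tolerance = 1e-12)

  fbw1 <- extract_features(fx$vol, fx$delin, binning_config("FBW"))
  fbw2 <- extract_features(vol2, fx$delin, binning_config("FBW"))
  expect_false(isTRUE(all.equal(fbw2[texture_names], fbw1[texture_names])))
})

test_that("sub-threshold lesions yield no feature vector", {
  vals <- array(0, dim = c(16, 16, 16))
  vals[2:8, 2:4, 2:4] <- 10          # 63 voxels
  v <- suv_volume(vals, voxel_size_mm = 4)
  d <- delineate_threshold(v, whole_seed(v), "SUV4")
  expect_null(extract_features(v, d))
})
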