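#' The 49-feature radiomic panel
#'
#' Feature identifiers, grouped in 7 classes with cardinalities
#' 6 (conventional) / 5 (shape) / 6 (histogram) / 7 (GLCM) / 11 (GLRLM) /
#' 11 (GLZLM) / 3 (NGLDM). These identifiers are the stable serialization
#' names used in feature tables.
#'
#' @return Data frame with columns `feature` and `class`.
#' @examples
#' table(feature_panel()$class)
#' @export
feature_panel <- function() {
  conv <- c("SUVmin", "SUVmean", "SUVstd", "SUVmax", "SUVpeak", "TLG")
  shape <- c("volume_mL", "volume_voxels", "surface_mm2", "sphericity",
             "compacity")
  hist <- c("skewness", "kurtosis", "excess_kurtosis", "entropy_log10",
            "entropy_log2", "energy")
  glcm <- c("homogeneity", "energy", "contrast", "correlation",
            "entropy_log10", "entropy_log2", "dissimilarity")
  glrlm <- c("SRE", "LRE", "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE",
             "LRHGE", "GLNU", "RLNU", "RP")
  glzlm <- c("SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE", "LZLGE",
             "LZHGE", "GLNU", "ZLNU", "ZP")
  ngldm <- c("coarseness", "contrast", "busyness")
  data.frame(
    feature = c(paste0("CONV_", conv), paste0("SHAPE_", shape),
                paste0("HIST_", hist), paste0("GLCM_", glcm),
                paste0("GLRLM_", glrlm), paste0("GLZLM_", glzlm),
                paste0("NGLDM_", ngldm)),
    class = rep(c("conventional", "shape", "histogram", "glcm", "glrlm",
                  "glzlm", "ngldm"),
                times = c(6, 5, 6, 7, 11, 11, 3)),
    stringsAsFactors = FALSE)
}

# Crop volume and mask to the mask bounding box and discretize the masked
# voxels. Returns integer level array (0 outside mask), mask array, G.
texture_arrays <- function(volume, mask, config) {
  idx <- which(mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  m <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  v <- volume$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dm <- dim(m)
  disc <- discretize(v[m], config)
  lev <- array(0L, dim = dm)
  lev[m] <- disc$levels
  list(lev = lev, mask = m, G = disc$G, dim = dm)
}

#' Gray-level co-occurrence features
#'
#' Co-occurrences are counted over all 13 unique 3-D directions at
#' Chebyshev distance 1, in both orientations, pooled into a single
#' symmetric matrix and normalized to probabilities.
#'
#' @param lev integer 3-D array of gray levels (0 outside the mask).
#' @param mask logical 3-D array.
#' @param G number of gray levels.
#' @return Named vector of 7 features (`GLCM_` prefix).
#' @export
glcm_features <- function(lev, mask, G) {
  if (sum(mask) < 2L) stop("GLCM requires at least 2 masked voxels")
  counts <- cpp_glcm_counts(as.integer(lev), as.logical(mask),
                            as.integer(dim(mask)), as.integer(G))
  tot <- sum(counts)
  if (tot == 0) stop("no co-occurring voxel pairs inside the mask")
  P <- counts / tot
  nz <- which(P > 0, arr.ind = TRUE)
  p <- P[nz]
  i <- nz[, 1]
  j <- nz[, 2]
  pi_marg <- rowSums(P)
  mu <- sum(seq_len(G) * pi_marg)
  sig2 <- sum((seq_len(G) - mu)^2 * pi_marg)
  corr <- if (sig2 > 0) sum((i - mu) * (j - mu) * p) / sig2 else 1
  c(GLCM_homogeneity = sum(p / (1 + abs(i - j))),
    GLCM_energy = sum(p^2),
    GLCM_contrast = sum((i - j)^2 * p),
    GLCM_correlation = corr,
    GLCM_entropy_log10 = -sum(p * log10(p)),
    GLCM_entropy_log2 = -sum(p * log2(p)),
    GLCM_dissimilarity = sum(abs(i - j) * p))
}

#' Gray-level run-length features
#'
#' Runs of equal gray level along each of the 13 directions, truncated at
#' the mask boundary, pooled into a single matrix. Run percentage divides
#' the number of runs by the pooled voxel coverage (13 x voxel count), so
#' it stays in (0, 1].
#'
#' @inheritParams glcm_features
#' @return Named vector of 11 features (`GLRLM_` prefix).
#' @export
glrlm_features <- function(lev, mask, G) {
  if (!any(mask)) stop("empty ROI")
  counts <- cpp_glrlm_counts(as.integer(lev), as.logical(mask),
                             as.integer(dim(mask)), as.integer(G))
  nz <- which(counts > 0, arr.ind = TRUE)
  r <- counts[nz]
  i <- nz[, 1]          # gray level
  l <- nz[, 2]          # run length
  Nr <- sum(r)
  Nv <- sum(mask)
  lev_tot <- rowsum(r, i)              # runs per gray level
  len_tot <- rowsum(r, l)              # runs per run length
  c(GLRLM_SRE = sum(r / l^2) / Nr,
    GLRLM_LRE = sum(r * l^2) / Nr,
    GLRLM_LGRE = sum(r / i^2) / Nr,
    GLRLM_HGRE = sum(r * i^2) / Nr,
    GLRLM_SRLGE = sum(r / (i^2 * l^2)) / Nr,
    GLRLM_SRHGE = sum(r * i^2 / l^2) / Nr,
    GLRLM_LRLGE = sum(r * l^2 / i^2) / Nr,
    GLRLM_LRHGE = sum(r * i^2 * l^2) / Nr,
    GLRLM_GLNU = sum(lev_tot^2) / Nr,
    GLRLM_RLNU = sum(len_tot^2) / Nr,
    GLRLM_RP = Nr / (13 * Nv))
}

#' Gray-level zone features
#'
#' Zones are 26-connected components of equal gray level within the mask;
#' the zone-size matrix counts zones by (level, size). Zone percentage is
#' zones / voxels.
#'
#' @inheritParams glcm_features
#' @return Named vector of 11 features (`GLZLM_` prefix).
#' @export
glzlm_features <- function(lev, mask, G) {
  if (!any(mask)) stop("empty ROI")
  labels <- cpp_label_zones(as.integer(lev), as.logical(mask),
                            as.integer(dim(mask)))
  labs <- labels[labels > 0]
  sizes <- tabulate(labs)
  zone_level <- lev[match(seq_along(sizes), labels)]
  Nz <- length(sizes)
  Nv <- sum(mask)
  i <- as.numeric(zone_level)
  s <- as.numeric(sizes)
  lev_tot <- rowsum(rep(1, Nz), i)
  size_tot <- rowsum(rep(1, Nz), s)
  c(GLZLM_SZE = sum(1 / s^2) / Nz,
    GLZLM_LZE = sum(s^2) / Nz,
    GLZLM_LGZE = sum(1 / i^2) / Nz,
    GLZLM_HGZE = sum(i^2) / Nz,
    GLZLM_SZLGE = sum(1 / (i^2 * s^2)) / Nz,
    GLZLM_SZHGE = sum(i^2 / s^2) / Nz,
    GLZLM_LZLGE = sum(s^2 / i^2) / Nz,
    GLZLM_LZHGE = sum(i^2 * s^2) / Nz,
    GLZLM_GLNU = sum(lev_tot^2) / Nz,
    GLZLM_ZLNU = sum(size_tot^2) / Nz,
    GLZLM_ZP = Nz / Nv)
}

#' Neighbourhood gray-level difference features
#'
#' Neighbourhood gray-tone-difference formulation: for each masked voxel
#' with at least one masked 26-neighbour, the absolute difference between
#' its level and the mean level of its masked neighbours is accumulated
#' per gray level, yielding coarseness, contrast and busyness. A
#' homogeneous ROI has zero differences: contrast and busyness are 0 and
#' coarseness diverges, so it is capped.
#'
#' @inheritParams glcm_features
#' @param coarseness_cap cap for the coarseness of (near-)homogeneous ROIs.
#' @return Named vector of 3 features (`NGLDM_` prefix).
#' @export
ngldm_features <- function(lev, mask, G, coarseness_cap = 1e6) {
  if (!any(mask)) stop("empty ROI")
  acc <- cpp_ngtdm(as.integer(lev), as.logical(mask),
                   as.integer(dim(mask)), as.integer(G))
  n_i <- acc$n
  s_i <- acc$s
  N <- sum(n_i)
  if (N == 0) stop("all masked voxels are neighbourless")
  p_i <- n_i / N
  occ <- which(p_i > 0)
  Ng <- length(occ)
  denom <- sum(p_i * s_i)
  coarseness <- if (denom > 0) min(coarseness_cap, 1 / denom)
  else coarseness_cap
  if (Ng > 1) {
    pr <- p_i[occ]
    gi <- occ
    contrast <- (sum(outer(pr, pr) * outer(gi, gi, `-`)^2) /
                   (Ng * (Ng - 1))) * (sum(s_i) / N)
    busy_den <- sum(abs(outer(gi * pr, gi * pr, `-`)))
    busyness <- if (busy_den > 0) denom / busy_den else 0
  } else {
    contrast <- 0
    busyness <- 0
  }
  c(NGLDM_coarseness = coarseness,
    NGLDM_contrast = contrast,
    NGLDM_busyness = busyness)
}

#' Histogram features of the discretized ROI
#'
#' First-order statistics of the gray-level histogram: skewness, kurtosis
#' (and its excess form), Shannon entropy in log10 and log2, and energy
#' (`sum p^2`). With `0 log 0 := 0`. A zero-variance ROI has skewness,
#' kurtosis and excess kurtosis defined as 0.
#'
#' @param levels integer vector of gray levels for the masked voxels.
#' @param G number of gray levels.
#' @return Named vector of 6 features (`HIST_` prefix).
#' @export
histogram_features <- function(levels, G) {
  n <- length(levels)
  if (n == 0L) stop("empty ROI")
  p <- tabulate(levels, nbins = G) / n
  p <- p[p > 0]
  m <- mean(levels)
  m2 <- mean((levels - m)^2)
  if (m2 > 0) {
    skew <- mean((levels - m)^3) / m2^1.5
    kurt <- mean((levels - m)^4) / m2^2
    exk <- kurt - 3
  } else {
    skew <- 0; kurt <- 0; exk <- 0
  }
  c(HIST_skewness = skew,
    HIST_kurtosis = kurt,
    HIST_excess_kurtosis = exk,
    HIST_entropy_log10 = -sum(p * log10(p)),
    HIST_entropy_log2 = -sum(p * log2(p)),
    HIST_energy = sum(p^2))
}

# Mesh surface area of a binary mask (mm^2): the 0.5 iso-surface of the
# lightly smoothed indicator field, triangulated by marching tetrahedra.
# Direct voxel-face counting overestimates areas and breaks the
# sphericity -> 1 limit for digitized balls.
mask_surface_area <- function(mask, voxel_size_mm, smooth_sigma_vox = 0.75) {
  field <- array(as.numeric(mask), dim = dim(mask))
  if (smooth_sigma_vox > 0)
    field <- gauss_smooth3d(field, rep(smooth_sigma_vox, 3))
  cpp_isosurface_area(as.numeric(field), as.integer(dim(mask)),
                      as.numeric(voxel_size_mm), 0.5)
}

#' Conventional SUV metrics and shape features
#'
#' SUV statistics over the mask (population standard deviation), SUVpeak,
#' total lesion glycolysis, and mesh-based shape descriptors. Sphericity is
#' `pi^(1/3) (6V)^(2/3) / A` (1 for a perfect ball); compacity is
#' `A^(3/2) / V` (mm-based).
#'
#' @param volume an [suv_volume()].
#' @param mask logical 3-D array (the delineated lesion).
#' @param delin delineation result; its recorded SUVpeak is reused when
#'   present, otherwise the peak is recomputed from the seed region.
#' @return Named vector of 11 features (`CONV_` and `SHAPE_` prefixes).
#' @export
conventional_shape_features <- function(volume, mask, delin) {
  suv <- volume$values[mask]
  n <- length(suv)
  if (n == 0L) stop("empty ROI")
  peak <- delin$suv_peak
  if (is.na(peak)) peak <- suv_peak(volume, delin$seed)
  vol_mm3 <- n * voxel_volume_mm3(volume)
  vol_mL <- vol_mm3 / 1000
  area <- mask_surface_area(mask, volume$voxel_size_mm)
  c(CONV_SUVmin = min(suv),
    CONV_SUVmean = mean(suv),
    CONV_SUVstd = sqrt(mean((suv - mean(suv))^2)),
    CONV_SUVmax = max(suv),
    CONV_SUVpeak = peak,
    CONV_TLG = mean(suv) * vol_mL,
    SHAPE_volume_mL = vol_mL,
    SHAPE_volume_voxels = n,
    SHAPE_surface_mm2 = area,
    SHAPE_sphericity = pi^(1 / 3) * (6 * vol_mm3)^(2 / 3) / area,
    SHAPE_compacity = area^(3 / 2) / vol_mm3)
}

#' Extract the full 49-feature panel for one delineated lesion
#'
#' Computes every feature in [feature_panel()] for a qualifying lesion
#' (mask of at least `min_voxels` voxels). Non-qualifying lesions yield
#' `NULL`.
#'
#' @param volume an [suv_volume()].
#' @param delin a delineation result from [delineate()],
#'   [delineate_threshold()] or [delineate_contrast()].
#' @param config a [binning_config()].
#' @param min_voxels qualification threshold.
#' @return Named numeric vector of 49 features, ordered as
#'   [feature_panel()], or `NULL` if the lesion does not qualify.
#' @export
extract_features <- function(volume, delin, config = binning_config("FBW"),
                             min_voxels = 64L) {
  if (is.null(delin$mask) || delin$n_voxels < min_voxels) return(NULL)
  ta <- texture_arrays(volume, delin$mask, config)
  out <- c(
    conventional_shape_features(volume, delin$mask, delin),
    histogram_features(ta$lev[ta$mask], ta$G),
    glcm_features(ta$lev, ta$mask, ta$G),
    glrlm_features(ta$lev, ta$mask, ta$G),
    glzlm_features(ta$lev, ta$mask, ta$G),
    ngldm_features(ta$lev, ta$mask, ta$G))
  panel <- feature_panel()$feature
  stopifnot(identical(names(out), panel))
  out
}
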