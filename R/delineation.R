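#' Peak SUV (1 mL sphere)
#'
#' Mean SUV in a 1.0 mL sphere centred on the voxel that maximizes that
#' mean, the centre being searched within the seed region. Sphere
#' membership is decided by voxel centres lying within the sphere radius;
#' where the sphere extends beyond the volume the mean is taken over the
#' in-bounds voxels, with a warning.
#'
#' @param volume an [suv_volume()].
#' @param seed a [seed_region()].
#' @param sphere_volume_mL sphere volume; 1.0 mL by convention.
#' @return SUV peak in g/mL.
#' @export
suv_peak <- function(volume, seed, sphere_volume_mL = 1.0) {
  dims <- dim(volume$values)
  seed <- clip_seed(seed, dims)
  vox <- volume$voxel_size_mm
  radius <- (3 * sphere_volume_mL * 1000 / (4 * pi))^(1 / 3)

  half <- floor(radius / vox)
  offs <- expand.grid(dx = -half[1]:half[1], dy = -half[2]:half[2],
                      dz = -half[3]:half[3])
  keep <- sqrt((offs$dx * vox[1])^2 + (offs$dy * vox[2])^2 +
                 (offs$dz * vox[3])^2) <= radius
  offs <- offs[keep, , drop = FALSE]

  centers <- index_to_coord(seed_voxels(seed, dims), dims)
  best <- -Inf
  clipped <- FALSE
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1] + offs$dx
    cy <- centers[i, 2] + offs$dy
    cz <- centers[i, 3] + offs$dz
    inb <- cx >= 1 & cx <= dims[1] & cy >= 1 & cy <= dims[2] &
      cz >= 1 & cz <= dims[3]
    if (!all(inb)) clipped <- TRUE
    idx <- (cz[inb] - 1) * dims[1] * dims[2] + (cy[inb] - 1) * dims[1] +
      cx[inb]
    m <- mean(volume$values[idx])
    if (m > best) best <- m
  }
  if (clipped)
    warning("peak sphere clipped at the volume boundary; ",
            "mean taken over in-bounds voxels")
  best
}

# 26-connected component of `mask` containing the highest-SUV voxel of the
# seed region (NULL if the mask is empty there).
seeded_component <- function(mask, volume, seed) {
  dims <- dim(volume$values)
  sv <- seed_voxels(seed, dims)
  inside <- sv[mask[sv]]
  if (length(inside) == 0L) return(NULL)
  top <- inside[which.max(volume$values[inside])]
  labels <- cpp_label_zones(integer(length(mask)), as.logical(mask),
                            as.integer(dims))
  comp <- labels == labels[top]
  array(comp, dim = dims)
}

delineation_result <- function(mask, method, threshold, volume, seed,
                               suv_peak_val = NA_real_,
                               background = NA_real_,
                               min_voxels = 64L) {
  n <- if (is.null(mask)) 0L else sum(mask)
  list(mask = mask,
       method = method,
       threshold_used = threshold,
       suv_max = max(volume$values[seed_voxels(seed, dim(volume$values))]),
       suv_peak = suv_peak_val,
       background_suv = background,
       n_voxels = n,
       qualifies = n >= min_voxels,
       lesion_id = seed$lesion_id,
       seed = seed)
}

#' Threshold-based lesion delineation
#'
#' `PCT40`: isocontour at 40\% of the lesion's SUVmax (taken within the
#' seed region). `SUV4`: fixed isocontour at SUV 4.0 g/mL. Voxels with
#' SUV >= threshold are kept and restricted to the 26-connected component
#' containing the seed's maximum voxel. A lesion qualifies for feature
#' extraction when its mask has at least `min_voxels` voxels.
#'
#' @param volume an [suv_volume()].
#' @param seed a [seed_region()].
#' @param mode `"PCT40"` or `"SUV4"`.
#' @param pct threshold fraction for `PCT40`.
#' @param suv_threshold fixed threshold for `SUV4` (g/mL).
#' @param min_voxels qualification threshold (voxels).
#' @param closed use `>=` (the default, LIFEx-style closed threshold)
#'   rather than `>`.
#' @return A delineation result: list with `mask` (logical array or `NULL`
#'   when empty), `method`, `threshold_used`, `suv_max`, `suv_peak`,
#'   `background_suv`, `n_voxels`, `qualifies`, `lesion_id`.
#' @export
delineate_threshold <- function(volume, seed, mode = c("PCT40", "SUV4"),
                                pct = 0.40, suv_threshold = 4.0,
                                min_voxels = 64L, closed = TRUE) {
  mode <- match.arg(mode)
  dims <- dim(volume$values)
  seed <- clip_seed(seed, dims)
  smax <- max(volume$values[seed_voxels(seed, dims)])
  thr <- if (mode == "PCT40") pct * smax else suv_threshold
  raw <- if (closed) volume$values >= thr else volume$values > thr
  mask <- seeded_component(raw, volume, seed)
  delineation_result(mask, mode, thr, volume, seed, min_voxels = min_voxels)
}

#' Background SUV from a 2 cm shell
#'
#' Mean SUV over the voxels whose Euclidean distance from the volume
#' delineated at 70\% of SUVmax lies in `[20, 20 + voxel pitch)` mm,
#' excluding voxels with SUV > 4 (so that neighbouring lesions do not
#' contaminate the background estimate). Distances are computed with an
#' exact Euclidean distance transform of the 70\% mask's complement.
#'
#' @inheritParams delineate_threshold
#' @return Background SUV in g/mL.
#' @export
background_shell_mean <- function(volume, seed) {
  dims <- dim(volume$values)
  seed <- clip_seed(seed, dims)
  smax <- max(volume$values[seed_voxels(seed, dims)])
  core <- seeded_component(volume$values >= 0.7 * smax, volume, seed)
  if (is.null(core))
    stop("70% volume is empty; cannot estimate background")
  dsq <- cpp_edt_sq(as.logical(core), as.integer(dims),
                    as.numeric(volume$voxel_size_mm))
  d <- sqrt(dsq)
  pitch <- min(volume$voxel_size_mm)
  shell <- d >= 20 & d < 20 + pitch
  shell <- shell & volume$values <= 4
  if (!any(shell))
    stop("no valid background: shell empty after excluding SUV > 4")
  mean(volume$values[shell])
}

#' Contrast-based lesion delineation
#'
#' Isocontour at `0.5 * SUVpeak + background`, the background being the
#' 2 cm shell estimate of [background_shell_mean()].
#'
#' @inheritParams delineate_threshold
#' @return A delineation result (see [delineate_threshold()]); records the
#'   background and the threshold actually used.
#' @export
delineate_contrast <- function(volume, seed, min_voxels = 64L,
                               closed = TRUE) {
  dims <- dim(volume$values)
  seed <- clip_seed(seed, dims)
  pk <- suv_peak(volume, seed)
  bg <- background_shell_mean(volume, seed)
  thr <- 0.5 * pk + bg
  raw <- if (closed) volume$values >= thr else volume$values > thr
  mask <- seeded_component(raw, volume, seed)
  delineation_result(mask, "CONTRAST", thr, volume, seed,
                     suv_peak_val = pk, background = bg,
                     min_voxels = min_voxels)
}

#' Summarize delineation results as a per-lesion table
#'
#' @param delins list of delineation results.
#' @param path optional CSV output path.
#' @return Data frame with columns `lesion`, `method`, `threshold_suv`,
#'   `n_voxels`, `qualifies`.
#' @export
delineation_summary <- function(delins, path = NULL) {
  out <- do.call(rbind, lapply(delins, function(d) data.frame(
    lesion = d$lesion_id, method = d$method,
    threshold_suv = d$threshold_used, n_voxels = d$n_voxels,
    qualifies = d$qualifies, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  if (!is.null(path))
    write.csv(out, path, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  out
}

#' Delineate with a method chosen by name
#'
#' @inheritParams delineate_threshold
#' @param method `"pct40"`, `"suv4"` or `"contrast"`.
#' @export
delineate <- function(volume, seed, method = c("pct40", "suv4", "contrast"),
                      min_voxels = 64L) {
  method <- match.arg(method)
  switch(method,
         pct40 = delineate_threshold(volume, seed, "PCT40",
                                     min_voxels = min_voxels),
         suv4 = delineate_threshold(volume, seed, "SUV4",
                                    min_voxels = min_voxels),
         contrast = delineate_contrast(volume, seed,
                                       min_voxels = min_voxels))
}
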