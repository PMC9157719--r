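#' Synthetic dual-time-point PET study design
#'
#' Describes the acquisition geometry and protocol of a simulated
#' double-baseline FDG-PET study: every patient is scanned on `n_days`
#' consecutive days, at two post-injection uptake times per day, and each
#' scan is degraded by a Gaussian point-spread function emulating the
#' reconstruction variant (a narrower PSF mimics resolution-modelled
#' reconstruction, a wider one a harmonized standard reconstruction).
#'
#' @param n_patients number of patients.
#' @param lesions_per_patient inclusive integer range, e.g. `c(1, 10)`.
#' @param grid_shape 3 integers, voxel grid per scan.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param uptake_times_min two post-injection times in minutes, strictly
#'   increasing.
#' @param n_days number of scan days (>= 2 for test-retest).
#' @param psf_fwhm_mm full width at half maximum (mm) of the Gaussian PSF.
#' @param background_suv soft-tissue background SUV (g/mL).
#' @param rng_seed master seed; all randomness in the study derives from it.
#' @return An object of class `study_design`.
#' @examples
#' study_design(n_patients = 2, grid_shape = c(32, 32, 32))
#' @export
study_design <- function(n_patients = 10,
                         lesions_per_patient = c(1, 10),
                         grid_shape = c(64, 64, 64),
                         voxel_size_mm = 4,
                         uptake_times_min = c(60, 90),
                         n_days = 2,
                         psf_fwhm_mm = 5,
                         background_suv = 1.5,
                         rng_seed = 1L) {
  stopifnot(n_patients >= 1, length(grid_shape) == 3, voxel_size_mm > 0,
            psf_fwhm_mm >= 0, background_suv > 0)
  if (length(uptake_times_min) != 2 || diff(uptake_times_min) <= 0)
    stop("uptake_times_min must be two strictly increasing times")
  if (n_days < 2)
    stop("n_days must be >= 2 (test-retest design)")
  lesions_per_patient <- as.integer(lesions_per_patient)
  if (length(lesions_per_patient) == 1L)
    lesions_per_patient <- rep(lesions_per_patient, 2L)
  structure(
    list(n_patients = as.integer(n_patients),
         lesions_per_patient = lesions_per_patient,
         grid_shape = as.integer(grid_shape),
         voxel_size_mm = voxel_size_mm,
         uptake_times_min = uptake_times_min,
         n_days = as.integer(n_days),
         psf_fwhm_mm = psf_fwhm_mm,
         background_suv = background_suv,
         rng_seed = as.integer(rng_seed)),
    class = "study_design")
}

#' Synthetic lesion specification
#'
#' An ellipsoidal lesion with a smooth radial falloff, a multiplicative
#' log-normal texture field of controllable amplitude and correlation
#' length, a fractional uptake change per 30 min of extra uptake time, and
#' day-to-day (test-retest) multiplicative noise.
#'
#' @param center_mm lesion centre in mm (world coordinates).
#' @param semi_axes_mm three positive semi-axes in mm.
#' @param peak_suv SUV at the lesion core before texture and drift (g/mL).
#' @param heterogeneity_amplitude log-scale standard deviation of the
#'   multiplicative texture field (0 = homogeneous).
#' @param texture_correlation_mm correlation length of the texture field.
#' @param uptake_slope fractional change in lesion uptake per 30 min of
#'   additional uptake time (0.2 means +20\% between 60 and 90 min).
#' @param heterogeneity_slope fractional change in texture amplitude per
#'   30 min.
#' @param trt_noise_cv coefficient of variation of the per-scan global
#'   multiplicative test-retest noise factor.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center_mm, semi_axes_mm, peak_suv,
                        heterogeneity_amplitude = 0.3,
                        texture_correlation_mm = 12,
                        uptake_slope = 0.12,
                        heterogeneity_slope = 0.1,
                        trt_noise_cv = 0.1) {
  stopifnot(length(center_mm) == 3, length(semi_axes_mm) == 3,
            all(semi_axes_mm > 0), peak_suv > 0,
            heterogeneity_amplitude >= 0, texture_correlation_mm > 0,
            trt_noise_cv >= 0)
  structure(
    list(center_mm = as.numeric(center_mm),
         semi_axes_mm = as.numeric(semi_axes_mm),
         peak_suv = peak_suv,
         heterogeneity_amplitude = heterogeneity_amplitude,
         texture_correlation_mm = texture_correlation_mm,
         uptake_slope = uptake_slope,
         heterogeneity_slope = heterogeneity_slope,
         trt_noise_cv = trt_noise_cv),
    class = "lesion_spec")
}

# Deterministic substream seed derived from the master seed and a tuple of
# integer codes (patient, day, time, lesion, purpose). Multiplicative LCG
# fold modulo 2^31 - 1; stable under re-ordering of generation calls.
substream_seed <- function(master, ...) {
  codes <- c(...)
  h <- (as.numeric(master) %% 2147483646) + 1
  for (x in codes) {
    h <- (h * 48271 + (as.numeric(x) %% 2147483647) + 1) %% 2147483647
    if (h == 0) h <- 1
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Separable Gaussian smoothing with per-axis sigma in voxels. Kernel rows
# are renormalized at the boundary, so constants are preserved exactly.
gauss_smooth3d <- function(a, sigma_vox) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- d[ax]
    half <- max(1L, ceiling(4 * s))
    off <- (-half):half
    k <- exp(-0.5 * (off / s)^2)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- i + off
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok]
    }
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    m <- K %*% matrix(ap, nrow = n)
    a <- aperm(array(m, dim = d[perm]), order(perm))
  }
  a
}

fwhm_to_sigma <- function(fwhm_mm, voxel_mm) {
  fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
}

# Patch voxel bounds (1-based inclusive, on the design grid) enclosing the
# lesion plus a 25 mm margin. Independent of day/time/PSF so the texture
# field is reproducible across scans.
lesion_patch_bounds <- function(spec, design) {
  vox <- design$voxel_size_mm
  margin <- 25
  lo_mm <- spec$center_mm - spec$semi_axes_mm - margin
  hi_mm <- spec$center_mm + spec$semi_axes_mm + margin
  lo <- floor(lo_mm / vox) + 1L
  hi <- ceiling(hi_mm / vox) + 1L
  list(lo = as.integer(lo), hi = as.integer(hi))
}

# Radial falloff: flat core out to 60% of the normalized ellipsoid radius,
# cosine taper to zero at the ellipsoid boundary.
radial_profile <- function(r, core = 0.6) {
  p <- numeric(length(r))
  p[r <= core] <- 1
  mid <- r > core & r < 1
  p[mid] <- 0.5 * (1 + cos(pi * (r[mid] - core) / (1 - core)))
  p
}

#' Generate one synthetic lesion patch
#'
#' Builds the SUV field of a single lesion on a voxel patch of the design
#' grid: an ellipsoid with smooth radial falloff to the local background,
#' multiplied by a spatially correlated positive texture field, globally
#' scaled for uptake time, perturbed by a per-scan test-retest noise
#' factor, and finally convolved with the PSF.
#'
#' @param spec a [lesion_spec()].
#' @param design a [study_design()].
#' @param day scan day index (1-based).
#' @param time uptake-time index (1 or 2).
#' @param lesion_index integer used (with `day` and `time`) to derive the
#'   lesion's random substreams from `design$rng_seed`.
#' @param patient patient index used in substream derivation.
#' @param psf_fwhm_mm PSF override; defaults to the design's value. Use 0
#'   to inspect the unsmoothed field.
#' @param background_suv local background; defaults to the design's value.
#' @return An [suv_volume()] patch whose `origin_mm` places it on the design
#'   grid.
#' @export
generate_lesion <- function(spec, design, day = 1L, time = 1L,
                            lesion_index = 1L, patient = 1L,
                            psf_fwhm_mm = design$psf_fwhm_mm,
                            background_suv = design$background_suv) {
  b <- lesion_patch_bounds(spec, design)
  if (any(b$lo < 1L) || any(b$hi > design$grid_shape))
    stop("lesion at (", paste(round(spec$center_mm, 1), collapse = ", "),
         ") mm does not fit in the grid with a 25 mm margin")
  comp <- lesion_component(spec, design, day, time, lesion_index, patient,
                           psf_fwhm_mm)
  suv_volume(background_suv + comp,
             voxel_size_mm = rep(design$voxel_size_mm, 3),
             origin_mm = (b$lo - 1) * design$voxel_size_mm)
}

# Additive SUV contribution of a lesion on its patch (background excluded).
lesion_component <- function(spec, design, day, time, lesion_index, patient,
                             psf_fwhm_mm) {
  b <- lesion_patch_bounds(spec, design)
  vox <- design$voxel_size_mm
  dims <- b$hi - b$lo + 1L
  cx <- ((b$lo[1]:b$hi[1]) - 1) * vox
  cy <- ((b$lo[2]:b$hi[2]) - 1) * vox
  cz <- ((b$lo[3]:b$hi[3]) - 1) * vox

  rx <- (cx - spec$center_mm[1]) / spec$semi_axes_mm[1]
  ry <- (cy - spec$center_mm[2]) / spec$semi_axes_mm[2]
  rz <- (cz - spec$center_mm[3]) / spec$semi_axes_mm[3]
  r <- sqrt(outer(outer(rx^2, ry^2, `+`), rz^2, `+`))
  prof <- array(radial_profile(r), dim = dims)

  dt30 <- (design$uptake_times_min[time] - design$uptake_times_min[1]) / 30

  amp <- spec$heterogeneity_amplitude *
    (1 + spec$heterogeneity_slope * dt30)
  tex <- 1
  if (spec$heterogeneity_amplitude > 0) {
    g <- with_seed(
      substream_seed(design$rng_seed, patient, lesion_index, 101),
      array(rnorm(prod(dims)), dim = dims))
    g <- gauss_smooth3d(g, rep(fwhm_to_sigma(spec$texture_correlation_mm,
                                             vox), 3))
    g <- (g - mean(g)) / sd(g)
    tex <- exp(amp * g - amp^2 / 2)
  }

  scale_t <- 1 + spec$uptake_slope * dt30

  noise <- 1
  if (spec$trt_noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$trt_noise_cv^2))
    noise <- with_seed(
      substream_seed(design$rng_seed, patient, lesion_index, day, time, 202),
      rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog))
  }

  comp <- (spec$peak_suv - design$background_suv) * prof * tex *
    scale_t * noise
  if (psf_fwhm_mm > 0)
    comp <- gauss_smooth3d(comp, rep(fwhm_to_sigma(psf_fwhm_mm, vox), 3))
  comp
}

#' Generate a complete synthetic study
#'
#' Assembles one SUV volume per (patient, day, uptake time) by adding every
#' lesion's contribution to a uniform background, and records per-lesion
#' seed regions and the generating ground truth.
#'
#' @param design a [study_design()].
#' @param specs list of per-patient lists of [lesion_spec()] (as returned
#'   by [sample_lesion_specs()]); `specs[[p]]` holds patient `p`'s lesions.
#' @return A list with elements `volumes` (nested list
#'   `[[patient]][[day]][[time]]` of [suv_volume()]), `seeds` (per-patient
#'   lists of [seed_region()]), `ground_truth` (data frame) and `design`.
#' @export
generate_study <- function(design, specs) {
  if (length(specs) != design$n_patients)
    stop("specs must have one element per patient")
  vox <- design$voxel_size_mm

  # placement validation: margin and pairwise overlap (ellipsoid bounding
  # boxes padded by one voxel must be disjoint)
  for (p in seq_along(specs)) {
    sl <- specs[[p]]
    for (i in seq_along(sl)) {
      b <- lesion_patch_bounds(sl[[i]], design)
      if (any(b$lo < 1L) || any(b$hi > design$grid_shape))
        stop("lesion ", i, " of patient ", p,
             " does not fit in the grid with a 25 mm margin")
    }
    if (length(sl) >= 2) {
      for (i in seq_len(length(sl) - 1)) for (j in (i + 1):length(sl)) {
        lo_i <- sl[[i]]$center_mm - sl[[i]]$semi_axes_mm - vox
        hi_i <- sl[[i]]$center_mm + sl[[i]]$semi_axes_mm + vox
        lo_j <- sl[[j]]$center_mm - sl[[j]]$semi_axes_mm - vox
        hi_j <- sl[[j]]$center_mm + sl[[j]]$semi_axes_mm + vox
        if (all(hi_i >= lo_j & hi_j >= lo_i))
          stop("lesions ", i, " and ", j, " of patient ", p, " overlap")
      }
    }
  }

  volumes <- vector("list", design$n_patients)
  seeds <- vector("list", design$n_patients)
  gt <- list()
  dt30 <- diff(design$uptake_times_min) / 30

  for (p in seq_len(design$n_patients)) {
    volumes[[p]] <- vector("list", design$n_days)
    seeds[[p]] <- list()
    for (i in seq_along(specs[[p]])) {
      sp <- specs[[p]][[i]]
      pad <- 2L  # two-voxel pad captures PSF spill-over around the support
      lo <- pmax(1L, as.integer(floor((sp$center_mm - sp$semi_axes_mm) /
                                        vox)) + 1L - pad)
      hi <- pmin(design$grid_shape,
                 as.integer(ceiling((sp$center_mm + sp$semi_axes_mm) /
                                      vox)) + 1L + pad)
      seeds[[p]][[i]] <- seed_region(lo, hi,
                                     sprintf("p%02d_l%02d", p, i))
      gt[[length(gt) + 1]] <- data.frame(
        patient = p, lesion = sprintf("p%02d_l%02d", p, i),
        peak_suv = sp$peak_suv,
        uptake_scale_late = 1 + sp$uptake_slope * dt30,
        heterogeneity_direction = sign(sp$heterogeneity_slope),
        trt_noise_cv = sp$trt_noise_cv)
    }
    for (d in seq_len(design$n_days)) {
      volumes[[p]][[d]] <- vector("list", 2L)
      for (t in 1:2) {
        arr <- array(design$background_suv, dim = design$grid_shape)
        for (i in seq_along(specs[[p]])) {
          sp <- specs[[p]][[i]]
          b <- lesion_patch_bounds(sp, design)
          comp <- lesion_component(sp, design, d, t, i, p,
                                   design$psf_fwhm_mm)
          arr[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3]] <-
            arr[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3]] + comp
        }
        volumes[[p]][[d]][[t]] <- suv_volume(
          arr, voxel_size_mm = rep(vox, 3), origin_mm = c(0, 0, 0))
      }
    }
  }

  list(volumes = volumes, seeds = seeds,
       ground_truth = do.call(rbind, gt), design = design)
}

#' Sample lesion specifications for a design
#'
#' Draws, reproducibly from the design's seed, a set of non-overlapping
#' lesions per patient: peak SUV well above background, semi-axes large
#' enough that the delineated lesions comfortably exceed the 64-voxel
#' qualification threshold.
#'
#' @param design a [study_design()].
#' @param uptake_slope_mean,uptake_slope_sd across-lesion distribution of
#'   the fractional uptake change per 30 min.
#' @param heterogeneity_slope_mean,heterogeneity_slope_sd distribution of
#'   the texture-amplitude change per 30 min.
#' @param trt_noise_cv test-retest noise CV applied to every lesion.
#' @param peak_suv_range,semi_axes_range_mm uniform sampling ranges.
#' @param heterogeneity_amplitude,texture_correlation_mm texture field
#'   parameters shared by all lesions.
#' @param max_tries placement attempts per lesion before giving up.
#' @return A list of per-patient lists of [lesion_spec()].
#' @export
sample_lesion_specs <- function(design,
                                uptake_slope_mean = 0.12,
                                uptake_slope_sd = 0.06,
                                heterogeneity_slope_mean = 0.10,
                                heterogeneity_slope_sd = 0.05,
                                trt_noise_cv = 0.10,
                                peak_suv_range = c(6, 20),
                                semi_axes_range_mm = c(13, 18),
                                heterogeneity_amplitude = 0.3,
                                texture_correlation_mm = 12,
                                max_tries = 500L) {
  vox <- design$voxel_size_mm
  grid_mm <- design$grid_shape * vox
  lapply(seq_len(design$n_patients), function(p) {
    with_seed(substream_seed(design$rng_seed, p, 303), {
      lo_n <- design$lesions_per_patient[1]
      hi_n <- design$lesions_per_patient[2]
      n <- if (lo_n == hi_n) lo_n else sample(lo_n:hi_n, 1L)
      placed <- list()
      for (i in seq_len(n)) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          ax <- sort(runif(3, semi_axes_range_mm[1], semi_axes_range_mm[2]))
          lo_c <- ax + 25 + vox
          hi_c <- grid_mm - ax - 25 - vox
          if (any(hi_c <= lo_c))
            stop("grid too small to place lesions with a 25 mm margin")
          ctr <- runif(3, lo_c, hi_c)
          clash <- FALSE
          for (q in placed) {
            lo_i <- ctr - ax - vox; hi_i <- ctr + ax + vox
            lo_j <- q$center_mm - q$semi_axes_mm - vox
            hi_j <- q$center_mm + q$semi_axes_mm + vox
            if (all(hi_i >= lo_j & hi_j >= lo_i)) { clash <- TRUE; break }
          }
          if (!clash) {
            placed[[i]] <- lesion_spec(
              center_mm = ctr, semi_axes_mm = ax,
              peak_suv = runif(1, peak_suv_range[1], peak_suv_range[2]),
              heterogeneity_amplitude = heterogeneity_amplitude,
              texture_correlation_mm = texture_correlation_mm,
              uptake_slope = rnorm(1, uptake_slope_mean, uptake_slope_sd),
              heterogeneity_slope = rnorm(1, heterogeneity_slope_mean,
                                          heterogeneity_slope_sd),
              trt_noise_cv = trt_noise_cv)
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop("could not place lesion ", i, " for patient ", p,
               " after ", max_tries, " attempts")
      }
      placed
    })
  })
}

#' Write a synthetic study to disk
#'
#' One NIfTI volume per (patient, day, time), a JSON seed-region sidecar
#' per patient, and the ground truth as CSV.
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  design <- study$design
  for (p in seq_len(design$n_patients)) {
    for (d in seq_len(design$n_days)) for (t in 1:2) {
      f <- file.path(dir, sprintf("p%02d_d%d_t%d.nii.gz", p, d,
                                  round(design$uptake_times_min[t])))
      write_suv_volume(study$volumes[[p]][[d]][[t]], f)
    }
    write_seed_regions(study$seeds[[p]],
                       file.path(dir, sprintf("p%02d_seeds.json", p)))
  }
  write.csv(study$ground_truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(dir)
}
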