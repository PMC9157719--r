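#' SUV volume
#'
#' A 3-D scalar field of standardized uptake values (SUV, g/mL) on a regular
#' voxel grid. Voxel indices are 1-based in the R API; files written to disk
#' use 0-based, half-open conventions (see [write_seed_regions()]).
#'
#' @param values 3-D numeric array of SUV in g/mL; all finite and >= 0.
#' @param voxel_size_mm voxel spacing in mm, length 1 (isotropic) or 3.
#' @param origin_mm world-space position (mm) of the centre of voxel
#'   `[1, 1, 1]`.
#'
#' @return An object of class `suv_volume`: a list with elements `values`,
#'   `voxel_size_mm` (length 3) and `origin_mm`.
#' @examples
#' vol <- suv_volume(array(1.5, dim = c(8, 8, 8)), voxel_size_mm = 4)
#' voxel_volume_mm3(vol)
#' @export
suv_volume <- function(values, voxel_size_mm = 4, origin_mm = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array, got ", length(dim(values)),
         " dimension(s)")
  if (!all(is.finite(values)))
    stop("SUV volume contains non-finite voxels")
  if (any(values < 0))
    stop("SUV values must be >= 0")
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 1 or 3 positive values")
  structure(
    list(values = values,
         voxel_size_mm = as.numeric(voxel_size_mm),
         origin_mm = as.numeric(origin_mm)),
    class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<suv_volume> %d x %d x %d voxels, %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  cat(sprintf("  SUV range [%.3g, %.3g] g/mL\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @rdname suv_volume
#' @param vol an `suv_volume`.
#' @export
voxel_volume_mm3 <- function(vol) prod(vol$voxel_size_mm)

#' Seed region
#'
#' An axis-aligned voxel bounding box localizing one lesion. The lesion is
#' assumed to attain its maximum SUV inside the box; delineation searches are
#' restricted to the connected component reachable from that maximum.
#'
#' @param lo,hi 1-based inclusive voxel index bounds (length 3, `lo <= hi`).
#' @param lesion_id identifier for the lesion.
#' @return An object of class `seed_region`.
#' @examples
#' seed_region(c(10, 10, 10), c(20, 20, 18), "lesion-1")
#' @export
seed_region <- function(lo, hi, lesion_id = "lesion") {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L || any(hi < lo) || any(lo < 1L))
    stop("seed region must satisfy 1 <= lo <= hi on all three axes")
  structure(list(lo = lo, hi = hi, lesion_id = as.character(lesion_id)),
            class = "seed_region")
}

#' @export
print.seed_region <- function(x, ...) {
  cat(sprintf("<seed_region> %s: [%d:%d, %d:%d, %d:%d]\n", x$lesion_id,
              x$lo[1], x$hi[1], x$lo[2], x$hi[2], x$lo[3], x$hi[3]))
  invisible(x)
}

# Clip a seed region to the volume grid; error if it misses the grid.
clip_seed <- function(seed, dim3) {
  lo <- pmax(seed$lo, 1L)
  hi <- pmin(seed$hi, as.integer(dim3))
  if (any(hi < lo))
    stop("seed region '", seed$lesion_id, "' does not intersect the volume")
  seed_region(lo, hi, seed$lesion_id)
}

# Linear (column-major) indices of all voxels in a seed box.
seed_voxels <- function(seed, dim3) {
  ix <- seed$lo[1]:seed$hi[1]
  iy <- seed$lo[2]:seed$hi[2]
  iz <- seed$lo[3]:seed$hi[3]
  grid <- expand.grid(x = ix, y = iy, z = iz)
  (grid$z - 1L) * dim3[1] * dim3[2] + (grid$y - 1L) * dim3[1] + grid$x
}

# arr[ind] coordinates: linear index -> 1-based (x, y, z) matrix.
index_to_coord <- function(ind, dim3) {
  ind0 <- ind - 1L
  x <- ind0 %% dim3[1]
  y <- (ind0 %/% dim3[1]) %% dim3[2]
  z <- ind0 %/% (dim3[1] * dim3[2])
  cbind(x + 1L, y + 1L, z + 1L)
}
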