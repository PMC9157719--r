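#' Intensity discretization configuration
#'
#' Two schemes are supported. `FBW` (fixed bin width) bins SUV with a fixed
#' width over a fixed range shared by all lesions, so gray levels remain
#' comparable across lesions and scans; the defaults (0.25 g/mL over
#' 0-60 g/mL) give 240 levels. `FBN` (fixed bin number) rescales each
#' lesion's own SUVmin-SUVmax range onto a fixed number of bins (default
#' 64), making texture features invariant to affine rescaling of the
#' lesion's intensities.
#'
#' @param scheme `"FBW"` or `"FBN"`.
#' @param bin_width_gml bin width in g/mL (FBW).
#' @param range_gml SUV range `c(min, max)` in g/mL (FBW).
#' @param n_bins number of bins (FBN).
#' @return An object of class `binning_config`.
#' @examples
#' binning_config("FBW")
#' binning_config("FBN", n_bins = 64)
#' @export
binning_config <- function(scheme = c("FBW", "FBN"),
                           bin_width_gml = 0.25,
                           range_gml = c(0, 60),
                           n_bins = 64L) {
  scheme <- match.arg(scheme)
  stopifnot(bin_width_gml > 0, diff(range_gml) > 0, n_bins >= 2)
  structure(list(scheme = scheme,
                 bin_width_gml = bin_width_gml,
                 range_gml = as.numeric(range_gml),
                 n_bins = as.integer(n_bins)),
            class = "binning_config")
}

#' Discretize a region of interest
#'
#' Maps each masked voxel's SUV to an integer gray level in `1..G`.
#'
#' FBW: `level = floor((SUV - range_min) / W) + 1`, clamped to
#' `[1, ceil((range_max - range_min)/W)]`; values outside the range are
#' clamped with a warning. FBN:
#' `level = min(N, floor(N * (SUV - SUVmin)/(SUVmax - SUVmin)) + 1)` using
#' the lesion's own SUV range; a degenerate lesion (SUVmax == SUVmin) maps
#' every voxel to level 1 with `G = 1`.
#'
#' @param suv numeric vector of masked-voxel SUVs.
#' @param config a [binning_config()].
#' @return List with `levels` (integer vector, same length as `suv`) and
#'   `G` (number of gray levels).
#' @export
discretize <- function(suv, config) {
  if (length(suv) == 0L) stop("cannot discretize an empty ROI")
  if (config$scheme == "FBW") {
    rmin <- config$range_gml[1]
    rmax <- config$range_gml[2]
    W <- config$bin_width_gml
    G <- as.integer(ceiling((rmax - rmin) / W))
    if (any(suv < rmin) || any(suv > rmax))
      warning("SUV outside [", rmin, ", ", rmax, "] g/mL clamped during ",
              "fixed-bin-width discretization")
    lev <- floor((suv - rmin) / W) + 1
    lev <- pmin(pmax(lev, 1), G)
  } else {
    smin <- min(suv)
    smax <- max(suv)
    N <- config$n_bins
    if (smax == smin) {
      return(list(levels = rep(1L, length(suv)), G = 1L))
    }
    lev <- pmin(N, floor(N * (suv - smin) / (smax - smin)) + 1)
    G <- N
  }
  list(levels = as.integer(lev), G = as.integer(G))
}
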