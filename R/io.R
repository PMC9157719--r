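#' Read an SUV volume from a NIfTI-1 file
#'
#' Voxel values are interpreted as SUV in g/mL; spacing is taken from the
#' header. Only 3-D scalar images are accepted.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [suv_volume()].
#' @export
read_suv_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D volume, file has ", length(d), " dimensions")
  vals <- array(as.numeric(img), dim = d)
  if (!all(is.finite(vals)))
    stop("volume contains non-finite voxels")
  sp <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  orig <- c(0, 0, 0)
  if (!inherits(xf, "try-error")) {
    m <- unclass(xf)
    sp_x <- sqrt(colSums(m[1:3, 1:3]^2))
    if (all(sp_x > 0)) sp <- sp_x
    orig <- m[1:3, 4]
  }
  suv_volume(vals, voxel_size_mm = sp, origin_mm = orig)
}

#' Write an SUV volume (or mask) as NIfTI-1
#'
#' @param vol an [suv_volume()], or a logical/numeric 3-D array together with
#'   `voxel_size_mm`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_suv_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  m <- diag(4)
  diag(m)[1:3] <- vol$voxel_size_mm
  m[1:3, 4] <- vol$origin_mm
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a lesion mask with the parent volume's geometry
#'
#' @param mask logical 3-D array.
#' @param vol the parent [suv_volume()].
#' @param path output path.
#' @export
write_lesion_mask <- function(mask, vol, path) {
  write_suv_volume(
    suv_volume(array(as.numeric(mask), dim = dim(mask)),
               voxel_size_mm = vol$voxel_size_mm,
               origin_mm = vol$origin_mm),
    path)
}

#' Persist seed regions as a JSON sidecar
#'
#' Seed boxes are serialized with 0-based, half-open voxel bounds
#' (`lo` inclusive, `hi` exclusive), the usual interchange convention;
#' [read_seed_regions()] converts back to the package's 1-based inclusive
#' representation.
#'
#' @param seeds list of [seed_region()] objects.
#' @param path output `.json` path.
#' @export
write_seed_regions <- function(seeds, path) {
  recs <- lapply(seeds, function(s) {
    list(lesion_id = s$lesion_id,
         lo = as.integer(s$lo - 1L),   # 0-based inclusive
         hi = as.integer(s$hi))       # 0-based exclusive == 1-based inclusive
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_seed_regions
#' @export
read_seed_regions <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(recs)), function(i) {
    seed_region(lo = unlist(recs$lo[i]) + 1L,
                hi = unlist(recs$hi[i]),
                lesion_id = recs$lesion_id[i])
  })
}

#' Write / read a longitudinal feature table
#'
#' The long-format CSV is the interchange contract between extraction and
#' classification: columns `patient, lesion, day, time_min, reconstruction,
#' delineation, discretization, feature, value`, in that order, UTF-8.
#'
#' @param table data frame with the columns above.
#' @param path output CSV path.
#' @param overwrite overwrite an existing file?
#' @export
write_feature_table <- function(table, path, overwrite = FALSE) {
  cols <- c("patient", "lesion", "day", "time_min", "reconstruction",
            "delineation", "discretization", "feature", "value")
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("feature table is empty; refusing to write an empty file")
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("feature table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (file.exists(path) && !overwrite)
    stop("'", path, "' exists; set overwrite = TRUE to replace it")
  out <- table[, cols]
  out$value <- sprintf("%.12g", out$value)
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  tab$value <- as.numeric(tab$value)
  tab
}

#' Write a feature use-case classification report
#'
#' @param report classification data frame from [classify_all()].
#' @param path output CSV path.
#' @param summary_path optional JSON path for per-use-case percentages.
#' @export
write_classification_report <- function(report, path, summary_path = NULL) {
  cols <- c("feature", "class", "icc60", "icc90", "p_raw", "q_fdr",
            "mean_z", "sd_z", "use_case")
  write.csv(report[, cols], path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  if (!is.null(summary_path)) {
    n <- nrow(report)
    pct <- function(uc) 100 * sum(report$use_case == uc) / n
    jsonlite::write_json(
      list(n_features = n,
           pct_dtp = pct("DTP"), pct_cs1 = pct("CS1"),
           pct_cs2 = pct("CS2"), pct_discarded = pct("DISCARDED")),
      summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
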