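#' Agreement ICC (two-way mixed effects, single rating)
#'
#' ICC(A,1) in the McGraw-Wong nomenclature, computed from the two-way
#' ANOVA mean squares of an n lesions x k occasions table:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`. Absolute
#' agreement, so a systematic offset between test and retest is penalized.
#'
#' @param test,retest paired per-lesion feature values (k = 2 occasions).
#' @return The ICC (a single number in `[-1, 1]`).
#' @examples
#' icc_agreement_single(c(1, 2, 3, 4), c(1.1, 2.0, 2.9, 4.2))
#' @export
icc_agreement_single <- function(test, retest) {
  if (length(test) != length(retest))
    stop("test and retest must be paired")
  ok <- is.finite(test) & is.finite(retest)
  test <- test[ok]; retest <- retest[ok]
  n <- length(test)
  if (n < 3) stop("ICC requires at least 3 lesions")
  x <- cbind(test, retest)
  k <- 2
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (sst == 0 || denom == 0)
    stop("ICC undefined: zero total variance")
  (msr - mse) / denom
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired values. Zero differences are
#' dropped (classic Wilcoxon rule). The exact null distribution is used
#' for n <= `exact_max` differences without ties; otherwise the normal
#' approximation with continuity and tie correction.
#'
#' @param x,y paired per-lesion values (e.g. at 60 and 90 min).
#' @param exact_max largest n for the exact distribution.
#' @param zeros how to treat zero differences; only `"drop"` is
#'   implemented (Pratt's method deliberately not used).
#' @return Two-sided p-value.
#' @examples
#' wilcoxon_signed_rank(1:6, 1:6 + 0.5)  # all-positive differences
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L, zeros = "drop") {
  zeros <- match.arg(zeros, "drop")
  if (length(x) != length(y)) stop("x and y must be paired")
  d <- y - x
  d <- d[d != 0]
  if (length(d) == 0L) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  ties <- any(duplicated(abs(d)))
  use_exact <- length(d) <= exact_max && !ties
  res <- suppressWarnings(
    wilcox.test(d, mu = 0, paired = FALSE, exact = use_exact,
                correct = TRUE, alternative = "two.sided"))
  res$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment across the analyzed features;
#' adjusted values are monotone in rank order and capped at 1.
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @return Vector of adjusted q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Uptake-time z score
#'
#' Per-lesion change from 60 to 90 min (first scan day) normalized by the
#' across-lesion mean and standard deviation of the 60-min test-retest
#' difference:
#' `z = ((RF90 - RF60) - mean(TRT60)) / sd(TRT60)`,
#' where `TRT60` is the day-2 minus day-1 feature value at 60 min. A z
#' magnitude above 1 marks an uptake-time change exceeding test-retest
#' variability.
#'
#' @param rf60,rf90 per-lesion feature values at 60 and 90 min on day 1.
#' @param rf60_retest per-lesion feature values at 60 min on day 2.
#' @return List with `z` (per lesion), `mean_z`, `sd_z`, and `trt60`.
#' @export
uptake_z <- function(rf60, rf90, rf60_retest) {
  if (length(rf60) != length(rf90) || length(rf60) != length(rf60_retest))
    stop("per-lesion vectors must be aligned")
  if (length(rf60) < 2) stop("z score needs at least 2 lesions")
  trt60 <- rf60_retest - rf60
  s <- sd(trt60)
  if (!is.finite(s) || s == 0)
    stop("degenerate test-retest: sd(TRT60) = 0")
  z <- ((rf90 - rf60) - mean(trt60)) / s
  list(z = z, mean_z = mean(z), sd_z = sd(z), trt60 = trt60)
}

#' Classify one feature into a use case
#'
#' Flowchart rule: a feature is repeatable only if both ICCs exceed the
#' gate (default 0.9), otherwise it is discarded. A repeatable feature
#' that is significantly affected by uptake time (FDR-adjusted q below
#' `alpha`) *and* changes by more than test-retest variability
#' (`|mean z| >= z_gate`) is usable for dual-time-point imaging (DTP). A
#' repeatable feature that is clearly unaffected (not significant and
#' `|mean z| < z_gate`) is robust: cross-sectional level 2 (CS2). The
#' remaining repeatable features have an unclear time dependence:
#' cross-sectional level 1 (CS1).
#'
#' @param icc60,icc90 repeatability ICCs at the two uptake times.
#' @param q FDR-adjusted p-value of the uptake-time Wilcoxon test.
#' @param mean_z mean uptake-time z score across lesions.
#' @param icc_gate,alpha,z_gate decision thresholds.
#' @return One of `"DTP"`, `"CS1"`, `"CS2"`, `"DISCARDED"`.
#' @examples
#' classify_feature(0.95, 0.95, q = 0.01, mean_z = 1.5)  # "DTP"
#' classify_feature(0.85, 0.95, q = 0.01, mean_z = 1.5)  # "DISCARDED"
#' @export
classify_feature <- function(icc60, icc90, q, mean_z,
                             icc_gate = 0.9, alpha = 0.05, z_gate = 1.0) {
  stopifnot(is.finite(icc60), is.finite(icc90), is.finite(q),
            is.finite(mean_z))
  if (icc60 <= icc_gate || icc90 <= icc_gate) return("DISCARDED")
  sig <- q < alpha
  big <- abs(mean_z) >= z_gate
  if (sig && big) return("DTP")
  if (!sig && !big) return("CS2")
  "CS1"
}

#' Classify every feature of a longitudinal feature table
#'
#' Runs, per feature: the paired Wilcoxon test on the day-1 (60, 90 min)
#' values across lesions; ICC between day 1 and day 2 at each uptake time;
#' and the uptake-time z score. The Benjamini-Hochberg correction is
#' applied jointly across all analyzed features, and each feature is
#' assigned a use case with [classify_feature()].
#'
#' @param table long-format feature table with columns `lesion`, `day`,
#'   `time_min`, `feature`, `value` (as produced by
#'   [extract_study_features()]); additional metadata columns are ignored.
#' @param icc_gate,alpha,z_gate decision thresholds.
#' @return Data frame with one row per analyzable feature: `feature`,
#'   `class`, `icc60`, `icc90`, `p_raw`, `q_fdr`, `mean_z`, `sd_z`,
#'   `use_case`. Features with incomplete lesion coverage are dropped with
#'   a message.
#' @export
classify_all <- function(table, icc_gate = 0.9, alpha = 0.05, z_gate = 1.0) {
  stopifnot(all(c("lesion", "day", "time_min", "feature", "value") %in%
                  names(table)))
  times <- sort(unique(table$time_min))
  if (length(times) != 2) stop("expected exactly two uptake times")
  days <- sort(unique(table$day))
  if (length(days) < 2) stop("expected at least two scan days")
  days <- days[1:2]
  panel <- feature_panel()
  feats <- unique(table$feature)

  cell <- function(feature, day, time) {
    sub <- table[table$feature == feature & table$day == day &
                   table$time_min == time, c("lesion", "value")]
    setNames(sub$value, sub$lesion)
  }

  rows <- list()
  skipped <- character()
  for (f in feats) {
    v60d1 <- cell(f, days[1], times[1])
    v90d1 <- cell(f, days[1], times[2])
    v60d2 <- cell(f, days[2], times[1])
    v90d2 <- cell(f, days[2], times[2])
    lesions <- Reduce(intersect, list(names(v60d1), names(v90d1),
                                      names(v60d2), names(v90d2)))
    lesions <- lesions[
      is.finite(v60d1[lesions]) & is.finite(v90d1[lesions]) &
        is.finite(v60d2[lesions]) & is.finite(v90d2[lesions])]
    if (length(lesions) < 3) {
      skipped <- c(skipped, f)
      next
    }
    icc60 <- tryCatch(
      icc_agreement_single(v60d1[lesions], v60d2[lesions]),
      error = function(e) NA_real_)
    icc90 <- tryCatch(
      icc_agreement_single(v90d1[lesions], v90d2[lesions]),
      error = function(e) NA_real_)
    p <- suppressWarnings(
      wilcoxon_signed_rank(v60d1[lesions], v90d1[lesions]))
    zres <- tryCatch(
      uptake_z(v60d1[lesions], v90d1[lesions], v60d2[lesions]),
      error = function(e) list(mean_z = NA_real_, sd_z = NA_real_))
    rows[[f]] <- data.frame(
      feature = f,
      class = panel$class[match(f, panel$feature)],
      icc60 = icc60, icc90 = icc90, p_raw = p,
      mean_z = zres$mean_z, sd_z = zres$sd_z,
      n_lesions = length(lesions),
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    message("excluded ", length(skipped),
            " feature(s) with incomplete data: ",
            paste(skipped, collapse = ", "))
  if (!length(rows)) stop("no analyzable features")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_fdr <- bh_fdr(out$p_raw)
  out$use_case <- vapply(seq_len(nrow(out)), function(i) {
    r <- out[i, ]
    if (!is.finite(r$icc60) || !is.finite(r$icc90) ||
        !is.finite(r$q_fdr) || !is.finite(r$mean_z)) return("DISCARDED")
    classify_feature(r$icc60, r$icc90, r$q_fdr, r$mean_z,
                     icc_gate = icc_gate, alpha = alpha, z_gate = z_gate)
  }, character(1))
  out[, c("feature", "class", "icc60", "icc90", "p_raw", "q_fdr",
          "mean_z", "sd_z", "n_lesions", "use_case")]
}
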