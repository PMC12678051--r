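#' Fit reference-cohort normalization statistics
#'
#' Computes per-biomarker mean and sample (n-1) standard deviation from
#' a reference (healthy-control-like) table, together with the direction
#' in which each biomarker becomes abnormal. Volumes and T1/T2 ratios
#' decrease with pathology (`direction = "decrease"`); lesion volume
#' increases (`direction = "increase"`). Lesion-volume columns are
#' right-skewed and zero-inflated, so they are log1p-transformed before
#' the statistics are taken (configurable via `lesion_transform`).
#'
#' @param reference data.frame of raw reference biomarker values.
#' @param directions named character vector, one of `"increase"` /
#'   `"decrease"` per biomarker to be modelled.
#' @param lesion_cols names of lesion-volume columns (subject to
#'   `lesion_transform`); default `"lesion_volume"` when present.
#' @param lesion_transform `"log1p"` (default) or `"none"`.
#' @return object of class `reference_stats`: data.frame with columns
#'   `biomarker`, `mean`, `sd`, `direction`, `transform`.
#' @export
fit_reference_stats <- function(reference, directions,
                                lesion_cols = intersect("lesion_volume",
                                                        names(reference)),
                                lesion_transform = c("log1p", "none")) {
  lesion_transform <- match.arg(lesion_transform)
  if (is.null(names(directions)) ||
      !all(names(directions) %in% names(reference)))
    stop("directions must be named by reference columns", call. = FALSE)
  if (!all(directions %in% c("increase", "decrease")))
    stop("directions must be 'increase' or 'decrease'", call. = FALSE)
  stats_list <- lapply(names(directions), function(b) {
    x <- reference[[b]]
    if (sum(is.finite(x)) < 2L)
      stop("need at least 2 reference values for '", b, "'",
           call. = FALSE)
    tr <- if (b %in% lesion_cols) lesion_transform else "none"
    if (tr == "log1p") x <- log1p(x)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("degenerate reference: zero variance in '", b, "'",
           call. = FALSE)
    data.frame(biomarker = b, mean = mean(x), sd = s,
               direction = unname(directions[[b]]), transform = tr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, stats_list)
  class(out) <- c("reference_stats", "data.frame")
  out
}

#' Convert raw biomarker values to signed abnormality z-scores
#'
#' `z = (x - mean) / sd` against the reference statistics, sign-flipped
#' for `direction = "decrease"` biomarkers so that larger z always means
#' more abnormal. Columns without an entry in `stats` (e.g. sNfL, which
#' arrives as a pre-standardized age-adjusted z-score, and bookkeeping
#' columns) pass through unchanged. Lesion columns are transformed as
#' recorded in `stats` before scaling.
#'
#' @param raw data.frame with the raw biomarker columns.
#' @param stats a [fit_reference_stats()] object.
#' @return data.frame of the same shape with z-scored biomarkers.
#' @export
to_abnormality_z <- function(raw, stats) {
  if (!all(stats$biomarker %in% names(raw)))
    stop("raw table lacks biomarkers present in the reference stats",
         call. = FALSE)
  out <- raw
  for (i in seq_len(nrow(stats))) {
    b <- stats$biomarker[i]
    x <- raw[[b]]
    if (any(!is.finite(x)))
      stop("non-finite raw values in '", b, "'", call. = FALSE)
    if (stats$transform[i] == "log1p") x <- log1p(x)
    z <- (x - stats$mean[i]) / stats$sd[i]
    if (stats$direction[i] == "decrease") z <- -z
    out[[b]] <- z
  }
  out
}

#' Invert abnormality z-scores back to the raw scale
#'
#' The z-scoring is affine and invertible per biomarker; this undoes it
#' (including the sign flip and any lesion transform). Used mainly by
#' the synthetic generator to emit raw-scale tables.
#'
#' @param z data.frame of abnormality z-scores.
#' @param stats a [fit_reference_stats()] object.
#' @return data.frame on the raw scale.
#' @export
from_abnormality_z <- function(z, stats) {
  out <- z
  for (i in seq_len(nrow(stats))) {
    b <- stats$biomarker[i]
    zz <- z[[b]]
    if (stats$direction[i] == "decrease") zz <- -zz
    x <- zz * stats$sd[i] + stats$mean[i]
    if (stats$transform[i] == "log1p") x <- expm1(x)
    out[[b]] <- x
  }
  out
}
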