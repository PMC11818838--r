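# Batch summary statistics of the study: coefficient of variation,
# relative range of angular displacement (RDiff), compression summaries
# and per-variant flexion-extension summaries.

#' Coefficient of variation
#'
#' `100 * SD / mean` with the sample (n - 1) standard deviation.
#'
#' @param values Non-empty numeric vector with non-zero mean.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(1, 2, 3))  # 50
#' @export
coefficient_of_variation <- function(values) {
  if (!is.numeric(values) || length(values) == 0L || any(!is.finite(values)))
    stop("'values' must be a non-empty finite numeric vector", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("CV is undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Relative change of angular displacement (RDiff)
#'
#' `100 * (max - min) / mean` of a batch of angular ranges: the spread of
#' the flexion-extension range across the material samples of one model
#' variant, relative to its mean.
#'
#' @param ranges Non-empty numeric vector of angular ranges (deg) with
#'   positive mean.
#' @return RDiff in percent.
#' @examples
#' rdiff(c(9, 10))       # 10.526
#' rdiff(c(70, 74, 78))  # 10.811
#' @export
rdiff <- function(ranges) {
  if (!is.numeric(ranges) || length(ranges) == 0L || any(!is.finite(ranges)))
    stop("'ranges' must be a non-empty finite numeric vector", call. = FALSE)
  m <- mean(ranges)
  if (m <= 0) stop("RDiff requires a positive mean range", call. = FALSE)
  100 * (max(ranges) - min(ranges)) / m
}

#' Compression-stage summary
#'
#' Mean, sample SD, CV, minimum and maximum of the contact force at full
#' indentation, per tissue group and pooled over both groups.
#'
#' @param healthy,oa Numeric vectors of contact forces (N) at the full
#'   indentation, one per material sample; equal lengths.
#' @return An object of class `compression_summary`: a data frame with
#'   rows `healthy`, `oa`, `combined` and columns `n`, `mean_N`, `sd_N`,
#'   `cv_pct`, `min_N`, `max_N`.
#' @export
summarize_compression <- function(healthy, oa) {
  if (length(healthy) != length(oa))
    stop("group force vectors must have equal length", call. = FALSE)
  row <- function(x) data.frame(
    n = length(x), mean_N = mean(x), sd_N = stats::sd(x),
    cv_pct = coefficient_of_variation(x), min_N = min(x), max_N = max(x))
  out <- rbind(healthy = row(healthy), oa = row(oa),
               combined = row(c(healthy, oa)))
  class(out) <- c("compression_summary", class(out))
  out
}

#' @export
print.compression_summary <- function(x, ...) {
  cat("Contact force at full indentation\n")
  print.data.frame(round(as.data.frame(x), 2))
  invisible(x)
}

#' Per-variant flexion-extension summary
#'
#' Summarises the paired healthy/OA batches of one ligament-system
#' variant: RDiff and CV of the angular ranges per group and pooled, the
#' maximum pooled range, and per-ligament CVs of the branch force maxima
#' (maximum flexion-branch force for PCL, MCL and LCL; maximum
#' extension-branch force for the ACL, which is inactive in flexion).
#'
#' @param records A data frame with one row per (group, sample) run:
#'   columns `group` (`"healthy"`/`"oa"`), `sample`, `range_deg`,
#'   `ACL_ext_N`, `PCL_flex_N`, `MCL_flex_N`, `LCL_flex_N`.
#' @param variant Variant id stored in the output row (default 1).
#' @return A one-row data frame with columns `variant`, `RDiff_H`,
#'   `CV_H`, `RDiff_OA`, `CV_OA`, `RDiff_C`, `CV_C`, `Range_C_deg` and
#'   `CV_<lig>_<grp>` for the four ligaments in both groups.
#' @export
summarize_variant <- function(records, variant = 1L) {
  need <- c("group", "sample", "range_deg", "ACL_ext_N", "PCL_flex_N",
            "MCL_flex_N", "LCL_flex_N")
  if (!all(need %in% names(records)))
    stop("missing columns: ", paste(setdiff(need, names(records)),
                                    collapse = ", "), call. = FALSE)
  h <- records[records$group == "healthy", ]
  o <- records[records$group == "oa", ]
  if (nrow(h) == 0L || nrow(o) == 0L || nrow(h) != nrow(o))
    stop("records must hold paired healthy and oa batches", call. = FALSE)
  h <- h[order(h$sample), ]; o <- o[order(o$sample), ]
  lig_cv <- function(d, col) coefficient_of_variation(d[[col]])
  data.frame(
    variant = variant,
    RDiff_H = rdiff(h$range_deg), CV_H = coefficient_of_variation(h$range_deg),
    RDiff_OA = rdiff(o$range_deg), CV_OA = coefficient_of_variation(o$range_deg),
    RDiff_C = rdiff(c(h$range_deg, o$range_deg)),
    CV_C = coefficient_of_variation(c(h$range_deg, o$range_deg)),
    Range_C_deg = max(c(h$range_deg, o$range_deg)),
    CV_ACL_H = lig_cv(h, "ACL_ext_N"), CV_ACL_OA = lig_cv(o, "ACL_ext_N"),
    CV_PCL_H = lig_cv(h, "PCL_flex_N"), CV_PCL_OA = lig_cv(o, "PCL_flex_N"),
    CV_LCL_H = lig_cv(h, "LCL_flex_N"), CV_LCL_OA = lig_cv(o, "LCL_flex_N"),
    CV_MCL_H = lig_cv(h, "MCL_flex_N"), CV_MCL_OA = lig_cv(o, "MCL_flex_N"))
}
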