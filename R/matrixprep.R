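#' Median-center an intensity matrix
#'
#' Subtracts each row's (analyte's) median — or each column's (sample's)
#' when `axis = "cols"` — so that centered medians are exactly 0. This is
#' the standard display preprocessing for protein-array heatmaps.
#'
#' @param m Numeric matrix (rows = analytes, columns = samples) with finite
#'   values and dimnames.
#' @param axis `"rows"` (default, per analyte) or `"cols"` (per sample).
#' @return Centered matrix of the same shape.
#' @export
median_center <- function(m, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("matrix must be numeric")
  if (any(!is.finite(m))) stop("matrix values must be finite")
  if (axis == "rows") {
    if (ncol(m) < 1)
      stop(sprintf("empty row(s): %s",
                   paste(rownames(m), collapse = ", ")))
    m - apply(m, 1, stats::median)
  } else {
    if (nrow(m) < 1)
      stop(sprintf("empty column(s): %s",
                   paste(colnames(m), collapse = ", ")))
    sweep(m, 2, apply(m, 2, stats::median))
  }
}

#' Clip matrix values into a fixed display range
#'
#' Saturates values below `lo` at `lo` and above `hi` at `hi`; values
#' already inside the range pass through unchanged (so the operation is
#' idempotent). The conventional heatmap display range is \[-3, 3\].
#'
#' @param m Numeric matrix.
#' @param lo,hi Range bounds, `hi > lo` (defaults -3, 3).
#' @return Clipped matrix of the same shape.
#' @export
scale_to_range <- function(m, lo = -3, hi = 3) {
  if (!is.numeric(lo) || !is.numeric(hi) || hi <= lo)
    stop("'hi' must exceed 'lo'")
  m <- as.matrix(m)
  m[m < lo] <- lo
  m[m > hi] <- hi
  m
}
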