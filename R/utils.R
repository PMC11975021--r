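## shared input checks

.check_peaks <- function(peaks) {
  need <- c("peak_id", "chrom", "start", "end")
  if (!is.data.frame(peaks) || !all(need %in% names(peaks))) {
    stop("peaks must be a data frame with columns: ", paste(need, collapse = ", "))
  }
  if (any(peaks$start >= peaks$end)) {
    bad <- which(peaks$start >= peaks$end)[1]
    stop("malformed peak interval (start >= end) at row ", bad, ": ",
         peaks$peak_id[bad])
  }
  if (anyDuplicated(peaks$peak_id)) stop("duplicate peak_ids")
  ord <- order(peaks$chrom, peaks$start)
  if (!identical(ord, seq_len(nrow(peaks)))) {
    stop("peaks must be sorted by (chrom, start)")
  }
  invisible(TRUE)
}

#' Percentage of a count relative to a total
#'
#' Small reporting helper used when recomputing printed cohort arithmetic:
#' `100 * n / total`, rounded to `digits`.
#'
#' @param n,total Counts.
#' @param digits Decimal places (default 1, matching typical cohort tables).
#' @return Numeric percentage.
#' @export
pct <- function(n, total, digits = 1) round(100 * n / total, digits)
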