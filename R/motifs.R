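#' Directional motif representation test
#'
#' For each transcription-factor motif, compares its occurrence among peaks
#' more accessible in cases (`up_peaks`) versus peaks more accessible in
#' controls (`down_peaks`) with a two-sided Fisher exact test on the 2x2
#' table (peaks with / without the motif in each set). The fold change is
#' the ratio of occurrence proportions, so a motif four times as frequent in
#' case-enriched chromatin has fold 4. By default occurrence is binary per
#' peak (at least one hit); `mode = "hits"` weights peaks by their hit
#' counts instead.
#'
#' Motifs absent from both peak sets are skipped. The same exact-test
#' implementation as [fisher_obs_exp()] is used.
#'
#' @param motif_hits Data frame `peak_id`, `motif_id`, `n_hits`.
#' @param up_peaks,down_peaks Disjoint character vectors of peak ids.
#' @param alpha Nominal significance threshold (default 0.01).
#' @param mode `"binary"` (default) or `"hits"`.
#' @return Data frame per motif: `motif_id`, `a`, `b`, `c`, `d`,
#'   `fold_change`, `p`, `significant`.
#' @export
directional_motif_test <- function(motif_hits, up_peaks, down_peaks,
                                   alpha = 0.01,
                                   mode = c("binary", "hits")) {
  mode <- match.arg(mode)
  if (length(intersect(up_peaks, down_peaks))) {
    stop("up_peaks and down_peaks must be disjoint")
  }
  motifs <- sort(unique(motif_hits$motif_id))
  rows <- lapply(motifs, function(m) {
    with_m <- motif_hits[motif_hits$motif_id == m & motif_hits$n_hits > 0, ]
    if (mode == "binary") {
      a <- sum(up_peaks %in% with_m$peak_id)
      c_ <- sum(down_peaks %in% with_m$peak_id)
      b <- length(up_peaks) - a
      d <- length(down_peaks) - c_
    } else {
      hits <- stats::setNames(with_m$n_hits, with_m$peak_id)
      a <- sum(hits[intersect(up_peaks, names(hits))])
      c_ <- sum(hits[intersect(down_peaks, names(hits))])
      b <- length(up_peaks) - sum(up_peaks %in% names(hits))
      d <- length(down_peaks) - sum(down_peaks %in% names(hits))
    }
    if (a + c_ == 0) return(NULL)  # motif absent from both sets
    ft <- fisher_obs_exp(a, b, c_, d)
    data.frame(motif_id = m, a = a, b = b, c = c_, d = d,
               fold_change = ft$effect, p = ft$p,
               significant = ft$p < alpha, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(motif_id = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), fold_change = numeric(0),
                      p = numeric(0), significant = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
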