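#' Case-control differential testing on pseudobulk read totals
#'
#' For each (lineage, timepoint) stratum, case reads per feature are pooled
#' over case donors' pseudobulk totals and control reads over control donors,
#' and each feature is tested with [fisher_obs_exp()] against all other
#' features' reads. Benjamini-Hochberg correction is applied within
#' (modality, timepoint) across lineages and features by default, or pooled
#' across timepoints with `bh_by = "modality"`. Features with zero reads in
#' both groups within a stratum are excluded from testing and from the BH
#' denominator.
#'
#' When `case_subset` is supplied (a vector of case donor ids), the analysis
#' is restricted to those cases and to the controls sharing their `pair_id`,
#' mirroring the matched-pair subgroup design.
#'
#' @param pb A `pseudobulk` object ([make_pseudobulk()]).
#' @param samples Data frame with columns `donor_id`, `status`
#'   (`case`/`control`) and `pair_id` (each pair one case and one control).
#' @param fdr FDR threshold used for the `significant` flag (default 0.10).
#' @param case_subset Optional character vector of case donor ids.
#' @param bh_by `"modality_timepoint"` (default) or `"modality"`.
#' @param verbose Emit per-stratum messages.
#' @return Data frame with one row per tested (feature, lineage, timepoint):
#'   `feature_id`, `lineage`, `timepoint`, `modality`, the table entries
#'   `a`, `b`, `c`, `d`, `effect`, `direction` (`up_in_cases` /
#'   `up_in_controls`), `p`, `q`, `significant`.
#' @export
run_differential <- function(pb, samples, fdr = 0.10, case_subset = NULL,
                             bh_by = c("modality_timepoint", "modality"),
                             verbose = FALSE) {
  stopifnot(inherits(pb, "pseudobulk"), is.data.frame(samples))
  bh_by <- match.arg(bh_by)
  .check_pairs(samples)
  cases <- samples$donor_id[samples$status == "case"]
  controls <- samples$donor_id[samples$status == "control"]
  if (!is.null(case_subset)) {
    unknown <- setdiff(case_subset, cases)
    if (length(unknown)) {
      stop("case_subset contains non-case donor(s): ",
           paste(unknown, collapse = ", "))
    }
    cases <- intersect(cases, case_subset)
    keep_pairs <- samples$pair_id[samples$donor_id %in% cases]
    controls <- samples$donor_id[samples$status == "control" &
                                   samples$pair_id %in% keep_pairs]
    missing_ctrl <- setdiff(keep_pairs,
                            samples$pair_id[samples$donor_id %in% controls])
    if (length(missing_ctrl)) {
      stop("missing matched control for pair(s): ",
           paste(missing_ctrl, collapse = ", "))
    }
  }
  keys <- pb$keys
  out <- list()
  for (tp in sort(unique(keys$timepoint))) {
    for (lin in intersect(parent_lineages(), unique(keys$lineage))) {
      case_cols <- keys$key[keys$timepoint == tp & keys$lineage == lin &
                              keys$donor_id %in% cases]
      ctrl_cols <- keys$key[keys$timepoint == tp & keys$lineage == lin &
                              keys$donor_id %in% controls]
      if (length(case_cols) == 0 || length(ctrl_cols) == 0) {
        warning(sprintf("stratum %s/%s skipped: missing %s donors",
                        lin, tp,
                        if (length(case_cols) == 0) "case" else "control"))
        next
      }
      a <- rowSums(pb$counts[, case_cols, drop = FALSE])
      c_ <- rowSums(pb$counts[, ctrl_cols, drop = FALSE])
      tested <- a + c_ > 0
      if (!any(tested)) next
      a <- a[tested]; c_ <- c_[tested]
      b <- sum(a) - a
      d <- sum(c_) - c_
      ft <- fisher_obs_exp(a, b, c_, d)
      out[[paste(tp, lin)]] <- data.frame(
        feature_id = rownames(pb$counts)[tested],
        lineage = lin, timepoint = tp, modality = pb$modality,
        a = a, b = b, c = c_, d = d,
        effect = ft$effect,
        direction = ifelse(ft$effect > 1, "up_in_cases", "up_in_controls"),
        p = ft$p, row.names = NULL, stringsAsFactors = FALSE)
      if (verbose) {
        message(sprintf("stratum %s/%s: %d features tested", lin, tp, sum(tested)))
      }
    }
  }
  if (length(out) == 0) {
    stop("no testable stratum: pseudobulk lacks case/control coverage")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  grp <- if (bh_by == "modality_timepoint") res$timepoint else res$modality
  res$q <- NA_real_
  for (g in unique(grp)) {
    sel <- grp == g
    res$q[sel] <- bh_fdr(res$p[sel])
  }
  res$significant <- res$q < fdr
  res
}

.check_pairs <- function(samples) {
  need <- c("donor_id", "status", "pair_id")
  if (!all(need %in% names(samples))) {
    stop("samples must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(samples$status %in% c("case", "control"))) {
    stop("status must be 'case' or 'control'")
  }
  tab <- table(samples$pair_id, samples$status)
  if (any(tab > 1)) {
    stop("each pair_id must map to exactly one case and one control")
  }
  invisible(TRUE)
}
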