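#' Classify autoantibody-order endotypes
#'
#' Assigns a disease endotype from the set of autoantibodies detected in the
#' first autoantibody-positive sample. The strict IAA-first endotype requires
#' insulin autoantibody (IAA) to be the only detectable antibody; the looser
#' one allows multiple antibodies as long as GADA is absent. GADA-first
#' strict/loose are defined symmetrically. Samples positive for both IAA and
#' GADA (and any set containing neither) fall into `other`. The categories
#' are mutually exclusive; cumulative reporting where loose includes strict
#' is provided by [endotype_counts()].
#'
#' @param antibodies A character vector of antibody names (a single set), or
#'   a list of such vectors. Valid names: `IAA`, `GADA`, `IA2A`, `ZnT8A`.
#' @return Character vector of endotypes: `IAA_first_strict`,
#'   `IAA_first_loose`, `GADA_first_strict`, `GADA_first_loose`, `other`.
#' @examples
#' classify_endotype(list(c("IAA"), c("IAA", "IA2A"), c("IAA", "GADA")))
#' @export
classify_endotype <- function(antibodies) {
  if (!is.list(antibodies)) antibodies <- list(antibodies)
  valid <- c("IAA", "GADA", "IA2A", "ZnT8A")
  vapply(antibodies, function(ab) {
    if (length(ab) == 0) stop("empty antibody set for a case")
    bad <- setdiff(ab, valid)
    if (length(bad)) stop("unknown antibody: ", paste(bad, collapse = ", "))
    ab <- unique(ab)
    has_iaa <- "IAA" %in% ab
    has_gada <- "GADA" %in% ab
    if (has_iaa && !has_gada) {
      if (length(ab) == 1) "IAA_first_strict" else "IAA_first_loose"
    } else if (has_gada && !has_iaa) {
      if (length(ab) == 1) "GADA_first_strict" else "GADA_first_loose"
    } else "other"
  }, character(1))
}

#' Tabulate endotype labels with exclusive or cumulative counting
#'
#' With `cumulative = TRUE` the looser category includes the strict one
#' (cohort tables conventionally report "IAA first, looser criterion" as
#' strict + loose); with `cumulative = FALSE` the mutually exclusive counts
#' are returned.
#'
#' @param endotypes Character vector of endotype labels for cases.
#' @param cumulative Fold strict counts into the loose rows (default FALSE).
#' @return Data frame `endotype`, `n`, `pct` (percent of cases).
#' @export
endotype_counts <- function(endotypes, cumulative = FALSE) {
  lv <- c("IAA_first_strict", "IAA_first_loose",
          "GADA_first_strict", "GADA_first_loose", "other")
  n <- as.integer(table(factor(endotypes, levels = lv)))
  names(n) <- lv
  if (cumulative) {
    n["IAA_first_loose"] <- n["IAA_first_loose"] + n["IAA_first_strict"]
    n["GADA_first_loose"] <- n["GADA_first_loose"] + n["GADA_first_strict"]
  }
  data.frame(endotype = lv, n = unname(n),
             pct = pct(unname(n), length(endotypes)),
             stringsAsFactors = FALSE)
}

#' Donors belonging to an endotype group
#'
#' Resolves an analysis group to case donor ids. For a `*_loose` group the
#' strict endotype is included by default (the looser criterion subsumes the
#' strict one); set `cumulative = FALSE` for the exclusive category.
#'
#' @param samples Sample table with `donor_id`, `status`, `endotype`.
#' @param group One of the endotype labels.
#' @param cumulative Include strict cases in a loose group (default TRUE).
#' @return Character vector of case donor ids.
#' @export
endotype_donors <- function(samples, group, cumulative = TRUE) {
  labels <- group
  if (cumulative && grepl("_loose$", group)) {
    labels <- c(sub("_loose$", "_strict", group), group)
  }
  samples$donor_id[samples$status == "case" & samples$endotype %in% labels]
}

#' Endotype subgroup differential analysis
#'
#' Runs the matched-pair case-control differential machinery restricted to
#' the cases of one endotype and their paired controls; identical to
#' [run_differential()] with `case_subset`.
#'
#' @param pb A `pseudobulk` object.
#' @param samples Sample table with `endotype` column.
#' @param group Endotype group label (see [endotype_donors()]).
#' @param cumulative Passed to [endotype_donors()].
#' @param ... Further arguments to [run_differential()].
#' @return Differential table as from [run_differential()].
#' @export
endotype_differential <- function(pb, samples, group, cumulative = TRUE, ...) {
  donors <- endotype_donors(samples, group, cumulative)
  if (length(donors) == 0) stop("no case donors with endotype ", group)
  run_differential(pb, samples, case_subset = donors, ...)
}

#' Overlap of subgroup and overall replicated signals
#'
#' Per (lineage, timepoint, direction) stratum, the fraction of overall
#' replicated case-control signals also present, with the same direction, in
#' the subgroup's replicated set. Strata with no overall signal are reported
#' with `NA`.
#'
#' @param subgroup_replicated,overall_replicated Replicated-set data frames
#'   from [assess_replication()] (`$replicated`), keyed by `feature_id`,
#'   `lineage`, `timepoint`, `direction`.
#' @return Data frame `lineage`, `timepoint`, `direction`, `n_overall`,
#'   `n_shared`, `fraction`.
#' @export
overlap_with_overall <- function(subgroup_replicated, overall_replicated) {
  keyify <- function(x) paste(x$feature_id, x$lineage, x$timepoint,
                              x$direction, sep = "|")
  sub_keys <- keyify(subgroup_replicated)
  strata <- unique(overall_replicated[, c("lineage", "timepoint", "direction")])
  if (nrow(strata) == 0) {
    return(data.frame(lineage = character(0), timepoint = character(0),
                      direction = character(0), n_overall = integer(0),
                      n_shared = integer(0), fraction = numeric(0)))
  }
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    sel <- overall_replicated$lineage == strata$lineage[i] &
      overall_replicated$timepoint == strata$timepoint[i] &
      overall_replicated$direction == strata$direction[i]
    keys <- keyify(overall_replicated[sel, , drop = FALSE])
    n <- length(keys)
    shared <- sum(keys %in% sub_keys)
    data.frame(lineage = strata$lineage[i], timepoint = strata$timepoint[i],
               direction = strata$direction[i], n_overall = n,
               n_shared = shared,
               fraction = if (n > 0) shared / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$lineage, out$timepoint, out$direction), ]
}
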