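#' Null calibration study
#'
#' Simulates `n_replicates` null cohorts (no planted effects, Poisson
#' counts) under the default desk-scale conditions and, per replicate,
#' records (i) the mean empirical false-discovery proportion of the
#' differential stage across its BH correction families (one family per
#' modality and timepoint; with all features null the family FDP is 1 when
#' the family rejects anything and 0 otherwise) and (ii) the fraction of
#' candidate peak-gene pairs reaching nominal p < 0.05 in the link discovery
#' stage, which should sit near the nominal 5%.
#'
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param n_replicates Number of null cohorts (default 20).
#' @param fdr FDR threshold (default 0.10).
#' @param ... Overrides forwarded to [sim_config()].
#' @return Data frame with one row per replicate: `replicate`, `fdp`,
#'   `link_nominal_rate`, `n_tests`, `n_pairs_tested`.
#' @export
null_calibration_study <- function(seed, n_replicates = 20, fdr = 0.10, ...) {
  rows <- lapply(seq_len(n_replicates), function(r) {
    sim <- simulate_null(sim_config(seed = seed + r, ...))
    pbs <- suppressMessages(pseudobulk_all(sim$bundle))
    diffs <- lapply(pbs, run_differential, samples = sim$bundle$samples,
                    fdr = fdr)
    fam_fdp <- unlist(lapply(diffs, function(tab) {
      vapply(split(tab$significant, tab$timepoint),
             function(s) as.numeric(any(s)), numeric(1))
    }))
    pairs <- candidate_pairs(sim$bundle$peaks, sim$bundle$genes)
    lk <- suppressMessages(link_correlation(pbs$snATAC, pbs$snRNA, pairs))
    data.frame(replicate = r, fdp = mean(fam_fdp),
               link_nominal_rate = mean(lk$p_discovery < 0.05, na.rm = TRUE),
               n_tests = sum(vapply(diffs, nrow, integer(1))),
               n_pairs_tested = sum(!is.na(lk$p_discovery)))
  })
  do.call(rbind, rows)
}

#' Planted-effect recovery study
#'
#' Runs the full pipeline on one cohort generated with the default recovery
#' conditions ([recovery_config()]) and measures how much of the planted
#' structure is recovered: the fraction of planted two-fold monocyte-T1
#' genes significant at the FDR threshold with the correct direction; the
#' fractions of planted links discovered and validated; and the fraction of
#' planted QTL (SNV, feature) pairs whose best |rho| exceeds the 95th
#' percentile of the non-planted scan.
#'
#' @param seed Seed for [recovery_config()] and the simulation.
#' @param fdr FDR threshold (default 0.10).
#' @param ... Overrides forwarded to [recovery_config()].
#' @return List with `de_recovery`, `link_recovery`, `link_validation`,
#'   `qtl_rank_rate`, plus the underlying pipeline result in `result`.
#' @export
recovery_study <- function(seed, fdr = 0.10, ...) {
  res <- suppressMessages(suppressWarnings(
    run_pipeline(recovery_config(seed, ...), fdr = fdr)))
  truth <- res$truth
  de_genes <- truth$de$feature_id[grepl("^g", truth$de$feature_id)]
  d <- res$differential$snRNA
  hit <- d[d$feature_id %in% de_genes & d$lineage == "Monocyte" &
             d$timepoint == "T1", ]
  up <- truth$de$feature_id[truth$de$lfc > 0]
  ok_dir <- ifelse(hit$feature_id %in% up, hit$direction == "up_in_cases",
                   hit$direction == "up_in_controls")
  de_recovery <- if (nrow(hit)) mean(hit$significant & ok_dir) else NA_real_

  lk <- res$links
  key <- paste(lk$peak_id, lk$gene_id)
  truth_key <- paste(truth$links$peak_id, truth$links$gene_id)
  planted <- lk[key %in% truth_key, , drop = FALSE]
  link_recovery <- mean(planted$discovered)
  link_validation <- mean(planted$discovered & planted$validated)

  q <- res$qtl
  qkey <- paste(q$snv_id, q$feature_id)
  tkey <- paste(truth$qtls$snv_id, truth$qtls$feature_id)
  qtl_rank_rate <- if (length(tkey)) {
    best <- tapply(abs(q$rho[qkey %in% tkey]), qkey[qkey %in% tkey], max)
    cut <- stats::quantile(abs(q$rho[!qkey %in% tkey]), 0.95, na.rm = TRUE)
    mean(best > cut)
  } else NA_real_

  list(de_recovery = de_recovery, link_recovery = link_recovery,
       link_validation = link_validation, qtl_rank_rate = qtl_rank_rate,
       result = res)
}

#' Endotype-design overlap study
#'
#' Simulates `n_replicates` cohorts under [endotype_design_config()] (half
#' of the planted monocyte-T1 effects restricted to GADA-first cases) and,
#' per replicate, computes the monocyte-T1 overlap fraction of the overall
#' replicated case-control signals with the GADA-first and with the
#' IAA-first subgroup replicated signals. Under this design the GADA-first
#' overlap should exceed the IAA-first overlap.
#'
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param n_replicates Number of cohorts (default 20).
#' @param fdr FDR threshold (default 0.10).
#' @param ... Overrides forwarded to [endotype_design_config()].
#' @return Data frame per replicate: `replicate`, `gada_overlap`,
#'   `iaa_overlap`, `n_overall` (overall replicated monocyte-T1 signals).
#' @export
endotype_overlap_study <- function(seed, n_replicates = 20, fdr = 0.10, ...) {
  rows <- lapply(seq_len(n_replicates), function(r) {
    sim <- simulate_cohort(endotype_design_config(seed + r, ...))
    pbs <- suppressMessages(pseudobulk_all(sim$bundle))
    samples <- sim$bundle$samples
    diffs <- lapply(pbs, run_differential, samples = samples, fdr = fdr)
    pairs <- candidate_pairs(sim$bundle$peaks, sim$bundle$genes)
    lk <- suppressMessages(link_correlation(pbs$snATAC, pbs$snRNA, pairs))
    disc <- lk[lk$discovered, , drop = FALSE]
    overall <- assess_replication(diffs, links = disc, q_threshold = fdr)
    frac <- function(group) {
      donors <- endotype_donors(samples, group)
      if (length(donors) == 0) return(NA_real_)
      ediffs <- suppressWarnings(lapply(
        pbs, run_differential, samples = samples, fdr = fdr,
        case_subset = donors))
      erepl <- assess_replication(ediffs, links = disc, q_threshold = fdr)
      ov <- overlap_with_overall(erepl$replicated, overall$replicated)
      sel <- ov$lineage == "Monocyte" & ov$timepoint == "T1"
      if (sum(ov$n_overall[sel]) == 0) return(NA_real_)
      sum(ov$n_shared[sel]) / sum(ov$n_overall[sel])
    }
    mono_t1 <- overall$replicated$lineage == "Monocyte" &
      overall$replicated$timepoint == "T1"
    data.frame(replicate = r, gada_overlap = frac("GADA_first_loose"),
               iaa_overlap = frac("IAA_first_strict"),
               n_overall = sum(mono_t1))
  })
  do.call(rbind, rows)
}
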