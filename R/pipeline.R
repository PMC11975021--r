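#' Normalized pseudobulk for every layer of a bundle
#'
#' Convenience wrapper: [make_pseudobulk()] + [normalize_per_million()] per
#' layer.
#'
#' @param bundle A `cohort_bundle`.
#' @param lineage_map Passed to [make_pseudobulk()].
#' @return Named list of normalized `pseudobulk` objects.
#' @export
pseudobulk_all <- function(bundle, lineage_map = default_lineage_map()) {
  lapply(bundle$layers, function(lay) {
    normalize_per_million(make_pseudobulk(lay, bundle$cells, lineage_map))
  })
}

#' Run the full case-control multiome analysis pipeline
#'
#' Executes, in order: simulation (when `config` is a [sim_config()]) or use
#' of a supplied bundle; pseudobulk aggregation and normalization per layer;
#' differential testing per modality; peak-gene link discovery and
#' validation; cross-layer replication; QTL scans (genes on snRNA, peaks on
#' snATAC) and locus overlap; adjacency clustering of differential peaks;
#' directional motif tests; and endotype subgroup differentials with overlap
#' against the overall replicated signals. When `out_dir` is given, each
#' stage writes one TSV/JSON and a run manifest records the seed and every
#' threshold; rerunning with the same config and seed reproduces every
#' output byte for byte.
#'
#' @param config A `sim_config` or an existing `cohort_bundle`.
#' @param out_dir Optional output directory for stage files.
#' @param fdr FDR threshold (default 0.10).
#' @param link_p,link_r Link discovery thresholds (defaults 0.05, 0.05).
#' @param validation_r Link validation threshold (default 0.65).
#' @param min_layers Replication layers including discovery (default 2).
#' @param motif_alpha Motif test threshold (default 0.01).
#' @param qtl_window Cis window for the QTL scan in bp (default 1e6).
#' @param snv_report_window Locus reporting window (default 1e5).
#' @param n_permutations Adjacency permutations (default 1000).
#' @param endotype_groups Subgroups analyzed (default IAA-first strict and
#'   GADA-first loose).
#' @return List with all stage results: `bundle`, `truth` (when simulated),
#'   `pseudobulk`, `differential`, `links`, `replication`, `qtl`,
#'   `qtl_overlap`, `adjacency`, `motifs`, `endotype`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, fdr = 0.10,
                         link_p = 0.05, link_r = 0.05, validation_r = 0.65,
                         min_layers = 2, motif_alpha = 0.01,
                         qtl_window = 1e6, snv_report_window = 1e5,
                         n_permutations = 1000,
                         endotype_groups = c("IAA_first_strict",
                                             "GADA_first_loose")) {
  if (inherits(config, "sim_config")) {
    sim <- simulate_cohort(config)
    bundle <- sim$bundle; truth <- sim$truth
    seed <- config$seed
  } else if (inherits(config, "cohort_bundle")) {
    bundle <- config; truth <- NULL
    seed <- 1L
  } else stop("config must be a sim_config or a cohort_bundle")

  pbs <- pseudobulk_all(bundle)
  diffs <- lapply(pbs, run_differential, samples = bundle$samples, fdr = fdr)

  pairs <- candidate_pairs(bundle$peaks, bundle$genes)
  links <- link_correlation(pbs$snATAC, pbs$snRNA, pairs,
                            p_threshold = link_p, r_threshold = link_r)
  links <- validate_links(links, pbs$snATAC, pbs$scRNA,
                          r_threshold = validation_r)
  disc_links <- links[links$discovered, , drop = FALSE]

  repl <- assess_replication(diffs, links = disc_links, q_threshold = fdr,
                             min_layers = min_layers)

  fpos <- feature_positions(bundle)
  qtl <- rbind(
    qtl_scan(bundle$genotypes, pbs$snRNA,
             fpos[fpos$feature_id %in% bundle$genes$gene_id, ],
             window = qtl_window),
    qtl_scan(bundle$genotypes, pbs$snATAC,
             fpos[fpos$feature_id %in% bundle$peaks$peak_id, ],
             window = qtl_window))
  qtl_overlap <- overlap_with_differential(qtl, diffs, fpos, bundle$genotypes,
                                           window = snv_report_window)

  adjacency <- adjacency_analysis(diffs$snATAC, bundle$peaks,
                                  q_threshold = fdr,
                                  n_permutations = n_permutations,
                                  seed = seed + 7L)

  atac_sig <- diffs$snATAC[diffs$snATAC$significant, , drop = FALSE]
  up <- unique(atac_sig$feature_id[atac_sig$direction == "up_in_cases"])
  down <- setdiff(unique(atac_sig$feature_id[
    atac_sig$direction == "up_in_controls"]), up)
  motifs <- if (!is.null(bundle$motif_hits) && length(up) && length(down)) {
    directional_motif_test(bundle$motif_hits, up, down, alpha = motif_alpha)
  } else NULL

  endo <- list()
  for (grp in endotype_groups) {
    donors <- endotype_donors(bundle$samples, grp)
    if (length(donors) == 0) next
    ediffs <- lapply(pbs, run_differential, samples = bundle$samples,
                     fdr = fdr, case_subset = donors)
    erepl <- assess_replication(ediffs, links = disc_links,
                                q_threshold = fdr, min_layers = min_layers)
    endo[[grp]] <- list(
      differential = ediffs, replication = erepl,
      overlap = overlap_with_overall(erepl$replicated, repl$replicated))
  }

  manifest <- list(
    package = "pbmultiome",
    version = as.character(utils::packageVersion("pbmultiome")),
    seed = seed,
    thresholds = list(fdr = fdr, link_p = link_p, link_r = link_r,
                      validation_r = validation_r, min_layers = min_layers,
                      motif_alpha = motif_alpha, qtl_window = qtl_window,
                      snv_report_window = snv_report_window,
                      n_permutations = n_permutations),
    config = if (inherits(config, "sim_config")) {
      config[c("n_pairs", "n_genes", "n_peaks", "cells_per_sample",
               "rna_depth", "atac_depth", "overdispersion", "seed")]
    } else "external bundle",
    n_cells = vapply(bundle$layers, function(l) nrow(l$counts), integer(1)))

  out <- list(bundle = bundle, truth = truth, pseudobulk = pbs,
              differential = diffs, links = links, replication = repl,
              qtl = qtl, qtl_overlap = qtl_overlap, adjacency = adjacency,
              motifs = motifs, endotype = endo, manifest = manifest)
  if (!is.null(out_dir)) .write_stage_outputs(out, out_dir)
  out
}

.write_stage_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  for (m in names(res$differential)) tsv(res$differential[[m]],
                                         sprintf("diff_%s.tsv", m))
  tsv(res$links, "links.tsv")
  tsv(res$replication$records, "replication.tsv")
  tsv(res$qtl, "qtl.tsv")
  tsv(res$qtl_overlap, "qtl_overlap.tsv")
  jsonlite::write_json(
    res$adjacency[c("observed", "expected_analytic", "expected_perm", "ratio")],
    file.path(out_dir, "adjacency.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(res$motifs)) tsv(res$motifs, "motifs.tsv")
  for (grp in names(res$endotype)) {
    tsv(res$endotype[[grp]]$overlap, sprintf("endotype_overlap_%s.tsv", grp))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
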