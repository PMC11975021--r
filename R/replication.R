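#' Cross-layer replication of differential discoveries
#'
#' Classifies each differential discovery by how many orthogonal data layers
#' independently show the same signal. For a gene discovered in an RNA
#' modality at (gene, lineage, timepoint), the candidate layers are: the
#' other RNA modality at the same (lineage, timepoint); the same modality at
#' each other timepoint; and, when a links table is supplied, snATAC peaks
#' linked to the gene at the same (lineage, timepoint). A peak discovery
#' symmetrically draws on the other snATAC timepoints and on its linked
#' gene's expression in each RNA modality. A layer replicates when the
#' corresponding test reaches `q < q_threshold` with concordant direction
#' (for linked peak-gene layers, concordance means accessibility and
#' expression change share sign). A discovery is "replicated" when the signal
#' is present in at least `min_layers` layers including the discovery itself,
#' i.e. `n_replicating >= min_layers - 1`.
#'
#' Layers whose differential table is absent from `results` are counted as
#' untested, not as failed.
#'
#' @param results Named list of differential tables from
#'   [run_differential()], named by modality (`snRNA`, `scRNA`, `snATAC`);
#'   any subset may be present.
#' @param links Optional links table with `peak_id` and `gene_id` columns
#'   (typically discovered links from [link_correlation()]).
#' @param q_threshold Significance threshold for discovery and replication
#'   (default 0.10).
#' @param min_layers Minimum number of layers (including discovery) for the
#'   replicated set (default 2).
#' @return List with `records` (one row per discovery: key columns,
#'   `layers_tested`, `layers_replicated` as comma strings, `n_replicating`,
#'   `replicated`) and `replicated` (the subset of discoveries in the
#'   replicated set, with `direction`).
#' @export
assess_replication <- function(results, links = NULL, q_threshold = 0.10,
                               min_layers = 2) {
  stopifnot(is.list(results), length(results) > 0)
  mods <- names(results)
  ## significance lookup: modality|feature|lineage|timepoint -> direction
  sig <- list()
  for (m in mods) {
    tab <- results[[m]]
    hit <- tab$q < q_threshold
    sig[[m]] <- stats::setNames(
      tab$direction[hit],
      paste(tab$feature_id[hit], tab$lineage[hit], tab$timepoint[hit], sep = "|"))
  }
  link_by_gene <- link_by_peak <- list()
  if (!is.null(links) && nrow(links) > 0) {
    link_by_gene <- split(links$peak_id, links$gene_id)
    link_by_peak <- split(links$gene_id, links$peak_id)
  }
  timepoints <- sort(unique(unlist(lapply(results, function(x) x$timepoint))))
  recs <- list()
  for (m in mods) {
    tab <- results[[m]]
    disc <- tab[tab$q < q_threshold, , drop = FALSE]
    if (nrow(disc) == 0) next
    layers_tested <- character(nrow(disc))
    layers_rep <- character(nrow(disc))
    n_rep <- integer(nrow(disc))
    for (i in seq_len(nrow(disc))) {
      f <- disc$feature_id[i]; L <- disc$lineage[i]; tp <- disc$timepoint[i]
      dir <- disc$direction[i]
      menu <- .layer_menu(m, f, L, tp, timepoints, mods,
                          link_by_gene, link_by_peak)
      hits <- vapply(menu, function(layer) {
        any(vapply(layer$keys, function(k) {
          d <- sig[[layer$modality]][k]
          !is.na(d) && d == dir
        }, logical(1)))
      }, logical(1))
      layers_tested[i] <- paste(names(menu), collapse = ",")
      layers_rep[i] <- paste(names(menu)[hits], collapse = ",")
      n_rep[i] <- sum(hits)
    }
    recs[[m]] <- data.frame(
      feature_id = disc$feature_id, lineage = disc$lineage,
      timepoint = disc$timepoint, modality = m, direction = disc$direction,
      q = disc$q, layers_tested = layers_tested,
      layers_replicated = layers_rep, n_replicating = n_rep,
      replicated = n_rep >= (min_layers - 1),
      stringsAsFactors = FALSE)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(feature_id = character(0), lineage = character(0),
               timepoint = character(0), modality = character(0),
               direction = character(0), q = numeric(0),
               layers_tested = character(0), layers_replicated = character(0),
               n_replicating = integer(0), replicated = logical(0))
  rownames(records) <- NULL
  list(records = records,
       replicated = records[records$replicated, , drop = FALSE])
}

## candidate replication layers for one discovery; each entry holds the
## modality to look in and the keys (feature|lineage|timepoint) that count.
.layer_menu <- function(modality, f, L, tp, timepoints, available,
                        link_by_gene, link_by_peak) {
  menu <- list()
  other_tp <- setdiff(timepoints, tp)
  if (modality %in% c("snRNA", "scRNA")) {
    other_rna <- setdiff(c("snRNA", "scRNA"), modality)
    if (other_rna %in% available) {
      menu[[paste0(other_rna, "@", tp)]] <-
        list(modality = other_rna, keys = paste(f, L, tp, sep = "|"))
    }
    for (t2 in other_tp) {
      menu[[paste0(modality, "@", t2)]] <-
        list(modality = modality, keys = paste(f, L, t2, sep = "|"))
    }
    pk <- link_by_gene[[f]]
    if ("snATAC" %in% available && !is.null(pk)) {
      menu[["linked_snATAC"]] <-
        list(modality = "snATAC", keys = paste(pk, L, tp, sep = "|"))
    }
  } else {
    for (t2 in other_tp) {
      menu[[paste0("snATAC@", t2)]] <-
        list(modality = "snATAC", keys = paste(f, L, t2, sep = "|"))
    }
    g <- link_by_peak[[f]]
    if (!is.null(g)) {
      for (rna in intersect(c("snRNA", "scRNA"), available)) {
        menu[[paste0("linked_", rna)]] <-
          list(modality = rna, keys = paste(g, L, tp, sep = "|"))
      }
    }
  }
  menu
}
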