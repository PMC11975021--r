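## Shared fixtures: simulated cohorts are expensive, so they are built once
## per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

## small cohort with a little of everything planted; fast (~1 s)
tiny_cohort <- function() {
  cached("tiny_cohort", {
    cfg <- recovery_config(seed = 11, n_pairs = 3, n_genes = 40, n_peaks = 60,
                           cells_per_sample = 30, n_snvs = 4,
                           n_de_genes = 4, n_de_peaks = 3, n_links = 3,
                           n_qtls = 2)
    simulate_cohort(cfg)
  })
}

## default-scale recovery cohort run through the full pipeline (~20 s)
recovery_result <- function() {
  cached("recovery_result", {
    suppressMessages(suppressWarnings(run_pipeline(recovery_config(seed = 3))))
  })
}

## hand-built toy pseudobulk: 3 features x 4 keys (2 donors x 1 tp x 2 lineages)
toy_pseudobulk <- function(modality = "snRNA") {
  counts <- matrix(c(10, 20, 30,
                     5, 10, 15,
                     8, 0, 2,
                     1, 1, 0),
                   nrow = 3,
                   dimnames = list(c("f1", "f2", "f3"),
                                   c("d1|T1|B", "d2|T1|B",
                                     "d1|T1|NK", "d2|T1|NK")))
  keys <- data.frame(key = colnames(counts),
                     donor_id = rep(c("d1", "d2"), 2),
                     timepoint = "T1",
                     lineage = rep(c("B", "NK"), each = 2),
                     n_cells = 1L, stringsAsFactors = FALSE)
  structure(list(modality = modality, counts = counts, keys = keys),
            class = "pseudobulk")
}

toy_samples <- function() {
  data.frame(donor_id = c("d1", "d2"), status = c("case", "control"),
             pair_id = "p1", endotype = c("IAA_first_strict", "none"),
             stringsAsFactors = FALSE)
}

## independent exact-test oracle: exhaustive enumeration over the
## hypergeometric support using log-binomial coefficients only
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b; N <- m + n
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(N, k)
  probs <- exp(logp)
  p0 <- probs[support == a]
  min(1, sum(probs[probs <= p0 * (1 + 1e-7)]))
}

## brute-force candidate-pair scan (quadratic reference implementation)
brute_candidate_pairs <- function(peaks, genes, max_dist = 1e6) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    mid <- (peaks$start[i] + peaks$end[i]) / 2
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      dist <- abs(mid - genes$tss[j])
      if (dist <= max_dist) {
        rows[[length(rows) + 1L]] <- data.frame(
          peak_id = peaks$peak_id[i], gene_id = genes$gene_id[j],
          distance = dist, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$peak_id, out$gene_id), ]
}

## overlap fraction for one (lineage, timepoint), pooled over directions
stratum_overlap <- function(overlap_tab, lineage, timepoint) {
  sel <- overlap_tab$lineage == lineage & overlap_tab$timepoint == timepoint
  n <- sum(overlap_tab$n_overall[sel])
  if (n == 0) return(NA_real_)
  sum(overlap_tab$n_shared[sel]) / n
}
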