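#!/usr/bin/env Rscript
## Autoantibody-order endotype analysis: subgroup differential testing of
## IAA-first and GADA-first cases against their matched controls, and the
## overlap of subgroup replicated signals with the overall case-control
## replicated set (per lineage, time point and direction).

suppressMessages(library(pbmultiome))

bundle <- read_bundle("results/bundle")
pbs <- pseudobulk_all(bundle)
diffs <- lapply(pbs, run_differential, samples = bundle$samples)
links <- utils::read.table("results/links.tsv", sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
disc <- links[links$discovered, ]
overall <- assess_replication(diffs, links = disc)

print(endotype_counts(bundle$samples$endotype[bundle$samples$status == "case"],
                      cumulative = TRUE))

for (grp in c("IAA_first_strict", "GADA_first_loose")) {
  donors <- endotype_donors(bundle$samples, grp)
  if (length(donors) == 0) { cat(grp, ": no cases\n"); next }
  ediffs <- suppressWarnings(lapply(pbs, run_differential,
                                    samples = bundle$samples,
                                    case_subset = donors))
  erepl <- assess_replication(ediffs, links = disc)
  ov <- overlap_with_overall(erepl$replicated, overall$replicated)
  utils::write.table(ov, sprintf("results/endotype_overlap_%s.tsv", grp),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mono <- ov$lineage == "Monocyte" & ov$timepoint == "T1"
  cat(sprintf("%s (%d cases): overall overlap %.0f%%; monocyte-T1 overlap %.0f%%\n",
              grp, length(donors),
              100 * sum(ov$n_shared) / max(1, sum(ov$n_overall)),
              100 * sum(ov$n_shared[mono]) / max(1, sum(ov$n_overall[mono]))))
}
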