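#!/usr/bin/env Rscript
## Lineage-collapsed pseudobulk differential testing: per-feature Fisher
## observed/expected tests per (lineage, timepoint), BH within
## (modality, timepoint), FDR 10%.

suppressMessages(library(pbmultiome))

bundle <- read_bundle("results/bundle")
pbs <- pseudobulk_all(bundle)

for (m in names(pbs)) {
  d <- run_differential(pbs[[m]], bundle$samples, fdr = 0.10)
  utils::write.table(d, sprintf("results/diff_%s.tsv", m), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sig <- d[d$significant, ]
  cat(sprintf("%s: %d tests, %d significant at q<0.10\n", m, nrow(d),
              nrow(sig)))
  counts <- table(sig$lineage, sig$timepoint)
  print(counts)
}
cat("differential tables written to results/diff_*.tsv\n")
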