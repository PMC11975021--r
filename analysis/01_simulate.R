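#!/usr/bin/env Rscript
## Build the synthetic longitudinal multiome cohort used by the downstream
## analysis scripts: 20 matched case/control pairs, three time points,
## three data layers, with planted differential genes/peaks (two-fold,
## monocytes at T1), peak-gene links and dosage QTLs.

suppressMessages(library(pbmultiome))

seed <- as.integer(Sys.getenv("COHORT_SEED", "7"))
cfg <- recovery_config(seed)
sim <- simulate_cohort(cfg)

dir.create("results", showWarnings = FALSE)
write_bundle(sim$bundle, "results/bundle")
truth <- sim$truth
utils::write.table(truth$de, "results/truth_de.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(truth$links, "results/truth_links.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(truth$qtls, "results/truth_qtls.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("cohort: %d donors, %d genes, %d peaks, seed %d\n",
            nrow(sim$bundle$samples), nrow(sim$bundle$genes),
            nrow(sim$bundle$peaks), seed))
cat(sprintf("planted: %d DE effects, %d links, %d QTLs\n",
            nrow(truth$de), nrow(truth$links), nrow(truth$qtls)))
cat("bundle written to results/bundle\n")
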