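#!/usr/bin/env Rscript
## Genotype-dosage QTL scan: Spearman rank correlation of normalized
## pseudobulk signal against alt-allele dosage for features within 1 Mb of
## each index SNV, Bonferroni per (cell type, modality); then the overlap
## of QTL loci with case-control differential features within 100 kb.

suppressMessages(library(pbmultiome))

bundle <- read_bundle("results/bundle")
pbs <- pseudobulk_all(bundle)
fpos <- feature_positions(bundle)

qtl <- rbind(
  qtl_scan(bundle$genotypes, pbs$snRNA,
           fpos[fpos$feature_id %in% bundle$genes$gene_id, ]),
  qtl_scan(bundle$genotypes, pbs$snATAC,
           fpos[fpos$feature_id %in% bundle$peaks$peak_id, ]))
utils::write.table(qtl, "results/qtl.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
hits <- qtl[qtl$p_bonf < 0.05, ]
cat(sprintf("%d QTL tests; %d Bonferroni-significant associations at %d SNVs\n",
            nrow(qtl), nrow(hits), length(unique(hits$snv_id))))

diffs <- lapply(c("snRNA", "scRNA", "snATAC"), function(m) utils::read.table(
  sprintf("results/diff_%s.tsv", m), sep = "\t", header = TRUE,
  stringsAsFactors = FALSE))
ov <- overlap_with_differential(qtl, diffs, fpos, bundle$genotypes,
                                window = 1e5)
utils::write.table(ov, "results/qtl_overlap.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat(sprintf("%d/%d loci with a QTL feature also case-control significant\n",
            sum(ov$overlap), nrow(ov)))
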