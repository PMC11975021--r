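#!/usr/bin/env Rscript
## Peak-gene cis linking: candidate pairs within 1 Mb of each TSS,
## discovery in the multiome pseudobulk (nominal p<0.05, |r|>0.05),
## validation in the unpaired layers (same sign, |r|>0.65), and the
## per-distance-bin density summary.

suppressMessages(library(pbmultiome))

bundle <- read_bundle("results/bundle")
pbs <- pseudobulk_all(bundle)

pairs <- candidate_pairs(bundle$peaks, bundle$genes)
cat(sprintf("%d candidate peak-gene pairs within 1 Mb\n", nrow(pairs)))

links <- link_correlation(pbs$snATAC, pbs$snRNA, pairs)
links <- validate_links(links, pbs$snATAC, pbs$scRNA)
utils::write.table(links, "results/links.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

disc <- links[links$discovered, ]
cat(sprintf("%d links discovered; %d (%.0f%%) validated in unpaired layers\n",
            nrow(disc), sum(disc$validated),
            100 * mean(disc$validated)))
print(table(disc$bin))
dens <- link_density(links, pairs)
print(dens)
utils::write.table(dens, "results/link_density.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
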