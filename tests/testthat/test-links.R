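test_that("candidate pairs obey the closed 1 Mb midpoint-to-TSS bound", {
  peaks <- data.frame(peak_id = "p1", chrom = "chr1", start = 100, end = 300)
  genes <- data.frame(gene_id = c("gA", "gB", "gC"),
                      chrom = c("chr1", "chr2", "chr1"),
                      tss = c(1200, 1200, 1000200), strand = "+")
  cp <- candidate_pairs(peaks, genes)
  # midpoint 200; gA at distance 1000 included; gB excluded (chr2);
  # gC at exactly 1,000,000 included (closed bound)
  expect_setequal(cp$gene_id, c("gA", "gC"))
  expect_equal(cp$distance[cp$gene_id == "gA"], 1000)
  expect_equal(cp$distance[cp$gene_id == "gC"], 1e6)
  genes$tss[3] <- 1000201
  cp2 <- candidate_pairs(peaks, genes)
  expect_equal(cp2$gene_id, "gA")
})

test_that("candidate pairs agree with the brute-force scan", {
  sim <- tiny_cohort()
  cp <- candidate_pairs(sim$bundle$peaks, sim$bundle$genes)
  bf <- brute_candidate_pairs(sim$bundle$peaks, sim$bundle$genes)
  cp <- cp[order(cp$peak_id, cp$gene_id), ]
  expect_equal(cp$peak_id, bf$peak_id)
  expect_equal(cp$gene_id, bf$gene_id)
  expect_equal(cp$distance, bf$distance)
  expect_false(any(duplicated(paste(cp$peak_id, cp$gene_id))))
})

test_that("distance bins partition [0, 1 Mb] with upward boundaries", {
  expect_equal(classify_distance(3000), "promoter")
  expect_equal(classify_distance(250000), "distal")
  expect_equal(classify_distance(5000), "proximal")    # boundary up
  expect_equal(classify_distance(c(0, 4999, 20000, 499999, 500000, 1e6)),
               c("promoter", "promoter", "distal", "distal",
                 "long_range", "long_range"))
  # no gaps or overlaps across a dense grid
  d <- seq(0, 1e6, by = 997)
  expect_false(anyNA(classify_distance(d)))
  expect_error(classify_distance(1e6 + 1), "1e6")
  expect_error(classify_distance(-1), "1e6")
})

test_that("an exact affine relationship gives r = 1", {
  pb1 <- toy_pseudobulk("snATAC")
  pb2 <- toy_pseudobulk("snRNA")
  # gene f1 normalized signal an exact positive affine function of peak f1
  pb1$cpm <- matrix(c(10, 5, 1, 20, 5, 1, 30, 5, 1, 40, 5, 1), nrow = 3,
                    dimnames = dimnames(pb1$counts))
  pb2$cpm <- pb1$cpm * 2 + 1
  pb1$zero_keys <- pb2$zero_keys <- character(0)
  pairs <- data.frame(peak_id = "f1", gene_id = "f1", distance = 0,
                      bin = "promoter")
  lk <- link_correlation(pb1, pb2, pairs, min_obs = 4)
  expect_equal(lk$r_discovery, 1, tolerance = 1e-9)
})

test_that("validation requires sign concordance and |r| strictly above 0.65", {
  links <- data.frame(peak_id = c("p1", "p2", "p3"),
                      gene_id = c("g1", "g2", "g3"),
                      r_discovery = c(0.9, 0.8, 0.8))
  fake_pb <- function(cpm, modality) {
    keys <- data.frame(key = colnames(cpm), donor_id = sprintf("d%d", 1:6),
                       timepoint = "T1", lineage = "B", n_cells = 1L)
    structure(list(modality = modality, counts = cpm, cpm = cpm, keys = keys,
                   zero_keys = character(0)), class = "pseudobulk")
  }
  kk <- sprintf("d%d|T1|B", 1:6)
  atac <- fake_pb(matrix(c(1, 2, 3, 4, 5, 6,
                           1, 2, 3, 4, 5, 6,
                           1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE,
                         dimnames = list(c("p1", "p2", "p3"), kk)), "snATAC")
  set.seed(4)
  noisy <- c(1, 2, 3, 4, 5, 6) * 0.2 + c(3, -2, 4, -4, 2, -1)  # weak, |r|<0.65
  rna <- fake_pb(matrix(c(6, 5, 4, 3, 2, 1,       # perfectly anti-correlated
                          10, 20, 30, 40, 50, 60, # perfectly correlated
                          noisy), nrow = 3, byrow = TRUE,
                        dimnames = list(c("g1", "g2", "g3"), kk)), "scRNA")
  out <- validate_links(links, atac, rna)
  expect_false(out$validated[1])  # sign discordant with discovery
  expect_lt(out$r_validation[1], 0)
  expect_true(out$validated[2])
  expect_false(out$validated[3])  # below the 0.65 magnitude threshold
  expect_lt(abs(out$r_validation[3]), 0.65)
})

test_that("link density is links per kb per gene with candidate peaks", {
  links <- data.frame(bin = c("promoter", "promoter"),
                      gene_id = c("g1", "g1"), peak_id = c("p1", "p2"),
                      discovered = TRUE)
  pairs <- data.frame(bin = rep("promoter", 3), gene_id = c("g1", "g1", "g1"),
                      peak_id = c("p1", "p2", "p3"))
  dens <- link_density(links, pairs)
  expect_equal(dens$links_per_kb[dens$bin == "promoter"], 2 / (5 * 1))
  expect_equal(dens$links_per_kb[dens$bin == "distal"], 0)
  # doubling genes with identical structure leaves density unchanged
  links2 <- rbind(links, transform(links, gene_id = "g2"))
  pairs2 <- rbind(pairs, transform(pairs, gene_id = "g2"))
  dens2 <- link_density(links2, pairs2)
  expect_equal(dens2$links_per_kb[dens2$bin == "promoter"], 2 / (5 * 1))
})

test_that("planted links are recovered and independent pairs are not", {
  res <- recovery_result()
  truth_key <- paste(res$truth$links$peak_id, res$truth$links$gene_id)
  key <- paste(res$links$peak_id, res$links$gene_id)
  planted <- res$links[key %in% truth_key, ]
  expect_equal(nrow(planted), nrow(res$truth$links))
  expect_gt(mean(planted$discovered), 0.9)
  expect_gt(mean(planted$validated), 0.9)
  expect_gt(mean(abs(planted$r_discovery)), 0.65)
})
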