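test_that("a strictly monotone dosage-signal relationship gives rho 1", {
  genotypes <- data.frame(snv_id = "rs1", chrom = "chr1", pos = 1000,
                          d1 = 0L, d2 = 1L, d3 = 2L)
  cpm <- matrix(c(10, 20, 30), 1, 3,
                dimnames = list("f1", sprintf("d%d|T1|B", 1:3)))
  pb <- structure(list(
    modality = "snRNA", counts = cpm, cpm = cpm,
    keys = data.frame(key = colnames(cpm), donor_id = sprintf("d%d", 1:3),
                      timepoint = "T1", lineage = "B", n_cells = 1L),
    zero_keys = character(0)), class = "pseudobulk")
  fpos <- data.frame(feature_id = "f1", chrom = "chr1", pos = 500)
  res <- qtl_scan(genotypes, pb, fpos, min_donors = 3)
  expect_equal(res$rho, 1, tolerance = 1e-9)
  expect_equal(res$n_donors, 3L)
})

test_that("monomorphic SNVs are skipped with a message", {
  genotypes <- data.frame(snv_id = "rs1", chrom = "chr1", pos = 1000,
                          d1 = 1L, d2 = 1L, d3 = 1L, d4 = 1L, d5 = 1L)
  cpm <- matrix(rpois(5, 20), 1, 5,
                dimnames = list("f1", sprintf("d%d|T1|B", 1:5)))
  pb <- structure(list(
    modality = "snRNA", counts = cpm, cpm = cpm,
    keys = data.frame(key = colnames(cpm), donor_id = sprintf("d%d", 1:5),
                      timepoint = "T1", lineage = "B", n_cells = 1L),
    zero_keys = character(0)), class = "pseudobulk")
  fpos <- data.frame(feature_id = "f1", chrom = "chr1", pos = 500)
  expect_message(res <- qtl_scan(genotypes, pb, fpos), "monomorphic")
  expect_equal(nrow(res), 0)
})

test_that("Spearman rho is invariant to monotone transforms of the signal", {
  res <- recovery_result()
  pb <- res$pseudobulk$snRNA
  fpos <- feature_positions(res$bundle)
  fpos <- fpos[fpos$feature_id %in% res$bundle$genes$gene_id, ]
  g <- res$bundle$genotypes[1:2, ]
  r1 <- qtl_scan(g, pb, fpos)
  pb2 <- pb
  pb2$cpm <- log1p(pb$cpm) * 3 + 1  # strictly monotone transform
  r2 <- qtl_scan(g, pb2, fpos)
  expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
})

test_that("Bonferroni multiplier counts tests per (lineage, modality) and caps at 1", {
  res <- recovery_result()
  q <- res$qtl
  grp <- paste(q$lineage, q$modality)
  for (g in unique(grp)) {
    sel <- grp == g
    expect_equal(q$p_bonf[sel], pmin(1, q$p[sel] * sum(sel)), tolerance = 1e-12)
  }
  expect_true(all(q$p_bonf >= q$p - 1e-15))
  expect_true(all(q$p_bonf <= 1))
  expect_true(all(q$rho >= -1 & q$rho <= 1))
})

test_that("planted QTL pairs outrank permuted-dosage null scans", {
  res <- recovery_result()
  truth_key <- paste(res$truth$qtls$snv_id, res$truth$qtls$feature_id)
  q <- res$qtl
  key <- paste(q$snv_id, q$feature_id)
  planted_best <- tapply(abs(q$rho[key %in% truth_key]),
                         key[key %in% truth_key], max)
  null_rho <- abs(q$rho[!key %in% truth_key])
  expect_true(all(planted_best > quantile(null_rho, 0.95)))

  ## permutation calibration: shuffling dosages across donors destroys signal
  g <- res$bundle$genotypes
  donor_cols <- res$bundle$samples$donor_id
  set.seed(31)
  g[, donor_cols] <- g[, sample(donor_cols)]
  qperm <- suppressMessages(qtl_scan(g, res$pseudobulk$snRNA,
                                     feature_positions(res$bundle)))
  frac <- mean(qperm$p < 0.05)
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(qperm)) + 0.03)
})

test_that("QTL/differential locus overlap reports intersections", {
  fpos <- data.frame(feature_id = c("fA", "fB"), chrom = "chr1",
                     pos = c(1000, 900000))
  genotypes <- data.frame(snv_id = c("rs1", "rs2"), chrom = "chr1",
                          pos = c(2000, 500000))
  qtl <- data.frame(snv_id = "rs1", feature_id = "fA", p_bonf = 0.001)
  diff <- data.frame(feature_id = "fA", significant = TRUE)
  ov <- overlap_with_differential(qtl, diff, fpos, genotypes, window = 1e5)
  expect_true(ov$overlap[ov$snv_id == "rs1"])
  expect_equal(ov$n_both[ov$snv_id == "rs1"], 1)
  expect_false(ov$overlap[ov$snv_id == "rs2"])
  # no differential features near any SNV -> empty overlap
  diff0 <- data.frame(feature_id = character(0), significant = logical(0))
  ov0 <- overlap_with_differential(qtl, diff0, fpos, genotypes)
  expect_true(all(!ov0$overlap))
})
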