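test_that("same config and seed reproduce the identical cohort", {
  cfg <- sim_config(seed = 21, n_pairs = 3, n_genes = 30, n_peaks = 40,
                    cells_per_sample = 20, n_snvs = 3)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$bundle$layers$snRNA$counts, s2$bundle$layers$snRNA$counts)
  expect_identical(s1$bundle$layers$snATAC$counts, s2$bundle$layers$snATAC$counts)
  expect_identical(s1$bundle$samples, s2$bundle$samples)
  expect_identical(s1$bundle$genotypes, s2$bundle$genotypes)
  expect_identical(s1$truth, s2$truth)
  # a different seed gives a different cohort
  s3 <- simulate_cohort(sim_config(seed = 22, n_pairs = 3, n_genes = 30,
                                   n_peaks = 40, cells_per_sample = 20,
                                   n_snvs = 3))
  expect_false(identical(s1$bundle$layers$snRNA$counts,
                         s3$bundle$layers$snRNA$counts))
})

test_that("null simulation carries an empty truth", {
  sim <- simulate_null(sim_config(seed = 31, n_pairs = 2, n_genes = 20,
                                  n_peaks = 20, cells_per_sample = 10))
  expect_equal(nrow(sim$truth$de), 0)
  expect_equal(nrow(sim$truth$links), 0)
  expect_equal(nrow(sim$truth$qtls), 0)
})

test_that("configs referencing nonexistent features fail before simulation", {
  de <- data.frame(feature_id = "g9999", lineage = "Monocyte",
                   timepoint = "T1", lfc = 1, endotype = NA_character_)
  expect_error(sim_config(seed = 1, n_genes = 10, de_effects = de),
               "nonexistent feature")
  lk <- data.frame(peak_id = "pk9999", gene_id = "g0001", coef = 1)
  expect_error(sim_config(seed = 1, n_genes = 10, n_peaks = 10, links = lk),
               "nonexistent feature")
  expect_error(sim_config(seed = 1), NA)
})

test_that("structural invariants of the simulated bundle hold", {
  sim <- tiny_cohort()
  b <- sim$bundle
  expect_silent(validate_bundle(b))
  # genotype dosages in 0..2 and polymorphic
  donor_cols <- b$samples$donor_id
  for (s in seq_len(nrow(b$genotypes))) {
    d <- unlist(b$genotypes[s, donor_cols])
    expect_true(all(d %in% 0:2))
    expect_gte(length(unique(d)), 2)
  }
  # multiome layers share nuclei barcodes; scRNA does not
  expect_identical(rownames(b$layers$snRNA$counts),
                   rownames(b$layers$snATAC$counts))
  expect_length(intersect(rownames(b$layers$snRNA$counts),
                          rownames(b$layers$scRNA$counts)), 0)
  # each case endotype recorded in truth
  expect_setequal(sim$truth$endotypes$donor_id,
                  b$samples$donor_id[b$samples$status == "case"])
})

test_that("mean reads per cell match the configured depth", {
  cfg <- sim_config(seed = 55, n_pairs = 3, n_genes = 50, n_peaks = 50,
                    cells_per_sample = 80, rna_depth = 150, atac_depth = 300)
  sim <- simulate_null(cfg)
  for (spec in list(c("snRNA", 150), c("scRNA", 150), c("snATAC", 300))) {
    depth <- as.numeric(spec[2])
    per_cell <- Matrix::rowSums(sim$bundle$layers[[spec[1]]]$counts)
    se <- sd(per_cell) / sqrt(length(per_cell))
    expect_lt(abs(mean(per_cell) - depth), 3 * se + 1e-9)
  }
})

test_that("a planted two-fold monocyte-T1 effect shifts the proportion ratio to ~2", {
  ## Monte-Carlo oracle: the planted multiplier 2 acts on the feature's mean,
  ## so the case/control proportion ratio converges to 2/(1+r) where r is the
  ## feature's baseline share; with small r the ratio is just under 2.
  ratios <- sapply(1:12, function(i) {
    de <- data.frame(feature_id = "g0050", lineage = "Monocyte",
                     timepoint = "T1", lfc = 1, endotype = NA_character_)
    cfg <- sim_config(seed = 600 + i, n_pairs = 4, n_genes = 100, n_peaks = 20,
                      cells_per_sample = 60, rna_depth = 400, de_effects = de)
    sim <- simulate_cohort(cfg)
    pb <- suppressMessages(normalize_per_million(
      make_pseudobulk(sim$bundle$layers$snRNA, sim$bundle$cells)))
    res <- run_differential(pb, sim$bundle$samples)
    res$effect[res$feature_id == "g0050" & res$lineage == "Monocyte" &
                 res$timepoint == "T1"]
  })
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 2), 3 * se + 0.1)
  expect_gt(mean(ratios), 1.5)
})

test_that("null cohorts produce roughly nominal nominal-p fractions", {
  sim <- simulate_null(sim_config(seed = 77, n_pairs = 5, n_genes = 100,
                                  n_peaks = 50, cells_per_sample = 50))
  pb <- suppressMessages(normalize_per_million(
    make_pseudobulk(sim$bundle$layers$snRNA, sim$bundle$cells)))
  res <- run_differential(pb, sim$bundle$samples)
  # discrete exact test is conservative; the p<0.05 fraction must not exceed
  # nominal by more than Monte-Carlo noise
  frac <- mean(res$p < 0.05)
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(res)) + 0.01)
})
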