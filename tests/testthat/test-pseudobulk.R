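make_toy_layer <- function(counts, ids, feats, modality = "snRNA") {
  dimnames(counts) <- list(ids, feats)
  count_layer(modality, counts)
}

toy_cells <- function(ids, donor = "d1", tp = "T1", sub = "B naive",
                      layer = "snRNA") {
  data.frame(cell_id = ids, donor_id = donor, timepoint = tp,
             sublineage = sub, layer = layer, stringsAsFactors = FALSE)
}

test_that("pseudobulk totals are per-feature sums over cells in a key", {
  m <- rbind(c(1, 2), c(0, 3))
  lay <- make_toy_layer(m, c("c1", "c2"), c("fA", "fB"))
  pb <- make_pseudobulk(lay, toy_cells(c("c1", "c2")))
  expect_equal(unname(pb$counts[, 1]), c(1, 5))  # additivity, not (3, 5)
  expect_equal(nrow(pb$keys), 1L)
  expect_equal(pb$keys$lineage, "B")

  # single cell in a key: pseudobulk equals that cell's counts
  lay1 <- make_toy_layer(matrix(c(4, 7), 1), "c9", c("fA", "fB"))
  pb1 <- make_pseudobulk(lay1, toy_cells("c9"))
  expect_equal(unname(pb1$counts[, 1]), c(4, 7))
})

test_that("cell order does not change the pseudobulk table", {
  set.seed(1)
  m <- matrix(rpois(50, 3), 10, 5,
              dimnames = list(sprintf("c%d", 1:10), sprintf("f%d", 1:5)))
  cells <- toy_cells(sprintf("c%d", 1:10),
                     donor = rep(c("d1", "d2"), 5),
                     sub = rep(c("B naive", "NK"), each = 5))
  pb1 <- make_pseudobulk(count_layer("snRNA", m), cells)
  perm <- sample(10)
  pb2 <- make_pseudobulk(count_layer("snRNA", m[perm, ]), cells)
  expect_equal(pb1$counts[, sort(colnames(pb1$counts))],
               pb2$counts[, sort(colnames(pb2$counts))])
})

test_that("reads are conserved through collapse and aggregation", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:30, 1); f <- sample(3:12, 1)
    m <- matrix(rpois(n * f, 2), n, f,
                dimnames = list(sprintf("c%d", 1:n), sprintf("g%d", 1:f)))
    subs <- sample(names(default_lineage_map()), n, replace = TRUE)
    cells <- data.frame(cell_id = rownames(m),
                        donor_id = sample(c("d1", "d2"), n, TRUE),
                        timepoint = sample(c("T1", "T2"), n, TRUE),
                        sublineage = subs, layer = "snRNA",
                        stringsAsFactors = FALSE)
    pb <- make_pseudobulk(count_layer("snRNA", m), cells)
    expect_equal(sum(pb$counts), sum(m))
  }
})

test_that("missing or duplicate annotations are reported by cell id", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("c1", "c2"), c("f1", "f2")))
  lay <- count_layer("snRNA", m)
  expect_error(make_pseudobulk(lay, toy_cells("c1")), "c2")
  dup <- rbind(toy_cells(c("c1", "c2")), toy_cells("c1"))
  expect_error(make_pseudobulk(lay, dup), "duplicate")
})

test_that("count layers reject negative or fractional values", {
  expect_error(count_layer("snRNA",
                           matrix(c(-1, 1, 0, 2), 2,
                                  dimnames = list(c("a", "b"), c("x", "y")))),
               "non-negative")
  expect_error(count_layer("snRNA",
                           matrix(c(0.5, 1, 0, 2), 2,
                                  dimnames = list(c("a", "b"), c("x", "y")))),
               "integer")
})

test_that("per-million normalization is proportional and sums to 1e6", {
  pb <- toy_pseudobulk()
  pb$counts <- matrix(c(2, 2, 1, 3, 0, 0), nrow = 2,
                      dimnames = list(c("f1", "f2"),
                                      c("k1", "k2", "k3")))
  pb$keys <- data.frame(key = c("k1", "k2", "k3"), donor_id = "d1",
                        timepoint = "T1", lineage = c("B", "NK", "CD4T"),
                        n_cells = 1L)
  expect_message(pbn <- normalize_per_million(pb), "zero-total")
  expect_equal(unname(pbn$cpm[, "k1"]), c(5e5, 5e5))
  expect_equal(unname(pbn$cpm[, "k2"]), c(2.5e5, 7.5e5))
  expect_equal(pbn$zero_keys, "k3")
  expect_true(all(is.na(pbn$cpm[, "k3"])))

  # scale invariance
  pb10 <- pb; pb10$counts <- pb$counts * 10
  pbn10 <- suppressMessages(normalize_per_million(pb10))
  expect_equal(pbn10$cpm[, 1:2], pbn$cpm[, 1:2])
})

test_that("normalized signals sum to one million per key on simulated data", {
  sim <- tiny_cohort()
  pb <- suppressMessages(normalize_per_million(
    make_pseudobulk(sim$bundle$layers$snRNA, sim$bundle$cells)))
  sums <- colSums(pb$cpm)
  ok <- !colnames(pb$cpm) %in% pb$zero_keys
  expect_true(all(abs(sums[ok] - 1e6) < 1e-6 * 1e6))
})
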