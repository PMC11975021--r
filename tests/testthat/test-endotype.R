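test_that("endotype classification covers all nonempty antibody subsets", {
  expect_equal(classify_endotype("IAA"), "IAA_first_strict")
  expect_equal(classify_endotype(c("IAA", "IA2A")), "IAA_first_loose")
  expect_equal(classify_endotype("GADA"), "GADA_first_strict")
  expect_equal(classify_endotype(c("GADA", "ZnT8A", "IA2A")), "GADA_first_loose")
  expect_equal(classify_endotype(c("IAA", "GADA")), "other")
  expect_equal(classify_endotype(c("IA2A", "ZnT8A")), "other")

  # exhaustive: all 15 nonempty subsets classify without error and
  # the categories are mutually exclusive by construction
  abs4 <- c("IAA", "GADA", "IA2A", "ZnT8A")
  subsets <- unlist(lapply(1:4, function(k) {
    combn(abs4, k, simplify = FALSE)
  }), recursive = FALSE)
  labels <- classify_endotype(subsets)
  expect_length(labels, 15)
  expect_true(all(labels %in% c("IAA_first_strict", "IAA_first_loose",
                                "GADA_first_strict", "GADA_first_loose",
                                "other")))
  expect_equal(sum(labels == "IAA_first_strict"), 1)
  expect_equal(sum(labels == "GADA_first_strict"), 1)
  # loose IAA: subsets with IAA, no GADA, size > 1 -> 3 of them
  expect_equal(sum(labels == "IAA_first_loose"), 3)
  expect_equal(sum(labels == "GADA_first_loose"), 3)

  expect_error(classify_endotype(character(0)), "empty")
  expect_error(classify_endotype("XYZ"), "unknown")
})

test_that("endotype counting supports exclusive and cumulative conventions", {
  labels <- c(rep("IAA_first_strict", 21), rep("IAA_first_loose", 17),
              rep("GADA_first_strict", 8), rep("GADA_first_loose", 3))
  excl <- endotype_counts(labels)
  expect_equal(excl$n[excl$endotype == "IAA_first_strict"], 21)
  expect_equal(excl$n[excl$endotype == "IAA_first_loose"], 17)
  cum <- endotype_counts(labels, cumulative = TRUE)
  expect_equal(cum$n[cum$endotype == "IAA_first_loose"], 38)
  expect_equal(cum$pct[cum$endotype == "IAA_first_loose"], 77.6)
  expect_equal(cum$n[cum$endotype == "GADA_first_loose"], 11)
  expect_equal(cum$pct[cum$endotype == "GADA_first_loose"], 22.4)
})

test_that("endotype donor resolution subsumes strict into loose groups", {
  samples <- data.frame(
    donor_id = c("c1", "c2", "c3", "k1", "k2", "k3"),
    status = rep(c("case", "control"), each = 3),
    pair_id = rep(c("p1", "p2", "p3"), 2),
    endotype = c("GADA_first_strict", "GADA_first_loose", "IAA_first_strict",
                 "none", "none", "none"))
  expect_setequal(endotype_donors(samples, "GADA_first_loose"), c("c1", "c2"))
  expect_setequal(endotype_donors(samples, "GADA_first_loose",
                                  cumulative = FALSE), "c2")
  expect_setequal(endotype_donors(samples, "IAA_first_strict"), "c3")
})

test_that("subgroup of all cases reproduces the full differential analysis", {
  sim <- tiny_cohort()
  pb <- suppressMessages(pseudobulk_all(sim$bundle))$snRNA
  samples <- sim$bundle$samples
  samples$endotype[samples$status == "case"] <- "GADA_first_strict"
  full <- run_differential(pb, samples)
  sub <- endotype_differential(pb, samples, "GADA_first_strict")
  expect_equal(sub, full)
  expect_error(endotype_differential(pb, samples, "IAA_first_strict"),
               "no case donors")
})

test_that("overlap fractions respect direction and handle edge cases", {
  overall <- data.frame(
    feature_id = c("g1", "g2", "g3"), lineage = "Monocyte", timepoint = "T1",
    direction = c("up_in_cases", "up_in_cases", "up_in_controls"))
  # subgroup superset (same direction) -> fraction 1
  ov1 <- overlap_with_overall(overall, overall)
  expect_true(all(ov1$fraction == 1))
  # disjoint -> 0
  sub <- transform(overall, feature_id = c("h1", "h2", "h3"))
  ov0 <- overlap_with_overall(sub, overall)
  expect_true(all(ov0$fraction == 0))
  # direction mismatch does not count
  flip <- transform(overall, direction = ifelse(direction == "up_in_cases",
                                                "up_in_controls",
                                                "up_in_cases"))
  ovf <- overlap_with_overall(flip, overall)
  expect_equal(sum(ovf$n_shared), 0)
})

test_that("GADA-restricted planted effects surface in the GADA subgroup analysis", {
  cfg <- endotype_design_config(seed = 83)
  sim <- simulate_cohort(cfg)
  pbs <- suppressMessages(pseudobulk_all(sim$bundle))
  samples <- sim$bundle$samples
  gada_genes <- sim$truth$de$feature_id[!is.na(sim$truth$de$endotype)]
  shared_genes <- setdiff(sim$truth$de$feature_id[
    grepl("^g", sim$truth$de$feature_id)], gada_genes)
  full <- run_differential(pbs$snRNA, samples)
  gada <- endotype_differential(pbs$snRNA, samples, "GADA_first_loose")
  pick <- function(tab, genes) {
    sel <- tab$feature_id %in% genes & tab$lineage == "Monocyte" &
      tab$timepoint == "T1"
    tab[sel, ]
  }
  # GADA-specific effects: stronger effect estimate in the subgroup than
  # diluted across all cases
  expect_gt(mean(pick(gada, gada_genes)$effect),
            mean(pick(full, gada_genes)$effect))
  # shared effects appear in both analyses
  expect_gt(mean(pick(full, shared_genes)$significant), 0.7)
})
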