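#' Simulation configuration for synthetic multi-layer cohorts
#'
#' Describes a matched case-control cohort profiled at three time points in
#' three data layers: a nuclei-derived multiome pair (snRNA + snATAC sharing
#' nuclei) and an independent scRNA capture drawn from the same donor-level
#' means. Per-cell counts follow a gamma-Poisson (negative binomial) model;
#' at `overdispersion = 0` the counts are Poisson, where the pooled-read
#' Fisher observed/expected test is approximately calibrated.
#'
#' Planted structure, all optional:
#' * `de_effects`: rows `(feature_id, lineage, timepoint, lfc, endotype)`.
#'   Case donors' mean for that feature is multiplied by `2^lfc` in the given
#'   stratum; gene effects act on both RNA layers, peak effects on snATAC.
#'   A non-`NA` `endotype` (e.g. `"GADA_first"`) restricts the effect to case
#'   donors of that endotype (prefix match covers strict + loose).
#' * `links`: rows `(peak_id, gene_id, coef)`. A lognormal latent activity
#'   per (donor, timepoint) multiplies both members' means (raised to
#'   `coef`), inducing positive cross-modality correlation.
#' * `qtls`: rows `(snv_id, feature_id, beta)`. The feature's mean is
#'   multiplied by `(1 + beta)^dosage` per donor.
#'
#' Features carrying planted effects have their baseline relative abundance
#' floored at the feature mean before renormalization, reflecting that
#' plausible regulatory effects sit on moderately expressed features.
#'
#' @param seed Mandatory integer seed; the cohort is a pure function of
#'   (config, seed).
#' @param n_pairs Matched case/control pairs (default 10).
#' @param n_genes,n_peaks Feature counts (defaults 200 and 300).
#' @param cells_per_sample Cells (or nuclei) per donor, timepoint and layer
#'   (default 100).
#' @param lineage_props Named proportions over the five parent lineages.
#' @param rna_depth,atac_depth Mean reads per cell (defaults 200 and 400).
#' @param overdispersion Gamma-Poisson overdispersion `phi` (variance
#'   `mu + phi mu^2`); 0 gives Poisson counts.
#' @param baseline_shape Gamma shape for baseline feature abundances.
#' @param n_chroms,chrom_len Genome layout (defaults: 4 chromosomes, 25 Mb).
#' @param de_effects,links,qtls Planted-effect tables (see Details).
#' @param link_sdlog Lognormal sd of the shared link activity (default 0.5).
#' @param n_snvs Index SNVs in the genotype table (default 8).
#' @param maf Alt allele frequency for simulated dosages (default 0.4).
#' @param endotype_fracs Named fractions of cases per endotype label.
#' @param n_motifs,motif_bg_rate,motif_up_rate Motif-hit annotation: number
#'   of motifs, background occurrence rate, and occurrence rate of the first
#'   motif in planted case-up peaks.
#' @return An object of class `sim_config`.
#' @seealso [simulate_cohort()], [null_config()], [recovery_config()]
#' @export
sim_config <- function(seed,
                       n_pairs = 10, n_genes = 200, n_peaks = 300,
                       cells_per_sample = 100,
                       lineage_props = c(Monocyte = 0.25, B = 0.20,
                                         CD4T = 0.25, CD8T = 0.15, NK = 0.15),
                       rna_depth = 200, atac_depth = 400,
                       overdispersion = 0, baseline_shape = 2,
                       n_chroms = 4, chrom_len = 25e6,
                       de_effects = empty_de(), links = empty_links(),
                       qtls = empty_qtls(), link_sdlog = 0.5,
                       n_snvs = 8, maf = 0.4,
                       endotype_fracs = c(IAA_first_strict = 0.4,
                                          IAA_first_loose = 0.2,
                                          GADA_first_strict = 0.1,
                                          GADA_first_loose = 0.2,
                                          other = 0.1),
                       n_motifs = 10, motif_bg_rate = 0.10,
                       motif_up_rate = 0.50) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(setequal(names(lineage_props), parent_lineages()),
            abs(sum(lineage_props) - 1) < 1e-8,
            overdispersion >= 0, n_pairs >= 2)
  if (abs(sum(endotype_fracs) - 1) > 1e-8) {
    stop("endotype fractions must sum to 1")
  }
  cfg <- list(seed = as.integer(seed), n_pairs = n_pairs, n_genes = n_genes,
              n_peaks = n_peaks, cells_per_sample = cells_per_sample,
              lineage_props = lineage_props[parent_lineages()],
              rna_depth = rna_depth, atac_depth = atac_depth,
              overdispersion = overdispersion, baseline_shape = baseline_shape,
              n_chroms = n_chroms, chrom_len = chrom_len,
              de_effects = de_effects, links = links, qtls = qtls,
              link_sdlog = link_sdlog, n_snvs = n_snvs, maf = maf,
              endotype_fracs = endotype_fracs, n_motifs = n_motifs,
              motif_bg_rate = motif_bg_rate, motif_up_rate = motif_up_rate)
  class(cfg) <- "sim_config"
  .validate_planted(cfg)
  cfg
}

#' @rdname sim_config
#' @export
empty_de <- function() {
  data.frame(feature_id = character(0), lineage = character(0),
             timepoint = character(0), lfc = numeric(0),
             endotype = character(0), stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
empty_links <- function() {
  data.frame(peak_id = character(0), gene_id = character(0),
             coef = numeric(0), stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
empty_qtls <- function() {
  data.frame(snv_id = character(0), feature_id = character(0),
             beta = numeric(0), stringsAsFactors = FALSE)
}

.gene_ids <- function(n) sprintf("g%04d", seq_len(n))
.peak_ids <- function(n) sprintf("pk%04d", seq_len(n))
.snv_ids <- function(n) sprintf("rs%03d", seq_len(n))

.validate_planted <- function(cfg) {
  genes <- .gene_ids(cfg$n_genes); peaks <- .peak_ids(cfg$n_peaks)
  feats <- c(genes, peaks)
  for (tab in list(cfg$de_effects["feature_id"], cfg$qtls["feature_id"])) {
    bad <- setdiff(tab$feature_id, feats)
    if (length(bad)) stop("planted effect references nonexistent feature(s): ",
                          paste(bad, collapse = ", "))
  }
  if (nrow(cfg$links)) {
    bad <- c(setdiff(cfg$links$gene_id, genes), setdiff(cfg$links$peak_id, peaks))
    if (length(bad)) stop("planted link references nonexistent feature(s): ",
                          paste(bad, collapse = ", "))
  }
  if (nrow(cfg$qtls)) {
    bad <- setdiff(cfg$qtls$snv_id, .snv_ids(cfg$n_snvs))
    if (length(bad)) stop("planted QTL references nonexistent SNV(s): ",
                          paste(bad, collapse = ", "))
  }
  invisible(cfg)
}

#' Deterministic genome layout for a simulation config
#'
#' Genes and peaks are laid out evenly along `n_chroms` chromosomes; the
#' layout is a pure function of the config (no randomness), so planted links
#' can be chosen against it before simulation.
#'
#' @param config A `sim_config`.
#' @return List with `genes` (gene_id, chrom, tss, strand) and `peaks`
#'   (peak_id, chrom, start, end), both sorted by (chrom, position).
#' @export
sim_genome <- function(config) {
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  per_g <- ceiling(config$n_genes / config$n_chroms)
  g_chrom <- rep(chroms, each = per_g)[seq_len(config$n_genes)]
  g_rank <- unlist(lapply(table(factor(g_chrom, chroms)), seq_len))
  spacing_g <- config$chrom_len / (per_g + 1)
  genes <- data.frame(gene_id = .gene_ids(config$n_genes), chrom = g_chrom,
                      tss = round(g_rank * spacing_g),
                      strand = rep_len(c("+", "-"), config$n_genes),
                      stringsAsFactors = FALSE)
  per_p <- ceiling(config$n_peaks / config$n_chroms)
  p_chrom <- rep(chroms, each = per_p)[seq_len(config$n_peaks)]
  p_rank <- unlist(lapply(table(factor(p_chrom, chroms)), seq_len))
  spacing_p <- config$chrom_len / (per_p + 1)
  start <- round(p_rank * spacing_p + spacing_p / 3)
  peaks <- data.frame(peak_id = .peak_ids(config$n_peaks), chrom = p_chrom,
                      start = start, end = start + 400L,
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$tss), ]
  peaks <- peaks[order(peaks$chrom, peaks$start), ]
  rownames(genes) <- rownames(peaks) <- NULL
  list(genes = genes, peaks = peaks)
}

## sub-lineage label pools used when annotating simulated cells
.sublineage_pool <- function() {
  list(Monocyte = c("CD14 Mono", "CD16 Mono", "cDC", "pDC"),
       B = c("B naive", "B memory", "Plasmablast"),
       CD4T = c("CD4 Naive", "CD4 TCM", "Treg"),
       CD8T = c("CD8 Naive", "CD8 TEM", "MAIT"),
       NK = c("NK CD56dim", "NK CD56bright", "NKT"))
}

#' Simulate a synthetic multi-layer longitudinal cohort
#'
#' Generates the three count layers (snRNA, scRNA, snATAC), cell
#' annotations, sample metadata with endotypes, peak/gene tables, a genotype
#' dosage table and a motif-hit annotation, together with the ground truth
#' of every planted effect. The same (config, seed) always reproduces the
#' identical cohort.
#'
#' @param config A [sim_config()].
#' @return List with `bundle` (class `cohort_bundle`: `layers`, `cells`,
#'   `samples`, `peaks`, `genes`, `genotypes`, `motif_hits`) and `truth`
#'   (class `sim_truth`: `de`, `links`, `qtls`, `endotypes`,
#'   `planted_motif`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .validate_planted(config)
  withr::with_seed(config$seed, .simulate_impl(config))
}

#' Simulate a null cohort (no planted effects)
#'
#' As [simulate_cohort()] with every planted-effect table emptied; the truth
#' object contains zero planted records. Used by calibration analyses.
#'
#' @param config A [sim_config()]; its effect tables are ignored.
#' @return As [simulate_cohort()].
#' @export
simulate_null <- function(config) {
  config$de_effects <- empty_de()
  config$links <- empty_links()
  config$qtls <- empty_qtls()
  simulate_cohort(config)
}

.simulate_impl <- function(cfg) {
  genome <- sim_genome(cfg)
  gene_ids <- .gene_ids(cfg$n_genes)
  peak_ids <- .peak_ids(cfg$n_peaks)
  tps <- c("T1", "T2", "T3")
  lins <- parent_lineages()

  ## donors and endotypes
  case_ids <- sprintf("case%02d", seq_len(cfg$n_pairs))
  ctrl_ids <- sprintf("ctrl%02d", seq_len(cfg$n_pairs))
  pair_ids <- sprintf("p%02d", seq_len(cfg$n_pairs))
  endo_levels <- names(cfg$endotype_fracs)
  n_per <- floor(cfg$endotype_fracs * cfg$n_pairs)
  while (sum(n_per) < cfg$n_pairs) {
    i <- which.max(cfg$endotype_fracs * cfg$n_pairs - n_per)
    n_per[i] <- n_per[i] + 1
  }
  endo <- sample(rep(endo_levels, n_per))
  samples <- data.frame(
    donor_id = c(case_ids, ctrl_ids),
    status = rep(c("case", "control"), each = cfg$n_pairs),
    pair_id = rep(pair_ids, 2),
    endotype = c(endo, rep("none", cfg$n_pairs)),
    stringsAsFactors = FALSE)
  donors <- samples$donor_id

  ## genotype dosages for index SNVs (kept polymorphic)
  snvs <- .snv_ids(cfg$n_snvs)
  dosage <- matrix(NA_integer_, cfg$n_snvs, length(donors),
                   dimnames = list(snvs, donors))
  for (s in seq_len(cfg$n_snvs)) {
    for (try in 1:100) {
      d <- stats::rbinom(length(donors), 2, cfg$maf)
      if (length(unique(d)) >= 2) break
    }
    dosage[s, ] <- d
  }
  ## SNV positions: planted QTL SNVs sit 50 kb from their target feature
  fpos <- rbind(
    data.frame(feature_id = genome$genes$gene_id, chrom = genome$genes$chrom,
               pos = genome$genes$tss, stringsAsFactors = FALSE),
    data.frame(feature_id = genome$peaks$peak_id, chrom = genome$peaks$chrom,
               pos = floor((genome$peaks$start + genome$peaks$end) / 2),
               stringsAsFactors = FALSE))
  snv_chrom <- rep(sprintf("chr%d", seq_len(cfg$n_chroms)),
                   length.out = cfg$n_snvs)
  snv_pos <- round(seq(2e6, cfg$chrom_len - 2e6,
                       length.out = max(cfg$n_snvs, 2)))[seq_len(cfg$n_snvs)]
  genotypes <- data.frame(snv_id = snvs, chrom = snv_chrom, pos = snv_pos,
                          stringsAsFactors = FALSE)
  if (nrow(cfg$qtls)) {
    hit <- match(cfg$qtls$snv_id, genotypes$snv_id)
    tgt <- match(cfg$qtls$feature_id, fpos$feature_id)
    genotypes$chrom[hit] <- fpos$chrom[tgt]
    genotypes$pos[hit] <- fpos$pos[tgt] + 5e4
  }
  for (d in donors) genotypes[[d]] <- dosage[, d]

  ## baseline relative abundances; planted features floored at the mean
  planted_genes <- unique(c(
    cfg$de_effects$feature_id[grepl("^g", cfg$de_effects$feature_id)],
    cfg$links$gene_id,
    cfg$qtls$feature_id[grepl("^g", cfg$qtls$feature_id)]))
  planted_peaks <- unique(c(
    cfg$de_effects$feature_id[grepl("^pk", cfg$de_effects$feature_id)],
    cfg$links$peak_id,
    cfg$qtls$feature_id[grepl("^pk", cfg$qtls$feature_id)]))
  relab <- function(n, ids, planted) {
    w <- stats::rgamma(n, shape = cfg$baseline_shape)
    names(w) <- ids
    w[planted] <- pmax(w[planted], mean(w))
    w / sum(w)
  }
  relab_g <- relab(cfg$n_genes, gene_ids, planted_genes)
  relab_p <- relab(cfg$n_peaks, peak_ids, planted_peaks)

  ## shared link activity per (link, donor, timepoint)
  nl <- nrow(cfg$links)
  zlink <- if (nl > 0) {
    array(exp(stats::rnorm(nl * length(donors) * 3, 0, cfg$link_sdlog) -
                cfg$link_sdlog^2 / 2),
          dim = c(nl, length(donors), 3),
          dimnames = list(NULL, donors, tps))
  } else NULL

  endo_match <- function(donor_endo, eff_endo) {
    if (is.na(eff_endo)) TRUE else startsWith(donor_endo, eff_endo)
  }
  donor_endo <- stats::setNames(samples$endotype, samples$donor_id)
  donor_status <- stats::setNames(samples$status, samples$donor_id)

  ## donor-level mean multipliers, per modality feature vector
  mean_vec <- function(kind, donor, tp, lin) {
    if (kind == "gene") {
      mu <- relab_g
      ids <- gene_ids
    } else {
      mu <- relab_p
      ids <- peak_ids
    }
    de <- cfg$de_effects
    if (nrow(de)) {
      pref <- if (kind == "gene") "^g" else "^pk"
      sel <- grepl(pref, de$feature_id) & de$lineage == lin & de$timepoint == tp
      if (any(sel) && donor_status[donor] == "case") {
        for (j in which(sel)) {
          if (endo_match(donor_endo[donor], de$endotype[j])) {
            mu[de$feature_id[j]] <- mu[de$feature_id[j]] * 2^de$lfc[j]
          }
        }
      }
    }
    if (nrow(cfg$qtls)) {
      pref <- if (kind == "gene") "^g" else "^pk"
      sel <- grepl(pref, cfg$qtls$feature_id)
      for (j in which(sel)) {
        dd <- dosage[cfg$qtls$snv_id[j], donor]
        mu[cfg$qtls$feature_id[j]] <-
          mu[cfg$qtls$feature_id[j]] * (1 + cfg$qtls$beta[j])^dd
      }
    }
    if (nl > 0) {
      z <- zlink[, donor, tp]
      if (kind == "gene") {
        mu[cfg$links$gene_id] <- mu[cfg$links$gene_id] * z^cfg$links$coef
      } else {
        mu[cfg$links$peak_id] <- mu[cfg$links$peak_id] * z^cfg$links$coef
      }
    }
    stats::setNames(mu, ids)
  }

  rcounts <- function(n, mu) {
    lambda <- rep(mu, each = n)
    x <- if (cfg$overdispersion == 0) {
      stats::rpois(n * length(mu), lambda)
    } else {
      stats::rnbinom(n * length(mu), mu = lambda, size = 1 / cfg$overdispersion)
    }
    matrix(x, nrow = n, ncol = length(mu), dimnames = list(NULL, names(mu)))
  }

  pool <- .sublineage_pool()
  cells_rows <- list(); blocks <- list(snRNA = list(), scRNA = list(),
                                       snATAC = list())
  for (donor in donors) {
    for (tp in tps) {
      ## nuclei (multiome: shared between snRNA and snATAC) and independent
      ## scRNA cells each get their own lineage composition draw
      for (capture in c("nuc", "cell")) {
        n_by_lin <- stats::rmultinom(1, cfg$cells_per_sample,
                                     cfg$lineage_props)[, 1]
        sub <- unlist(lapply(lins, function(L) {
          if (n_by_lin[L] == 0) return(character(0))
          sample(pool[[L]], n_by_lin[L], replace = TRUE)
        }))
        lin_of <- rep(lins, n_by_lin)
        tag <- if (capture == "nuc") "n" else "c"
        ids <- sprintf("%s_%s_%s%04d", donor, tp, tag, seq_along(lin_of))
        layers_here <- if (capture == "nuc") c("snRNA", "snATAC") else "scRNA"
        for (lay in layers_here) {
          cells_rows[[length(cells_rows) + 1L]] <- data.frame(
            cell_id = ids, donor_id = donor, timepoint = tp,
            sublineage = sub, layer = lay, stringsAsFactors = FALSE)
        }
        for (L in lins[n_by_lin > 0]) {
          idx <- lin_of == L
          if (capture == "nuc") {
            mu_g <- mean_vec("gene", donor, tp, L) * cfg$rna_depth
            mu_p <- mean_vec("peak", donor, tp, L) * cfg$atac_depth
            m1 <- rcounts(sum(idx), mu_g); rownames(m1) <- ids[idx]
            m2 <- rcounts(sum(idx), mu_p); rownames(m2) <- ids[idx]
            blocks$snRNA[[length(blocks$snRNA) + 1L]] <- m1
            blocks$snATAC[[length(blocks$snATAC) + 1L]] <- m2
          } else {
            mu_g <- mean_vec("gene", donor, tp, L) * cfg$rna_depth
            m <- rcounts(sum(idx), mu_g); rownames(m) <- ids[idx]
            blocks$scRNA[[length(blocks$scRNA) + 1L]] <- m
          }
        }
      }
    }
  }
  cells <- do.call(rbind, cells_rows)
  layers <- list(
    snRNA = count_layer("snRNA", do.call(rbind, blocks$snRNA)),
    scRNA = count_layer("scRNA", do.call(rbind, blocks$scRNA)),
    snATAC = count_layer("snATAC", do.call(rbind, blocks$snATAC)))

  ## motif-hit annotation: background occurrence everywhere, first motif
  ## enriched in planted case-up peaks
  motifs <- sprintf("M%02d", seq_len(cfg$n_motifs))
  up_peaks <- unique(cfg$de_effects$feature_id[
    grepl("^pk", cfg$de_effects$feature_id) & cfg$de_effects$lfc > 0])
  hit_rows <- list()
  for (m in motifs) {
    rate <- rep(cfg$motif_bg_rate, cfg$n_peaks)
    if (m == motifs[1] && length(up_peaks)) {
      rate[match(up_peaks, peak_ids)] <- cfg$motif_up_rate
    }
    hit <- stats::rbinom(cfg$n_peaks, 1, rate) == 1
    if (any(hit)) {
      hit_rows[[m]] <- data.frame(peak_id = peak_ids[hit], motif_id = m,
                                  n_hits = 1L, stringsAsFactors = FALSE)
    }
  }
  motif_hits <- do.call(rbind, c(hit_rows, list(make.row.names = FALSE)))

  bundle <- structure(list(layers = layers, cells = cells, samples = samples,
                           peaks = genome$peaks, genes = genome$genes,
                           genotypes = genotypes, motif_hits = motif_hits),
                      class = "cohort_bundle")
  truth <- structure(list(
    de = cfg$de_effects, links = cfg$links, qtls = cfg$qtls,
    endotypes = samples[samples$status == "case", c("donor_id", "endotype")],
    planted_motif = if (length(up_peaks)) motifs[1] else NA_character_),
    class = "sim_truth")
  list(bundle = bundle, truth = truth)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> %d donors, layers: %s\n",
              nrow(x$samples), paste(names(x$layers), collapse = ", ")))
  for (l in x$layers) print(l)
  invisible(x)
}

#' Desk-scale null configuration
#'
#' The default calibration conditions: 10 matched pairs, 200 genes, 300
#' peaks, 100 cells per donor/timepoint/layer, Poisson counts
#' (overdispersion 0) and no planted effects.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
null_config <- function(seed, ...) sim_config(seed = seed, ...)

#' Default recovery configuration with planted effects
#'
#' Conditions used for power/recovery analyses: 20 matched pairs (40
#' donors), two-fold (lfc = 1) monocyte-T1 differential genes, up- and
#' down-regulated monocyte-T1 peaks, peak-gene links with shared activity
#' coefficient 1, and dosage QTLs with a 1.5x per-allele effect. Planted
#' feature sets are sampled deterministically from `seed`.
#'
#' @param seed Integer seed.
#' @param n_pairs Matched pairs (default 20).
#' @param n_de_genes Planted two-fold monocyte-T1 genes (default 20).
#' @param n_de_peaks Planted monocyte-T1 peaks, two-thirds up (default 12).
#' @param n_links Planted peak-gene links (default 15).
#' @param n_qtls Planted dosage QTLs on genes (default 6).
#' @param lfc Planted log2 fold change (default 1).
#' @param link_coef Shared-activity coefficient (default 1).
#' @param qtl_beta Per-allele effect (default 0.5).
#' @param contiguous_peaks Plant the up-regulated peaks on consecutive peaks
#'   of one chromosome (exercises adjacency clustering; default FALSE).
#' @param gada_fraction Fraction of planted DE genes restricted to
#'   GADA-first cases (default 0).
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
recovery_config <- function(seed, n_pairs = 20, n_de_genes = 20,
                            n_de_peaks = 12, n_links = 15, n_qtls = 6,
                            lfc = 1, link_coef = 1, qtl_beta = 0.5,
                            contiguous_peaks = FALSE, gada_fraction = 0, ...) {
  base <- sim_config(seed = seed, n_pairs = n_pairs, ...)
  genome <- sim_genome(base)
  withr::with_seed(seed + 1L, {
    de_genes <- sample(.gene_ids(base$n_genes), n_de_genes)
    if (n_de_peaks == 0) {
      up <- down <- character(0)
    } else if (contiguous_peaks) {
      pk_sorted <- genome$peaks$peak_id[genome$peaks$chrom == "chr1"]
      n_up <- ceiling(2 * n_de_peaks / 3)
      start <- sample(length(pk_sorted) - n_up, 1)
      up <- pk_sorted[start:(start + n_up - 1)]
      down <- sample(setdiff(.peak_ids(base$n_peaks), up), n_de_peaks - n_up)
    } else {
      pk <- sample(.peak_ids(base$n_peaks), n_de_peaks)
      up <- pk[seq_len(ceiling(2 * n_de_peaks / 3))]
      down <- setdiff(pk, up)
    }
    plant <- function(ids, l) {
      data.frame(feature_id = ids, lineage = rep("Monocyte", length(ids)),
                 timepoint = rep("T1", length(ids)), lfc = rep(l, length(ids)),
                 endotype = rep(NA_character_, length(ids)),
                 stringsAsFactors = FALSE)
    }
    de <- rbind(plant(de_genes, lfc), plant(up, lfc), plant(down, -lfc))
    if (gada_fraction > 0) {
      n_gada <- round(gada_fraction * n_de_genes)
      de$endotype[seq_len(n_gada)] <- "GADA_first"
    }
    cand <- candidate_pairs(genome$peaks, genome$genes)
    cand <- cand[!(cand$gene_id %in% de_genes) &
                   !(cand$peak_id %in% c(up, down)), , drop = FALSE]
    ## one link per gene and peak keeps planted correlations independent
    cand <- cand[sample(nrow(cand)), ]
    cand <- cand[!duplicated(cand$gene_id) & !duplicated(cand$peak_id), ]
    li <- utils::head(cand, n_links)
    links <- data.frame(peak_id = li$peak_id, gene_id = li$gene_id,
                        coef = rep(link_coef, nrow(li)),
                        stringsAsFactors = FALSE)
    qtl_genes <- sample(setdiff(.gene_ids(base$n_genes),
                                c(de_genes, links$gene_id)), n_qtls)
    qtls <- data.frame(snv_id = .snv_ids(base$n_snvs)[seq_len(n_qtls)],
                       feature_id = qtl_genes,
                       beta = rep(qtl_beta, length(qtl_genes)),
                       stringsAsFactors = FALSE)
  })
  base$de_effects <- de
  base$links <- links
  base$qtls <- qtls
  .validate_planted(base)
  base
}

#' Endotype-design configuration
#'
#' Ten matched pairs with planted monocyte-T1 differential genes, half of
#' which are restricted to GADA-first cases, emulating partial overlap of
#' subgroup and overall case-control signals. The subgroup-restricted
#' effects are planted at a larger fold change (default four-fold) than the
#' cohort-wide ones (two-fold): an endotype-driven signal can only shape the
#' pooled all-case pattern if it remains detectable after dilution across
#' the full case group, which is the regime the partial-overlap design
#' emulates. Endotype fractions mirror the cohort (more IAA-first than
#' GADA-first cases) and guarantee both subgroups are present. No links or
#' QTLs are planted: cross-layer replication proceeds through the scRNA
#' layer and other timepoints.
#'
#' @param seed Integer seed.
#' @param n_de_genes Planted monocyte-T1 genes (default 16; half
#'   GADA-restricted).
#' @param shared_lfc Log2 fold change of cohort-wide effects (default 1).
#' @param endotype_lfc Log2 fold change of GADA-restricted effects
#'   (default 2).
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
endotype_design_config <- function(seed, n_de_genes = 16, shared_lfc = 1,
                                   endotype_lfc = 2, ...) {
  base <- sim_config(seed = seed, n_pairs = 10,
                     endotype_fracs = c(IAA_first_strict = 0.4,
                                        IAA_first_loose = 0.1,
                                        GADA_first_strict = 0.2,
                                        GADA_first_loose = 0.1,
                                        other = 0.2), ...)
  withr::with_seed(seed + 1L, {
    genes <- sample(.gene_ids(base$n_genes), n_de_genes)
  })
  n_gada <- floor(n_de_genes / 2)
  base$de_effects <- data.frame(
    feature_id = genes,
    lineage = rep("Monocyte", n_de_genes),
    timepoint = rep("T1", n_de_genes),
    lfc = c(rep(endotype_lfc, n_gada), rep(shared_lfc, n_de_genes - n_gada)),
    endotype = c(rep("GADA_first", n_gada),
                 rep(NA_character_, n_de_genes - n_gada)),
    stringsAsFactors = FALSE)
  .validate_planted(base)
  base
}
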