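#' Encode diploid genotype strings as alt-allele dosages
#'
#' `0/0`, `0/1` (or `1/0`) and `1/1` become 0, 1 and 2 alt-allele copies;
#' missing genotypes (`./.`) become `NA`. Any other string is an error.
#'
#' @param genotype Character vector of genotype strings.
#' @return Integer vector of dosages with `NA` for missing.
#' @examples
#' encode_dosage(c("0/0", "0/1", "1/1", "./."))
#' @export
encode_dosage <- function(genotype) {
  lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  out <- lut[genotype]
  miss <- genotype %in% c("./.", ".|.", NA)
  out[miss] <- NA_integer_
  bad <- is.na(out) & !miss
  if (any(bad)) {
    stop("unrecognized genotype string(s): ",
         paste(unique(genotype[bad]), collapse = ", "))
  }
  unname(out)
}

#' Genotype-dosage QTL scan over cis features
#'
#' For each index SNV, every feature (gene TSS or peak midpoint) within
#' `window` bp on the same chromosome is tested in every (lineage, timepoint)
#' stratum: Spearman rank correlation (midranks for ties) between donor-level
#' normalized pseudobulk signal and allele dosage, with a two-sided p-value
#' from the t approximation. Bonferroni correction multiplies each p by the
#' number of tests performed within its (lineage, modality) group, capped at
#' one. Monomorphic SNVs (fewer than two distinct observed dosages) are
#' skipped with a message.
#'
#' @param genotypes Data frame with columns `snv_id`, `chrom`, `pos` followed
#'   by one integer dosage column per donor (0/1/2 or `NA`).
#' @param pb Normalized `pseudobulk` for one modality
#'   ([normalize_per_million()]).
#' @param feature_pos Data frame `feature_id`, `chrom`, `pos` locating each
#'   feature (TSS for genes, midpoint for peaks).
#' @param window Cis window in bp around the SNV (default 1e6).
#' @param min_donors Minimum donors with signal and genotype (default 5).
#' @return Data frame `snv_id`, `feature_id`, `modality`, `lineage`,
#'   `timepoint`, `rho`, `p`, `p_bonf`, `n_donors`.
#' @export
qtl_scan <- function(genotypes, pb, feature_pos, window = 1e6, min_donors = 5) {
  stopifnot(inherits(pb, "pseudobulk"))
  if (is.null(pb$cpm)) stop("pseudobulk must be normalized first")
  donor_cols <- setdiff(names(genotypes), c("snv_id", "chrom", "pos"))
  keys <- pb$keys[!(pb$keys$key %in% pb$zero_keys), , drop = FALSE]
  feature_pos <- feature_pos[feature_pos$feature_id %in% rownames(pb$cpm), , drop = FALSE]
  out <- list()
  for (s in seq_len(nrow(genotypes))) {
    dos <- unlist(genotypes[s, donor_cols])
    if (length(unique(dos[!is.na(dos)])) < 2) {
      message("qtl_scan: monomorphic SNV skipped: ", genotypes$snv_id[s])
      next
    }
    near <- feature_pos$feature_id[
      feature_pos$chrom == genotypes$chrom[s] &
        abs(feature_pos$pos - genotypes$pos[s]) <= window]
    if (length(near) == 0) next
    for (lin in unique(keys$lineage)) {
      for (tp in unique(keys$timepoint)) {
        kk <- keys[keys$lineage == lin & keys$timepoint == tp, , drop = FALSE]
        dvals <- dos[kk$donor_id]
        ok <- !is.na(dvals)
        if (sum(ok) < min_donors || length(unique(dvals[ok])) < 2) next
        Y <- t(pb$cpm[near, kk$key[ok], drop = FALSE])
        rx <- rank(dvals[ok])
        RY <- apply(Y, 2, rank)
        n <- sum(ok)
        sy <- apply(RY, 2, stats::sd)
        rho <- rep(NA_real_, length(near))
        good <- sy > 0
        if (any(good)) {
          rho[good] <- as.numeric(stats::cor(rx, RY[, good, drop = FALSE]))
        }
        tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
        p <- 2 * stats::pt(-abs(tt), df = n - 2)
        out[[length(out) + 1L]] <- data.frame(
          snv_id = genotypes$snv_id[s], feature_id = near,
          modality = pb$modality, lineage = lin, timepoint = tp,
          rho = rho, p = p, n_donors = n, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(snv_id = character(0), feature_id = character(0),
                      modality = character(0), lineage = character(0),
                      timepoint = character(0), rho = numeric(0),
                      p = numeric(0), p_bonf = numeric(0),
                      n_donors = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[!is.na(res$rho), , drop = FALSE]
  rownames(res) <- NULL
  ## Bonferroni multiplier: number of tests within (lineage, modality)
  grp <- paste(res$lineage, res$modality)
  n_tests <- table(grp)
  res$p_bonf <- pmin(1, res$p * as.numeric(n_tests[grp]))
  res
}

#' Overlap of QTL loci with case-control differential signals
#'
#' For each SNV locus, reports the differential-significant features within
#' `window` bp of the index variant and whether any QTL-associated feature at
#' the locus (Bonferroni p below `qtl_alpha`) is itself case-control
#' significant.
#'
#' @param qtl QTL table from [qtl_scan()].
#' @param differential Differential table(s) from [run_differential()] (a
#'   data frame or list of them), or a replicated set from
#'   [assess_replication()].
#' @param feature_pos Data frame `feature_id`, `chrom`, `pos`.
#' @param genotypes Genotype table (for SNV positions).
#' @param window Reporting window around the index SNV (default 1e5).
#' @param qtl_alpha Bonferroni-corrected significance for QTL hits
#'   (default 0.05).
#' @return Data frame per SNV: `snv_id`, `n_diff_features`,
#'   `n_qtl_features`, `n_both`, `overlap` (logical).
#' @export
overlap_with_differential <- function(qtl, differential, feature_pos,
                                      genotypes, window = 1e5,
                                      qtl_alpha = 0.05) {
  if (is.list(differential) && !is.data.frame(differential)) {
    differential <- do.call(rbind, lapply(differential, function(x) {
      x[, intersect(names(x), c("feature_id", "lineage", "timepoint",
                                "modality", "q", "significant"))]
    }))
  }
  sig_features <- unique(differential$feature_id[
    if ("significant" %in% names(differential)) differential$significant
    else rep(TRUE, nrow(differential))])
  out <- lapply(seq_len(nrow(genotypes)), function(s) {
    near <- feature_pos$feature_id[
      feature_pos$chrom == genotypes$chrom[s] &
        abs(feature_pos$pos - genotypes$pos[s]) <= window]
    diff_near <- intersect(near, sig_features)
    qtl_here <- unique(qtl$feature_id[qtl$snv_id == genotypes$snv_id[s] &
                                        qtl$p_bonf < qtl_alpha])
    both <- intersect(diff_near, qtl_here)
    data.frame(snv_id = genotypes$snv_id[s],
               n_diff_features = length(diff_near),
               n_qtl_features = length(qtl_here),
               n_both = length(both), overlap = length(both) > 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
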