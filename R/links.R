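#' Candidate peak-gene pairs within a cis window
#'
#' Enumerates every (peak, gene) pair on the same chromosome whose distance
#' from peak midpoint to gene TSS is at most `max_dist` (closed bound, so a
#' distance of exactly 1 Mb is included). Uses interval overlap on
#' TSS-centered windows followed by an exact distance filter.
#'
#' @param peaks Data frame with `peak_id`, `chrom`, `start`, `end`
#'   (0-based half-open), sorted by (chrom, start).
#' @param genes Data frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @param max_dist Maximum midpoint-to-TSS distance in bp (default 1e6).
#' @return Data frame `peak_id`, `gene_id`, `distance`, `bin`
#'   (see [classify_distance()]).
#' @export
candidate_pairs <- function(peaks, genes, max_dist = 1e6) {
  .check_peaks(peaks)
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(genes)))
  mid <- (peaks$start + peaks$end) / 2
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(floor(mid) + 1, floor(mid) + 1))
  win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1, genes$tss - max_dist - 2), genes$tss + max_dist + 2))
  ov <- GenomicRanges::findOverlaps(pk, win, ignore.strand = TRUE)
  pi <- S4Vectors::queryHits(ov); gi <- S4Vectors::subjectHits(ov)
  dist <- abs(mid[pi] - genes$tss[gi])
  keep <- dist <= max_dist
  pi <- pi[keep]; gi <- gi[keep]; dist <- dist[keep]
  ord <- order(pi, gi)
  data.frame(peak_id = peaks$peak_id[pi][ord], gene_id = genes$gene_id[gi][ord],
             distance = dist[ord],
             bin = classify_distance(dist[ord]),
             stringsAsFactors = FALSE)
}

#' Classify a peak-TSS distance into regulatory distance bins
#'
#' Half-open bins partitioning `[0, 1 Mb]` with boundaries assigned upward:
#' promoter `[0, 5 kb)`, proximal enhancer `[5, 20 kb)`, distal enhancer
#' `[20, 500 kb)`, long-range enhancer `[500 kb, 1 Mb]`.
#'
#' @param distance Numeric vector of distances in bp, each in `[0, 1e6]`.
#' @return Character vector of bin labels.
#' @examples
#' classify_distance(c(3000, 5000, 250000, 1e6))
#' @export
classify_distance <- function(distance) {
  if (length(distance) == 0) return(character(0))
  if (anyNA(distance) || any(distance < 0) || any(distance > 1e6)) {
    stop("distance must lie in [0, 1e6] bp")
  }
  c("promoter", "proximal", "distal", "long_range")[
    findInterval(distance, c(0, 5000, 20000, 500000))]
}

## Pearson r and two-sided t-approximation p between matched columns of two
## observation x feature matrices; returns NA for zero-variance columns.
.pairwise_pearson <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y), ncol(X) == ncol(Y))
  n <- nrow(X)
  sx <- apply(X, 2, stats::sd); sy <- apply(Y, 2, stats::sd)
  ok <- sx > 0 & sy > 0
  r <- rep(NA_real_, ncol(X))
  if (any(ok)) {
    Xs <- scale(X[, ok, drop = FALSE]); Ys <- scale(Y[, ok, drop = FALSE])
    r[ok] <- colSums(Xs * Ys) / (n - 1)
  }
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, p = p, n = n)
}

## Align two normalized pseudobulk objects on shared (donor,timepoint,lineage)
## keys and return observation matrices for the requested features.
.matched_cpm <- function(pb_x, pb_y, features_x, features_y) {
  kx <- setdiff(pb_x$keys$key, pb_x$zero_keys)
  ky <- setdiff(pb_y$keys$key, pb_y$zero_keys)
  shared <- intersect(kx, ky)
  list(X = t(pb_x$cpm[features_x, shared, drop = FALSE]),
       Y = t(pb_y$cpm[features_y, shared, drop = FALSE]),
       keys = shared)
}

#' Discover peak-gene links by pseudobulk correlation in the multiome layer
#'
#' For each candidate pair, computes the Pearson correlation between the
#' peak's normalized snATAC signal and the gene's normalized snRNA signal
#' across shared (donor, timepoint, lineage) pseudobulk observations, with a
#' two-sided p-value from the t approximation. Pairs with nominal `p <
#' p_threshold` and `|r| > r_threshold` are flagged as discovered links.
#' Zero-variance pairs are skipped (reported with `NA`).
#'
#' @param pb_atac Normalized snATAC `pseudobulk` (see
#'   [normalize_per_million()]); the multiome chromatin layer.
#' @param pb_rna Normalized snRNA `pseudobulk`; the multiome expression layer.
#' @param pairs Candidate pairs from [candidate_pairs()].
#' @param p_threshold,r_threshold Nominal discovery thresholds
#'   (defaults 0.05 and 0.05).
#' @param min_obs Minimum number of shared pseudobulk observations (default 5).
#' @return `pairs` with `r_discovery`, `p_discovery`, `n_obs` and logical
#'   `discovered` columns added.
#' @export
link_correlation <- function(pb_atac, pb_rna, pairs,
                             p_threshold = 0.05, r_threshold = 0.05,
                             min_obs = 5) {
  stopifnot(inherits(pb_atac, "pseudobulk"), inherits(pb_rna, "pseudobulk"))
  if (is.null(pb_atac$cpm) || is.null(pb_rna$cpm)) {
    stop("pseudobulk objects must be normalized first (normalize_per_million)")
  }
  m <- .matched_cpm(pb_atac, pb_rna, pairs$peak_id, pairs$gene_id)
  if (length(m$keys) < min_obs) {
    stop("fewer than ", min_obs, " shared pseudobulk observations")
  }
  pp <- .pairwise_pearson(m$X, m$Y)
  pairs$r_discovery <- pp$r
  pairs$p_discovery <- pp$p
  pairs$n_obs <- pp$n
  pairs$discovered <- !is.na(pp$r) & pp$p < p_threshold & abs(pp$r) > r_threshold
  n_skip <- sum(is.na(pp$r))
  if (n_skip > 0) {
    message("link_correlation: ", n_skip, " zero-variance pair(s) skipped")
  }
  pairs
}

#' Validate discovered links in the orthogonal unpaired layers
#'
#' Recomputes each link's correlation between the unpaired layers' sample
#' level normalized signals (independent snATAC pseudobulk vs scRNA
#' pseudobulk). A link is `validated` when the validation correlation has the
#' same sign as the discovery correlation and `|r| > 0.65` (strict
#' inequality).
#'
#' @param links Output of [link_correlation()] (typically filtered to
#'   `discovered` links).
#' @param pb_atac,pb_scrna Normalized pseudobulk objects for the unpaired
#'   snATAC and scRNA layers; must share donors with the multiome layer.
#' @param r_threshold Validation correlation magnitude (default 0.65).
#' @return `links` with `r_validation` and logical `validated` added.
#' @export
validate_links <- function(links, pb_atac, pb_scrna, r_threshold = 0.65) {
  if (is.null(pb_atac$cpm) || is.null(pb_scrna$cpm)) {
    stop("pseudobulk objects must be normalized first (normalize_per_million)")
  }
  m <- .matched_cpm(pb_atac, pb_scrna, links$peak_id, links$gene_id)
  pp <- .pairwise_pearson(m$X, m$Y)
  links$r_validation <- pp$r
  links$validated <- !is.na(pp$r) & !is.na(links$r_discovery) &
    sign(pp$r) == sign(links$r_discovery) & abs(pp$r) > r_threshold
  links
}

#' Per-bin link density summary
#'
#' Descriptive links-per-kb table: for each distance bin, the number of
#' discovered links divided by (bin width in kb times the number of genes
#' with at least one candidate peak in that bin).
#'
#' @param links Links table with `bin` and `discovered` columns.
#' @param pairs Full candidate-pair table (defines per-bin gene denominators).
#' @return Data frame with `bin`, `n_links`, `n_genes`, `width_kb`,
#'   `links_per_kb`.
#' @export
link_density <- function(links, pairs = links) {
  bins <- c(promoter = 5, proximal = 15, distal = 480, long_range = 500)
  keep <- if ("discovered" %in% names(links)) links$discovered else TRUE
  links <- links[keep, , drop = FALSE]
  out <- data.frame(bin = names(bins), width_kb = unname(bins),
                    stringsAsFactors = FALSE)
  out$n_links <- vapply(out$bin, function(b) sum(links$bin == b), integer(1))
  out$n_genes <- vapply(out$bin, function(b) {
    length(unique(pairs$gene_id[pairs$bin == b]))
  }, integer(1))
  out$links_per_kb <- ifelse(out$n_genes > 0,
                             out$n_links / (out$width_kb * out$n_genes), 0)
  out[, c("bin", "n_links", "n_genes", "width_kb", "links_per_kb")]
}
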