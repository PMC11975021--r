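#' Count adjacent significant peak pairs
#'
#' "Adjacent" means consecutive ranks in the sorted peak set on the same
#' chromosome (no base-pair gap rule by default). Returns the number of
#' consecutive pairs in which both members belong to the significant set.
#'
#' @param significant Character vector of significant peak ids; must all be
#'   present in `peaks`.
#' @param peaks Peak table (`peak_id`, `chrom`, `start`, `end`), sorted by
#'   (chrom, start).
#' @param max_gap Optional maximum bp gap between consecutive peaks for a
#'   pair to count (`Inf` disables the rule, the default).
#' @return Integer count of adjacent significant pairs.
#' @export
adjacent_pairs <- function(significant, peaks, max_gap = Inf) {
  .check_peaks(peaks)
  missing <- setdiff(significant, peaks$peak_id)
  if (length(missing)) {
    stop("significant peak id(s) absent from the peak set: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  flag <- peaks$peak_id %in% significant
  total <- 0L
  for (ch in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == ch)
    if (length(idx) < 2) next
    f <- flag[idx]
    both <- f[-length(f)] & f[-1]
    if (is.finite(max_gap)) {
      gap <- peaks$start[idx][-1] - peaks$end[idx][-length(idx)]
      both <- both & gap <= max_gap
    }
    total <- total + sum(both)
  }
  as.integer(total)
}

#' Expected number of adjacent significant pairs under random placement
#'
#' With `k` of `N` peaks significant on a chromosome and labels placed
#' uniformly at random, each of the `N - 1` consecutive pairs is doubly
#' significant with probability `k (k-1) / (N (N-1))`, so the expectation is
#' `k (k-1) / N`; chromosomes add. A label-shuffling permutation estimate is
#' returned alongside as an empirical check.
#'
#' @param k Integer vector: significant peaks per chromosome.
#' @param N Integer vector: total peaks per chromosome (`k <= N`).
#' @param n_permutations Number of label shuffles (default 1000; must be
#'   at least 1).
#' @param seed Optional seed for the permutation draw.
#' @return List with `analytic`, `perm_mean`, `perm_se`, and the permutation
#'   counts in `perm_counts`.
#' @export
expected_adjacent <- function(k, N, n_permutations = 1000, seed = NULL) {
  stopifnot(length(k) == length(N), all(k >= 0), all(N >= 1), all(k <= N))
  if (n_permutations < 1) stop("n_permutations must be at least 1")
  analytic <- sum(ifelse(N > 1, k * (k - 1) / N, 0))
  draw <- function() {
    tot <- 0L
    for (i in seq_along(k)) {
      if (N[i] < 2 || k[i] < 2) next
      f <- logical(N[i])
      f[sample.int(N[i], k[i])] <- TRUE
      tot <- tot + sum(f[-N[i]] & f[-1])
    }
    tot
  }
  counts <- if (is.null(seed)) {
    replicate(n_permutations, draw())
  } else {
    withr::with_seed(seed, replicate(n_permutations, draw()))
  }
  list(analytic = analytic, perm_mean = mean(counts),
       perm_se = stats::sd(counts) / sqrt(n_permutations),
       perm_counts = counts)
}

#' Adjacency excess of differential peaks across strata
#'
#' For each (lineage, timepoint) stratum of a snATAC differential table,
#' counts adjacent significant peak pairs and accumulates the analytic
#' chance expectation; stratum counts are summed across time points and
#' lineages, mirroring a genome-wide "observed vs expected by chance"
#' comparison.
#'
#' @param diff_atac snATAC differential table from [run_differential()].
#' @param peaks Sorted peak table.
#' @param q_threshold Significance threshold (default 0.10).
#' @param n_permutations Permutations per stratum for the empirical null
#'   (default 1000).
#' @param seed Seed for the permutation draws.
#' @return List with `observed`, `expected_analytic`, `expected_perm`,
#'   `ratio` (observed / analytic expectation) and a per-stratum data frame
#'   `strata`.
#' @export
adjacency_analysis <- function(diff_atac, peaks, q_threshold = 0.10,
                               n_permutations = 1000, seed = NULL) {
  .check_peaks(peaks)
  strata <- unique(diff_atac[, c("lineage", "timepoint")])
  chroms <- unique(peaks$chrom)
  N <- vapply(chroms, function(ch) sum(peaks$chrom == ch), integer(1))
  obs_tot <- 0L; ana_tot <- 0; perm_tot <- 0
  rows <- list()
  for (i in seq_len(nrow(strata))) {
    sel <- diff_atac$lineage == strata$lineage[i] &
      diff_atac$timepoint == strata$timepoint[i] &
      diff_atac$q < q_threshold
    sig <- unique(diff_atac$feature_id[sel])
    obs <- adjacent_pairs(sig, peaks)
    k <- vapply(chroms, function(ch) {
      sum(peaks$chrom == ch & peaks$peak_id %in% sig)
    }, integer(1))
    ex <- expected_adjacent(k, N, n_permutations = n_permutations,
                            seed = if (is.null(seed)) NULL else seed + i)
    obs_tot <- obs_tot + obs
    ana_tot <- ana_tot + ex$analytic
    perm_tot <- perm_tot + ex$perm_mean
    rows[[i]] <- data.frame(lineage = strata$lineage[i],
                            timepoint = strata$timepoint[i],
                            n_significant = length(sig), observed = obs,
                            expected = ex$analytic, stringsAsFactors = FALSE)
  }
  list(observed = obs_tot, expected_analytic = ana_tot,
       expected_perm = perm_tot,
       ratio = if (ana_tot > 0) obs_tot / ana_tot else NA_real_,
       strata = do.call(rbind, rows))
}
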