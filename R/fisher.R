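#' Fisher observed/expected test on pooled read totals
#'
#' The core case-control statistic: for a feature in one stratum, `a` is the
#' total case reads in the feature ("observed"), `b` the total case reads in
#' all other features ("expected"), and `c`, `d` the control counterparts.
#' The two-sided exact p-value for the 2x2 table `[[a, b], [c, d]]` is
#' computed with the point-probability rule (the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table), the same convention as
#' [stats::fisher.test()]. The effect is the case-over-control proportion
#' ratio `(a/(a+b)) / (c/(c+d))`.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param a,b,c,d Non-negative integer read counts; `a + b > 0` and
#'   `c + d > 0` are required for every table.
#' @return Data frame with columns `effect` and `p`.
#' @examples
#' fisher_obs_exp(10, 990, 10, 990) # identical proportions: effect 1, p 1
#' @export
fisher_obs_exp <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  v <- cbind(a, b, c, d)
  if (anyNA(v) || min(v) < 0 || any(v != round(v))) {
    stop("fisher_obs_exp: counts must be non-negative integers")
  }
  if (any(a + b == 0) || any(c + d == 0)) {
    stop("fisher_obs_exp: a margin is entirely zero (a+b = 0 or c+d = 0)")
  }
  effect <- (a / (a + b)) / (c / (c + d))
  p <- vapply(seq_len(n), function(i) {
    .fisher_two_sided(a[i], b[i], c[i], d[i])
  }, numeric(1))
  data.frame(effect = effect, p = p)
}

## two-sided point-probability p for [[a,b],[c,d]]; relative tolerance on the
## point mass guards against floating-point noise near ties (as fisher.test).
.fisher_two_sided <- function(a, b, c, d) {
  m <- a + c          # feature margin
  nn <- b + d         # all-other-features margin
  k <- a + b          # case margin
  lo <- max(0, k - nn)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, nn, k)
  d0 <- stats::dhyper(a, m, nn, k)
  min(1, sum(dens[dens <= d0 * (1 + 1e-7)]))
}

#' Benjamini-Hochberg q-values
#'
#' Standard BH step-up adjusted p-values via [stats::p.adjust()]. Input
#' p-values must lie in (0, 1]; an empty input yields an empty result.
#'
#' @param p_values Numeric vector of p-values.
#' @return Numeric vector of q-values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0) || any(p_values > 1)) {
    stop("bh_fdr: p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
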