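## The study's statistical primitives: binomial margin of error at the
## printed z, Shannon entropy of a variant spectrum, rank-sum comparison,
## significance stars.

#' Binomial margin of error for a read-derived proportion
#'
#' The asymptotic half-width `epsilon = z * sqrt(p * (1 - p) / n)`. The
#' default multiplier is the constant 2.326348, which the study labels a
#' 99% confidence level; that value is in fact the one-sided 99% (two-sided
#' 98%) normal quantile, and is used verbatim rather than corrected.
#'
#' @param p proportion in `[0, 1]`.
#' @param n number of supporting read pairs (>= 1).
#' @param z quantile multiplier.
#' @return list with `epsilon`, `z`, `p`, `n`.
#' @examples
#' marginOfError(0.5, 1000)$epsilon   # ~0.03678
#' @export
marginOfError <- function(p, n, z = 2.326348) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be >= 1")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  list(epsilon = z * sqrt(p * (1 - p) / n), z = z, p = p, n = as.integer(n))
}

#' Shannon entropy of a category spectrum
#'
#' `H = -sum(p * log2(p))` over positive-mass categories, with the
#' convention `0 * log(0) = 0`. Higher values indicate a more diverse
#' mutation spectrum.
#'
#' @param proportions non-negative fractions summing to 1 (within 1e-9).
#' @return list with `bits` and `k` (number of positive-mass categories).
#' @examples
#' shannonEntropy(c(0.5, 0.25, 0.25))$bits   # 1.5
#' @export
shannonEntropy <- function(proportions) {
  if (any(proportions < 0)) stop("negative proportion")
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1")
  pos <- proportions[proportions > 0]
  list(bits = -sum(pos * log2(pos)), k = length(pos))
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Exact p-value (full enumeration) when both samples have at most 8
#' observations and there are no ties; otherwise the normal approximation
#' with tie-corrected variance and continuity correction. Identical groups
#' give p = 1.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `statistic` (the Mann-Whitney U of `x`), `p` (two
#'   sided), `exact` (logical).
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))$p   # 0.1
#' @export
wilcoxonRankSum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p = 1,
                exact = FALSE))
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && max(length(x), length(y)) <= 8L
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p = unname(wt$p.value),
       exact = exact)
}

#' Significance stars for a p-value
#'
#' Inclusive boundaries: `*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001,
#' `****` p <= 0.0001, otherwise `ns`.
#'
#' @param p p-value in `[0, 1]`.
#' @return one of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
significanceStars <- function(p) {
  if (is.na(p) || p < 0 || p > 1) stop("p must be in [0, 1]")
  if (p <= 1e-4) "****"
  else if (p <= 1e-3) "***"
  else if (p <= 0.01) "**"
  else if (p <= 0.05) "*"
  else "ns"
}
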