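#' Upper-tail hypergeometric enrichment probability
#'
#' `P(X >= x)` when drawing `n` items without replacement from a population
#' of `N` containing `K` category members. Computed via [stats::phyper()],
#' which works in log space internally, so margins in the tens of thousands
#' are handled without overflow.
#'
#' @param N Population size.
#' @param K Category positives in the population.
#' @param n Number of draws.
#' @param x Observed positives among the draws.
#' @return Probability in `[0, 1]`.
#' @examples
#' hypergeom_upper(10, 5, 5, 5) # 1/252
#' @export
hypergeom_upper <- function(N, K, n, x) {
  check_margins(N, K, n, x)
  phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Point hypergeometric probability
#'
#' `P(X == x)` under the same model as [hypergeom_upper()]. Exposed because
#' published enrichment tables are sometimes computed with the point mass of
#' the observed table rather than its tail, and reproducing such values
#' requires the point form.
#'
#' @inheritParams hypergeom_upper
#' @return Probability in `[0, 1]`.
#' @export
hypergeom_point <- function(N, K, n, x) {
  check_margins(N, K, n, x)
  dhyper(x, K, N - K, n)
}

check_margins <- function(N, K, n, x) {
  stopifnot(N >= 0, K >= 0, K <= N, n >= 0, n <= N, x >= 0)
  if (x > min(n, K))
    stop("invalid margins: x = ", x, " exceeds min(n, K) = ", min(n, K))
  invisible(TRUE)
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Standard two-sided rule: the sum of probabilities of all tables with the
#' same margins whose point probability does not exceed that of the observed
#' table. Delegates to [stats::fisher.test()].
#'
#' @param a,b,c,d Cell counts, row-wise: `[[a, b], [c, d]]`.
#' @return Two-sided p-value.
#' @examples
#' fisher_two_tailed(2, 0, 0, 2) # 1/3
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
}

#' Expected category count under random draws
#'
#' `n * K / N`: the expected number of category members among `n` draws,
#' the baseline the observed overlap count is compared against.
#'
#' @inheritParams hypergeom_upper
#' @return Expected count.
#' @export
expected_count <- function(N, K, n) {
  stopifnot(N > 0, K >= 0, K <= N, n >= 0, n <= N)
  n * K / N
}

#' Enrichment of a locus set against a feature category
#'
#' Packages the `(N, K, n, x)` margins with the expected count and all three
#' statistics: upper-tail hypergeometric, point hypergeometric, and
#' two-tailed Fisher on the induced 2x2 table
#' `[[x, n - x], [K - x, N - K - n + x]]`.
#'
#' @param category Label for the feature set.
#' @inheritParams hypergeom_upper
#' @return One-row data frame (an enrichment result record).
#' @export
enrich_test <- function(category, N, K, n, x) {
  check_margins(N, K, n, x)
  data.frame(category = category, N = N, K = K, n = n, x = x,
             expected = expected_count(N, K, n),
             p_hyper_upper = hypergeom_upper(N, K, n, x),
             p_hyper_point = hypergeom_point(N, K, n, x),
             p_fisher_two = fisher_two_tailed(x, n - x, K - x, N - K - n + x),
             stringsAsFactors = FALSE)
}

#' Enrichment of expressed loci in a BED feature set
#'
#' Builds the margins from interval overlap: `N` population loci, of which
#' `K` overlap the features; `n` expressed loci, of which `x` overlap.
#'
#' @param expressed Interval data frame of expressed loci (the draws).
#' @param population Interval data frame of all annotated loci.
#' @param features Interval data frame (e.g. TFBS or TAD regions).
#' @param category Label.
#' @param min_bp Minimum overlap in bases.
#' @return One-row enrichment result (see [enrich_test()]).
#' @export
enrich_overlap <- function(expressed, population, features,
                           category = "features", min_bp = 1L) {
  enrich_test(category,
              N = nrow(population),
              K = overlap_count(population, features, min_bp),
              n = nrow(expressed),
              x = overlap_count(expressed, features, min_bp))
}
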