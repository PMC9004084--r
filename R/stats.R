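#' Wilcoxon rank-sum test
#'
#' Thin wrapper around [stats::wilcox.test] returning a compact result. Exact
#' p-values are used for small, untied samples; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples.
#' @param alternative One of "two.sided", "greater", "less" (`x` vs `y`).
#' @return A list with `statistic` (rank-sum U), `p`, `alternative`,
#'   `n1`, `n2`.
#' @export
wilcoxonRankSum <- function(x, y,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1L || length(y) < 1L) stop("empty sample")
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       alternative = alternative, n1 = length(x), n2 = length(y))
}

#' Benjamini-Hochberg adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Step-up BH q-values (monotone in p, clipped at 1).
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Bonferroni adjustment by a fixed factor
#'
#' Multiplies p-values by `m` and clips at 1. The default of 6 matches two
#' comparisons in each of three cell types / tissues.
#'
#' @param p Numeric vector of p-values.
#' @param m Number of comparisons.
#' @return Adjusted p-values.
#' @export
bonferroniAdjust <- function(p, m = 6) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}

#' Compare two correlations by Fisher's r-to-z transformation
#'
#' Independent-samples comparison
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`. For
#' `alternative = "greater"` the one-sided p is `1 - pnorm(z)` (testing
#' r1 > r2). A Steiger-style dependent-samples correction is not applied;
#' see the methods vignette.
#'
#' @param r1,r2 Sample correlations with `|r| < 1`.
#' @param n1,n2 Sample sizes (>= 4).
#' @param alternative "greater" (r1 > r2), "less" or "two.sided".
#' @return A list with `statistic` (z), `p`, `alternative`, `n1`, `n2`.
#' @export
fisherRtoZCompare <- function(r1, n1, r2, n2,
                              alternative = c("greater", "less",
                                              "two.sided")) {
  alternative <- match.arg(alternative)
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 < 4 || n2 < 4) stop("need n >= 4")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- switch(alternative,
              greater = 1 - pnorm(z),
              less = pnorm(z),
              two.sided = 2 * pnorm(-abs(z)))
  list(statistic = z, p = p, alternative = alternative, n1 = n1, n2 = n2)
}
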