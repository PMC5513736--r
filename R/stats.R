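#' Multiple-testing corrections
#'
#' `bonferroni()` returns family-wise error rates, `min(1, p * m)`;
#' `benjamini_hochberg()` returns step-up FDR-adjusted P values. Both
#' delegate to [stats::p.adjust()] with `m` equal to the vector length
#' (one test per gene).
#'
#' @param p Numeric vector of raw P values in `[0, 1]`.
#' @return Adjusted P values, same order as the input.
#' @examples
#' bonferroni(c(0.001, 0.5, 0.9))
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
bonferroni <- function(p) {
  check_pvec(p)
  p.adjust(p, method = "bonferroni")
}

#' @rdname bonferroni
#' @export
benjamini_hochberg <- function(p) {
  check_pvec(p)
  p.adjust(p, method = "BH")
}

check_pvec <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("P values must lie in [0, 1]")
  invisible(p)
}

#' Hypergeometric gene-set overlap test
#'
#' Significance of the intersection of two gene sets drawn without
#' replacement from a common universe: the upper-tail probability
#' `P(X >= overlap)` for `X ~ Hypergeometric(universe, size_a, size_b)`.
#' One-tailed (enrichment), as used for Venn-overlap and category
#' over-representation questions.
#'
#' @param overlap Observed intersection size.
#' @param size_a,size_b Sizes of the two sets.
#' @param universe Number of genes both sets are drawn from.
#' @return Upper-tail probability.
#' @examples
#' hypergeom_overlap(5, 5, 5, 10)  # 1/choose(10, 5)
#' @export
hypergeom_overlap <- function(overlap, size_a, size_b, universe) {
  if (overlap < 0 || size_a < 0 || size_b < 0 ||
      overlap > min(size_a, size_b) ||
      size_a > universe || size_b > universe)
    stop("inconsistent overlap/set/universe counts")
  phyper(overlap - 1, size_a, universe - size_a, size_b,
         lower.tail = FALSE)
}
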