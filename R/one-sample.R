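#' Binomial tail probabilities for insertion counts
#'
#' Under the one-sample null every base pair has the same insertion
#' probability `p` (total unique insertions / genome size), so the number
#' of unique insertions in a gene of `n` base pairs is
#' `X ~ Binomial(n, p)`. `binom_lower()` returns the essentiality tail
#' `P(X <= k)` — small when a gene has fewer insertions than its length
#' predicts — and `binom_upper()` the improved-fitness tail `P(X >= k)`.
#' Note `P(X >= k)` is `1 - P(X <= k - 1)`, which keeps the `P(X = k)`
#' term in the upper tail. Computed via the regularized incomplete beta
#' function ([stats::pbinom()]), stable for `n` up to at least 1e7.
#'
#' @param k Observed unique insertions, `0 <= k <= n`.
#' @param n Gene length in base pairs (effective length after trimming).
#' @param p Genome-wide per-bp insertion probability, in (0, 1).
#' @return Tail probability in `[0, 1]`; vectorized over `k` and `n`.
#' @examples
#' binom_lower(0, 500, 0.01)  # (1 - 0.01)^500
#' binom_upper(0, 500, 0.01)  # 1: the certain event
#' @export
binom_lower <- function(k, n, p) {
  check_binom_args(k, n, p)
  pbinom(k, n, p)
}

#' @rdname binom_lower
#' @export
binom_upper <- function(k, n, p) {
  check_binom_args(k, n, p)
  pbinom(k - 1, n, p, lower.tail = FALSE)
}

check_binom_args <- function(k, n, p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
  if (any(k < 0 | k > n)) stop("require 0 <= k <= n")
  invisible(NULL)
}

#' One-sample binomial essentiality analysis
#'
#' Tests every gene's central-interval insertion count against the
#' genome-wide binomial null. The lower tail is the essentiality P value
#' (fewer insertions than expected), the upper tail the improved-fitness
#' P value (more than expected). Bonferroni (FWER) and Benjamini-Hochberg
#' adjustments are computed separately for the two tails across all
#' testable genes. Genes with zero effective length are reported with
#' missing statistics and call `"untestable"`.
#'
#' Using unique insertions instead of read totals sidesteps amplification
#' artifacts, and the binomial length model keeps small genes — which can
#' lack insertions by chance alone — from being called essential merely
#' for being short.
#'
#' @param gene_counts Per-gene counts from [assign_to_genes()].
#' @param library `tn_library_summary` supplying the insertion
#'   probability.
#' @param fwer_max FWER threshold for calls (default 0.01).
#' @param max_central_insertions Genes must have fewer than this many
#'   central insertions to be called essential (default 4); a buffer
#'   against insertions that do not abolish function.
#' @param inclusive If `TRUE` the insertion gate is `<=` instead of the
#'   default strict `<`.
#' @return A `tn_one_sample` data.frame, one row per gene in input order:
#'   `gene_id`, `length`, `effective_length`, `insertions_total`,
#'   `insertions_central`, `reads_total`, `p_essential`, `p_fitness`,
#'   `fwer_essential`, `fwer_fitness`, `adjp_essential`, `adjp_fitness`,
#'   `call`.
#' @export
one_sample_analysis <- function(gene_counts, library, fwer_max = 0.01,
                                max_central_insertions = 4,
                                inclusive = FALSE) {
  p <- library$insertion_probability
  if (p <= 0 || p >= 1) stop("library insertion probability outside (0,1)")
  res <- data.frame(
    gene_id = gene_counts$gene_id,
    length = gene_counts$length,
    effective_length = gene_counts$effective_length,
    insertions_total = gene_counts$insertions_total,
    insertions_central = gene_counts$insertions_central,
    reads_total = gene_counts$reads_total,
    p_essential = NA_real_, p_fitness = NA_real_,
    stringsAsFactors = FALSE)

  ok <- res$effective_length > 0
  res$p_essential[ok] <- binom_lower(res$insertions_central[ok],
                                     res$effective_length[ok], p)
  res$p_fitness[ok] <- binom_upper(res$insertions_central[ok],
                                   res$effective_length[ok], p)
  res$fwer_essential <- na_keep(res$p_essential, bonferroni)
  res$fwer_fitness <- na_keep(res$p_fitness, bonferroni)
  res$adjp_essential <- na_keep(res$p_essential, benjamini_hochberg)
  res$adjp_fitness <- na_keep(res$p_fitness, benjamini_hochberg)

  res <- classify_essential(res, fwer_max = fwer_max,
                            max_central_insertions = max_central_insertions,
                            inclusive = inclusive)
  attr(res, "library") <- library
  attr(res, "params") <- list(fwer_max = fwer_max,
                              max_central_insertions = max_central_insertions,
                              inclusive = inclusive)
  class(res) <- c("tn_one_sample", "data.frame")
  res
}

# apply a correction over the non-missing entries only (m = genes tested)
na_keep <- function(p, f) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- f(p[ok])
  out
}

#' Classify one-sample results into essentiality calls
#'
#' A gene is `essential` when its essentiality FWER is below `fwer_max`
#' AND it has fewer than `max_central_insertions` unique insertions in the
#' central interval; significant genes failing the insertion gate are
#' `reduced_fitness`; genes whose improved-fitness FWER passes are
#' `improved_fitness`; everything else is `neutral` (genes with no
#' statistics: `untestable`).
#'
#' @param results data.frame with `fwer_essential`, `fwer_fitness`,
#'   `insertions_central` columns.
#' @inheritParams one_sample_analysis
#' @return `results` with the `call` column set.
#' @export
classify_essential <- function(results, fwer_max = 0.01,
                               max_central_insertions = 4,
                               inclusive = FALSE) {
  few <- if (inclusive)
    results$insertions_central <= max_central_insertions
  else
    results$insertions_central < max_central_insertions
  call <- rep("neutral", nrow(results))
  sig_low <- !is.na(results$fwer_essential) &
    results$fwer_essential < fwer_max
  sig_high <- !is.na(results$fwer_fitness) &
    results$fwer_fitness < fwer_max
  call[sig_high] <- "improved_fitness"
  call[sig_low & !few] <- "reduced_fitness"
  call[sig_low & few] <- "essential"
  call[is.na(results$p_essential)] <- "untestable"
  results$call <- call
  results
}

#' @export
print.tn_one_sample <- function(x, ...) {
  pr <- attr(x, "params")
  cat(sprintf(
    "One-sample binomial essentiality analysis: %d genes (FWER < %g, < %d central insertions)\n",
    nrow(x), pr$fwer_max, pr$max_central_insertions))
  print(table(call = x$call))
  invisible(x)
}

#' @export
summary.tn_one_sample <- function(object, ...) {
  lib <- attr(object, "library")
  print(lib)
  print(object)
  invisible(object)
}
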