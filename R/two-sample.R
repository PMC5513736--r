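#' Normalized per-gene fold change between two libraries
#'
#' Reads are normalized to library fractions before the ratio is taken:
#' `fc = ((reads_treat + pseudocount)/total_treat) /
#'       ((reads_ref + pseudocount)/total_ref)`.
#' The pseudocount (default 1 read) keeps the ratio finite for genes with
#' zero treatment reads — routine for conditionally essential genes.
#'
#' @param reads_treat,reads_ref Bias-corrected read counts for one gene.
#' @param total_treat,total_ref Summed bias-corrected reads over all
#'   genes in each library (must be > 0).
#' @param pseudocount Reads added to each gene count (default 1).
#' @return List with `fc` and `log2fc`; vectorized over genes.
#' @export
fold_change <- function(reads_treat, total_treat, reads_ref, total_ref,
                        pseudocount = 1) {
  if (any(c(total_treat, total_ref) <= 0))
    stop("library read totals must be positive")
  fc <- ((reads_treat + pseudocount) / total_treat) /
        ((reads_ref + pseudocount) / total_ref)
  list(fc = fc, log2fc = log2(fc))
}

#' Fisher's exact test on a 2x2 read-count table
#'
#' Two-sided exact P for the table
#' `[gene reads, rest-of-library reads] x [treatment, reference]`,
#' summing hypergeometric outcomes no more probable than the observed one
#' (via [stats::fisher.test()]).
#'
#' @param a,b,c,d Nonnegative integer cell counts: `a`,`b` = gene and
#'   rest-of-library reads in treatment; `c`,`d` the same in reference.
#' @return Two-sided P value.
#' @export
fisher_test <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("2x2 cell counts must be nonnegative")
  min(1, fisher.test(matrix(round(cells), nrow = 2, byrow = TRUE))$p.value)
}

#' Two-proportion z-test with pooled variance
#'
#' Compares `x1/n1` with `x2/n2` using the pooled-variance normal
#' approximation, two-sided, without continuity correction:
#' `z = (x1/n1 - x2/n2) / sqrt(pbar (1 - pbar) (1/n1 + 1/n2))`.
#' Applied both to read counts and to central insertion counts. When the
#' pooled proportion is 0 or 1 there is no evidence either way and `p = 1`
#' is returned.
#'
#' @param x1,n1 Successes and trials in the first sample.
#' @param x2,n2 Successes and trials in the second sample.
#' @return List with `z` and two-sided `p`; vectorized.
#' @export
proportions_test <- function(x1, n1, x2, n2) {
  if (any(n1 <= 0 | n2 <= 0)) stop("n1 and n2 must be positive")
  if (any(x1 > n1 | x2 > n2 | x1 < 0 | x2 < 0))
    stop("require 0 <= x <= n in both samples")
  pbar <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (x1 / n1 - x2 / n2) / se, 0)
  list(z = z, p = ifelse(se > 0, 2 * pnorm(-abs(z)), 1))
}

#' Welch t-test on per-replicate normalized gene fractions
#'
#' Only meaningful with at least two replicates per condition; returns
#' `NA` otherwise. When both groups are constant, equal means give
#' `p = 1` and unequal means `p = 0` (the formal limit).
#'
#' @param values_treat,values_ref Numeric vectors of per-replicate
#'   normalized gene fractions.
#' @return Two-sided P value or `NA`.
#' @export
replicate_ttest <- function(values_treat, values_ref) {
  if (length(values_treat) < 2L || length(values_ref) < 2L)
    return(NA_real_)
  if (sd(values_treat) == 0 && sd(values_ref) == 0)
    return(if (mean(values_treat) == mean(values_ref)) 1 else 0)
  t.test(values_treat, values_ref)$p.value
}

#' Two-sample conditional-essentiality analysis
#'
#' Compares a treatment library (after selective outgrowth) against a
#' reference library gene by gene. Each library (or replicate) is
#' processed independently — minimum-read filtering, its own read cap,
#' per-gene tallies, optional insertion weighting — then per-gene
#' normalized fold changes and significance tests are computed:
#' Fisher's exact and the two-proportion z-test on (rounded) read counts,
#' the two-proportion z-test on central insertion counts, and, when both
#' conditions have >= 2 replicates, a Welch t-test on per-replicate gene
#' fractions. Each P-value family is Benjamini-Hochberg adjusted across
#' genes.
#'
#' @param treat,ref A site data.frame ([call_insertion_sites()]) or a
#'   list of them (replicates).
#' @param genes Gene models from [read_genes()].
#' @param genome `tn_genome`.
#' @param min_hits Minimum reads per retained site (default 10).
#' @param capping Read-cap method per library, `"mean_plus_2sd"`
#'   (default), `"mean"`, `"median"` or `"none"`.
#' @param weighting Apply insertion-based read weighting (default TRUE).
#' @param pseudocount Fold-change pseudocount (default 1 read).
#' @param lfc_max,adjp_max,max_central_insertions,statistic Passed to
#'   [classify_conditional()].
#' @return A `tn_two_sample` data.frame, one row per gene: counts,
#'   fractions, `fc`, `log2fc`, raw and BH-adjusted P values per test,
#'   `insertions_central_treat/_ref` and the categorical `call`.
#' @export
two_sample_analysis <- function(treat, ref, genes, genome,
                                min_hits = 10,
                                capping = "mean_plus_2sd",
                                weighting = TRUE, pseudocount = 1,
                                lfc_max = -2, adjp_max = 0.05,
                                max_central_insertions = 4,
                                statistic = "proportions_insertions") {
  tr <- process_condition(treat, genes, genome, min_hits, capping, weighting)
  rf <- process_condition(ref, genes, genome, min_hits, capping, weighting)

  fcr <- fold_change(tr$reads, tr$total, rf$reads, rf$total, pseudocount)
  n <- nrow(genes)
  p_fisher <- vapply(seq_len(n), function(i)
    fisher_test(tr$reads[i], tr$total - tr$reads[i],
                rf$reads[i], rf$total - rf$reads[i]), 0)
  p_prop_reads <- proportions_test(tr$reads, tr$total, rf$reads, rf$total)$p
  p_prop_ins <- proportions_test(tr$ins, tr$ins_total,
                                 rf$ins, rf$ins_total)$p
  p_ttest <- if (tr$n_rep >= 2L && rf$n_rep >= 2L)
    vapply(seq_len(n), function(i)
      replicate_ttest(tr$frac[i, ], rf$frac[i, ]), 0)
  else rep(NA_real_, n)

  res <- data.frame(
    gene_id = genes$gene_id,
    reads_treat = tr$reads, reads_ref = rf$reads,
    frac_treat = tr$reads / tr$total, frac_ref = rf$reads / rf$total,
    fc = fcr$fc, log2fc = fcr$log2fc,
    p_fisher = p_fisher, adjp_fisher = benjamini_hochberg(p_fisher),
    p_prop_reads = p_prop_reads,
    adjp_prop_reads = benjamini_hochberg(p_prop_reads),
    p_prop_insertions = p_prop_ins,
    adjp_prop_insertions = benjamini_hochberg(p_prop_ins),
    p_ttest = p_ttest,
    adjp_ttest = na_keep(p_ttest, benjamini_hochberg),
    insertions_central_treat = tr$ins,
    insertions_central_ref = rf$ins,
    stringsAsFactors = FALSE)

  res <- classify_conditional(res, lfc_max = lfc_max, adjp_max = adjp_max,
                              max_central_insertions = max_central_insertions,
                              statistic = statistic)
  attr(res, "params") <- list(
    min_hits = min_hits, capping = capping, weighting = weighting,
    pseudocount = pseudocount, lfc_max = lfc_max, adjp_max = adjp_max,
    max_central_insertions = max_central_insertions, statistic = statistic,
    n_rep_treat = tr$n_rep, n_rep_ref = rf$n_rep)
  class(res) <- c("tn_two_sample", "data.frame")
  res
}

# one condition: per-replicate site filtering, capping, gene tallies and
# weighting; counts summed over replicates, fractions kept per replicate
process_condition <- function(sites, genes, genome, min_hits, capping,
                              weighting) {
  if (is.data.frame(sites)) sites <- list(sites)
  reps <- lapply(sites, function(s) {
    s <- filter_min_hits(s, min_hits)
    if (!identical(capping, "none") && nrow(s) > 0L)
      s <- apply_cap(s, compute_cap(s, capping))
    gc <- assign_to_genes(s, genes)
    lib <- summarize_library(s, genome, gc)
    if (weighting) gc <- weight_reads(gc, lib)
    gc
  })
  wr <- vapply(reps, function(gc) gc$reads_weighted, numeric(nrow(genes)))
  wr <- matrix(wr, nrow = nrow(genes))
  ins <- rowSums(matrix(
    vapply(reps, function(gc) gc$insertions_central, numeric(nrow(genes))),
    nrow = nrow(genes)))
  reads <- round_half_up(rowSums(wr))
  totals <- colSums(wr)
  if (any(totals <= 0)) stop("a replicate has zero reads in genes")
  list(reads = reads, total = sum(reads), ins = ins,
       ins_total = sum(ins), frac = sweep(wr, 2, totals, "/"),
       n_rep = length(reps))
}

#' Classify two-sample results into conditional-essentiality calls
#'
#' `depleted`: `log2fc` below `lfc_max` and the chosen adjusted P below
#' `adjp_max`; `conditionally_essential`: additionally fewer than
#' `max_central_insertions` central insertions in the treatment library;
#' `enriched`: `log2fc` above `-lfc_max` with significant adjusted P;
#' otherwise `neutral`.
#'
#' @param results `tn_two_sample` data.frame.
#' @param lfc_max log2 fold-change threshold (default -2, i.e. 16-fold
#'   depletion).
#' @param adjp_max Adjusted-P threshold (default 0.05).
#' @param max_central_insertions Treatment central-insertion gate
#'   (default 4, strict `<`).
#' @param statistic Which adjusted P value gates the calls:
#'   `"proportions_insertions"` (default), `"proportions_reads"`,
#'   `"fisher"` or `"ttest"`.
#' @param inclusive If `TRUE` the insertion gate is `<=`.
#' @return `results` with the `call` column set.
#' @export
classify_conditional <- function(results, lfc_max = -2, adjp_max = 0.05,
                                 max_central_insertions = 4,
                                 statistic = "proportions_insertions",
                                 inclusive = FALSE) {
  col <- switch(statistic,
    proportions_insertions = "adjp_prop_insertions",
    proportions_reads = "adjp_prop_reads",
    fisher = "adjp_fisher",
    ttest = "adjp_ttest",
    stop("unknown classification statistic: ", statistic))
  adj <- results[[col]]
  sig <- !is.na(adj) & adj < adjp_max
  few <- if (inclusive)
    results$insertions_central_treat <= max_central_insertions
  else
    results$insertions_central_treat < max_central_insertions
  call <- rep("neutral", nrow(results))
  call[sig & results$log2fc > -lfc_max] <- "enriched"
  call[sig & results$log2fc < lfc_max] <- "depleted"
  call[sig & results$log2fc < lfc_max & few] <- "conditionally_essential"
  results$call <- call
  results
}

#' @export
print.tn_two_sample <- function(x, ...) {
  pr <- attr(x, "params")
  cat(sprintf(
    "Two-sample conditional-essentiality analysis: %d genes (log2FC < %g, %s adj. P < %g)\n",
    nrow(x), pr$lfc_max, pr$statistic, pr$adjp_max))
  print(table(call = x$call))
  invisible(x)
}
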