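#' Call transposon insertion sites from aligned junction reads
#'
#' The sequencing primer reads outward from the transposon end, so the
#' first aligned base of a read is the transposon/genome junction: for a
#' forward-strand alignment that is the leftmost base, for a
#' reverse-strand alignment the rightmost base
#' (`leftmost + aligned_length - 1`). Sites are collapsed across strands —
#' gene disruption is a property of the position, and the two transposon
#' orientations at one base pair are not distinguishable in this read-out.
#'
#' @param reads data.frame from [read_alignments()].
#' @return data.frame of insertion sites: `replicon`, `position`,
#'   `read_count`, sorted by replicon then position.
#' @export
call_insertion_sites <- function(reads) {
  if (nrow(reads) == 0L)
    return(data.frame(replicon = character(), position = numeric(),
                      read_count = numeric(), stringsAsFactors = FALSE))
  junction <- ifelse(reads$strand == "reverse",
                     reads$leftmost + reads$aligned_length - 1,
                     reads$leftmost)
  dt <- data.table::data.table(replicon = reads$replicon,
                               position = junction)
  agg <- dt[, list(read_count = as.numeric(.N)),
            by = c("replicon", "position")]
  data.table::setorderv(agg, c("replicon", "position"))
  as.data.frame(agg)
}

#' Apply the minimum-read threshold to insertion sites
#'
#' A mapped position only counts as a genuine unique insertion if enough
#' independent junction reads support it; sites below `min_hits` reads
#' (default 10) are removed before all downstream statistics, including
#' the genome-wide insertion probability.
#'
#' @param sites Site data.frame from [call_insertion_sites()].
#' @param min_hits Minimum supporting reads per retained site (>= 1).
#' @return Filtered site data.frame, input order preserved.
#' @export
filter_min_hits <- function(sites, min_hits = 10) {
  if (length(min_hits) != 1L || is.na(min_hits) || min_hits < 1)
    stop("min_hits must be a single value >= 1")
  sites[sites$read_count >= min_hits, , drop = FALSE]
}

#' Aggregate insertion sites into per-gene counts
#'
#' A site contributes to a gene's full-interval tallies when
#' `start <= position <= end` and to the central tallies when it falls in
#' the trimmed central interval. Genes with no sites get zero counts; a
#' site inside two overlapping genes counts in both.
#'
#' @param sites Filtered site data.frame. If an uncapped `read_count_raw`
#'   column is present (added by [apply_cap()]), raw and capped read sums
#'   are reported separately; otherwise both equal the `read_count` sums.
#' @param genes Gene-model data.frame from [read_genes()].
#' @return data.frame with one row per gene (input order): `gene_id`,
#'   `length`, `effective_length`, `insertions_total`, `insertions_central`,
#'   `reads_total`, `reads_central`, `reads_capped`, `reads_capped_central`,
#'   `reads_weighted` (capped until [weight_reads()] is applied) and
#'   `insertion_density_norm` = central insertions per central bp.
#' @export
assign_to_genes <- function(sites, genes) {
  n <- nrow(genes)
  out <- data.frame(
    gene_id = genes$gene_id,
    length = genes$length,
    effective_length = genes$effective_length,
    insertions_total = numeric(n), insertions_central = numeric(n),
    reads_total = numeric(n), reads_central = numeric(n),
    reads_capped = numeric(n), reads_capped_central = numeric(n),
    stringsAsFactors = FALSE)

  if (nrow(sites) > 0L) {
    raw <- if ("read_count_raw" %in% names(sites))
      sites$read_count_raw else sites$read_count
    site_gr <- GenomicRanges::GRanges(
      sites$replicon, IRanges::IRanges(sites$position, sites$position))
    tally <- function(start, end) {
      gr <- GenomicRanges::GRanges(
        genes$replicon, IRanges::IRanges(start, end))
      ov <- GenomicRanges::findOverlaps(site_gr, gr)
      gi <- S4Vectors::subjectHits(ov)
      si <- S4Vectors::queryHits(ov)
      list(ins = tabulate(gi, nbins = n),
           reads = as.numeric(tapply_sum(raw[si], gi, n)),
           capped = as.numeric(tapply_sum(sites$read_count[si], gi, n)))
    }
    full <- tally(genes$start, genes$end)
    cen <- tally(genes$central_start, genes$central_end)
    out$insertions_total <- full$ins
    out$insertions_central <- cen$ins
    out$reads_total <- full$reads
    out$reads_central <- cen$reads
    out$reads_capped <- full$capped
    out$reads_capped_central <- cen$capped
  }
  out$reads_weighted <- out$reads_capped
  out$insertion_density_norm <-
    ifelse(out$effective_length > 0,
           out$insertions_central / out$effective_length, 0)
  out
}

# grouped sum with fixed group count (zeros kept)
tapply_sum <- function(x, g, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- rowsum(x, g)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

#' Summarize a Tn-seq library
#'
#' Library-wide totals behind the one-sample null: the genome-wide
#' insertion probability `p` is the number of unique insertions divided by
#' the genome size in base pairs, and the insertion density its reciprocal
#' (bp per insertion). `avg_norm_insertions` is the mean over all genes
#' (zeros included) of central insertions per central bp, the denominator
#' of the read-weighting correction.
#'
#' @param sites Filtered site data.frame.
#' @param genome `tn_genome`.
#' @param gene_counts Per-gene counts from [assign_to_genes()].
#' @return Object of class `tn_library_summary`: `total_insertions`,
#'   `total_mapped_reads`, `genome_length`, `insertion_probability`,
#'   `density` (bp per insertion), `avg_norm_insertions`, `n_genes`.
#' @export
summarize_library <- function(sites, genome, gene_counts) {
  if (nrow(sites) == 0L)
    stop("library has no insertion sites after filtering; unusable")
  total_ins <- nrow(sites)
  p <- total_ins / genome$total_length
  if (p >= 1) stop("more insertion sites than base pairs; corrupt input")
  structure(list(
    total_insertions = total_ins,
    total_mapped_reads = sum(sites$read_count),
    genome_length = genome$total_length,
    insertion_probability = p,
    density = genome$total_length / total_ins,
    avg_norm_insertions = mean(gene_counts$insertion_density_norm),
    n_genes = nrow(gene_counts)),
    class = "tn_library_summary")
}

#' @export
print.tn_library_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Tn-seq library: %s unique insertions over %s bp",
           " (1 per %.0f bp; p = %.3g)\n",
           "  mapped reads at retained sites: %s;",
           " mean central insertion density over %d genes: %.3g /bp\n"),
    format(x$total_insertions, big.mark = ","),
    format(x$genome_length, big.mark = ","),
    x$density, x$insertion_probability,
    format(x$total_mapped_reads, big.mark = ","),
    x$n_genes, x$avg_norm_insertions))
  invisible(x)
}
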