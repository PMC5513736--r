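#' Compute a read-capping policy for a library
#'
#' PCR amplification during sample preparation can grossly exaggerate the
#' read count at individual insertion sites ("jackpots"). Capping places a
#' library-derived upper bound on the reads allowed at any one site:
#' mean + 2 standard deviations of the per-site read counts (the default),
#' the mean, or the median. The standard deviation is the population
#' (n-divisor) statistic over all retained sites.
#'
#' @param sites Nonempty site data.frame.
#' @param method `"mean_plus_2sd"` (default), `"mean"` or `"median"`.
#' @return A `tn_cap_policy`: list with `method` and `cap_value`.
#' @export
compute_cap <- function(sites,
                        method = c("mean_plus_2sd", "mean", "median")) {
  method <- match.arg(method)
  x <- sites$read_count
  if (length(x) == 0L) stop("cannot compute a read cap from zero sites")
  cap <- switch(method,
    mean_plus_2sd = mean(x) + 2 * sqrt(mean((x - mean(x))^2)),
    mean = mean(x),
    median = stats::median(x))
  structure(list(method = method, cap_value = cap), class = "tn_cap_policy")
}

#' @export
print.tn_cap_policy <- function(x, ...) {
  cat(sprintf("Read cap: %s = %.4g reads/site\n", x$method, x$cap_value))
  invisible(x)
}

#' Apply a read cap to per-site counts
#'
#' Clamps each site's read count at the policy's `cap_value`; the site set
#' itself is unchanged and the operation is idempotent. The original
#' counts are preserved in a `read_count_raw` column so downstream
#' tallies can report both.
#'
#' @param sites Site data.frame.
#' @param policy `tn_cap_policy` from [compute_cap()], computed from this
#'   library or a declared reference.
#' @return `sites` with `read_count` clamped and `read_count_raw` added.
#' @export
apply_cap <- function(sites, policy) {
  stopifnot(inherits(policy, "tn_cap_policy"))
  if (!"read_count_raw" %in% names(sites))
    sites$read_count_raw <- sites$read_count
  sites$read_count <- pmin(sites$read_count, policy$cap_value)
  sites
}

#' Weight per-gene read counts by relative insertion density
#'
#' The number of distinct insertions a gene tolerates is a stronger
#' essentiality signal than its raw read total, which is hostage to
#' amplification artifacts. Weighting rescales each gene's (capped) read
#' total by its central insertion density relative to the genome-average
#' density over genes:
#' `reads_weighted(i) = reads_capped(i) * density(i) / mean density`.
#' Genes at exactly average density keep their reads; denser genes gain,
#' sparser genes lose; genes with no insertions go to zero.
#'
#' @param gene_counts Per-gene counts from [assign_to_genes()].
#' @param library `tn_library_summary` supplying `avg_norm_insertions`.
#' @return `gene_counts` with `reads_weighted` replaced.
#' @export
weight_reads <- function(gene_counts, library) {
  avg <- library$avg_norm_insertions
  if (!is.finite(avg) || avg <= 0)
    stop("average normalized insertions per gene is zero; cannot weight")
  gene_counts$reads_weighted <-
    gene_counts$reads_capped * gene_counts$insertion_density_norm / avg
  gene_counts
}

# round half-up; count-based tests need integers from weighted reads
round_half_up <- function(x) floor(x + 0.5)
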