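#' Configuration for the Tn5 library simulator
#'
#' The defaults describe a desk-scale Tn5 mutagenesis of a high-GC
#' bacterial chromosome: a 3 Mb replicon at 69% GC, 2,000 non-overlapping
#' genes with log-normal lengths (median ~900 bp), 10% of genes essential,
#' one insertion per 30 bp on average, a heavy-tailed (shifted geometric)
#' read count per site with mean 50 and 1% PCR-jackpot sites at 100x, and
#' 50 bp aligned junction reads.
#'
#' @param seed Integer RNG seed; every simulator stage derives its stream
#'   from it, so identical configs give byte-identical outputs.
#' @param genome_length Replicon length in bp.
#' @param gc_fraction GC content of the simulated sequence.
#' @param n_genes Number of non-overlapping genes.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene-length
#'   parameters (meanlog `log(900)` makes the median ~900 bp).
#' @param min_gene_length Lower clamp on simulated gene lengths (bp).
#' @param essential_fraction Fraction of genes made essential: their
#'   central interval receives no insertions (their trimmed 5'/3' ends
#'   still do, which is what the trimming buffer exists for).
#' @param essential_leak_rate Fraction of the normal insertion density
#'   still applied inside essential central intervals (default 0).
#' @param insertion_density Per-bp probability of a true transposon
#'   insertion site. The default 1/25 realizes a *unique-insertion*
#'   density (sites with >= 10 reads, the quantity a library summary
#'   reports) of about 1 per 30 bp, since a mean-50 shifted-geometric
#'   read count keeps a fraction (1 - 1/50)^9 ~ 0.83 of sites above the
#'   10-read threshold.
#' @param reads_per_site_mean Mean of the shifted-geometric (minimum 1)
#'   reads per insertion site.
#' @param jackpot_fraction Fraction of sites whose reads are multiplied
#'   by `jackpot_multiplier` (PCR jackpots).
#' @param jackpot_multiplier Read multiplier at jackpot sites (100x).
#' @param read_length Aligned read length in bp for emitted alignments.
#' @param trim_fraction 5'/3' trim used for the central intervals.
#' @param doublings Outgrowth doublings for [simulate_outgrowth()].
#' @param fitness_effects Optional named vector/list of per-doubling
#'   fitness multipliers by `gene_id`, applied to the truth table for
#'   [simulate_outgrowth()] (unlisted genes have fitness 1).
#' @param replicon_name Name of the simulated replicon.
#' @return A `tn_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 3e6,
                       gc_fraction = 0.69,
                       n_genes = 2000L,
                       gene_length_meanlog = log(900),
                       gene_length_sdlog = 0.45,
                       min_gene_length = 150L,
                       essential_fraction = 0.10,
                       essential_leak_rate = 0,
                       insertion_density = 1 / 25,
                       reads_per_site_mean = 50,
                       jackpot_fraction = 0.01,
                       jackpot_multiplier = 100,
                       read_length = 50L,
                       trim_fraction = 0.10,
                       doublings = 7,
                       fitness_effects = NULL,
                       replicon_name = "sim_chr1") {
  cfg <- as.list(environment())
  stopifnot(cfg$insertion_density > 0, cfg$insertion_density < 1,
            cfg$gc_fraction >= 0, cfg$gc_fraction <= 1,
            cfg$reads_per_site_mean >= 1, cfg$n_genes >= 1)
  structure(cfg, class = "tn_sim_config")
}

#' Simulate a genome with annotated genes and essentiality ground truth
#'
#' Draws an i.i.d. base sequence at the configured GC content and places
#' `n_genes` non-overlapping genes along it, distributing the intergenic
#' slack with random gaps (which always succeeds when total gene length
#' is at most 90% of the genome). A seeded run is fully deterministic.
#'
#' @param config `tn_sim_config`.
#' @param dir Optional directory; when given, `genome.fasta`,
#'   `genes.gff3` and `truth.tsv` are written there.
#' @return A `tn_sim_genome`: list with `genome` (`tn_genome`), `genes`
#'   (trimmed gene models), `truth` (data.frame `gene_id`, `essential`,
#'   `fitness`), `sequence` (`DNAStringSet`), `config` and `paths`.
#' @export
simulate_genome <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "tn_sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  L <- config$genome_length

  lens <- pmax(config$min_gene_length,
               round(rlnorm(n, config$gene_length_meanlog,
                            config$gene_length_sdlog)))
  if (sum(lens) > 0.9 * L)
    stop("genes occupy > 90% of the genome; lower n_genes or gene lengths")

  slack <- L - sum(lens)
  w <- runif(n + 1)
  gaps <- floor(slack * w / sum(w))
  gaps[n + 1] <- gaps[n + 1] + (slack - sum(gaps))
  starts <- 1 + cumsum(gaps[seq_len(n)]) + c(0, cumsum(lens))[seq_len(n)]
  genes <- data.frame(
    gene_id = sprintf("TNSIM_%04d", seq_len(n)),
    replicon = config$replicon_name,
    start = starts, end = starts + lens - 1,
    strand = ifelse(runif(n) < 0.5, "forward", "reverse"),
    stringsAsFactors = FALSE)
  genes <- trim_gene_models(genes, config$trim_fraction)

  ess <- rep(FALSE, n)
  n_ess <- round(config$essential_fraction * n)
  if (n_ess > 0) ess[sample.int(n, n_ess)] <- TRUE
  truth <- data.frame(gene_id = genes$gene_id, essential = ess,
                      fitness = 1, stringsAsFactors = FALSE)
  if (!is.null(config$fitness_effects)) {
    fe <- unlist(config$fitness_effects)
    hit <- match(names(fe), truth$gene_id)
    truth$fitness[hit[!is.na(hit)]] <- fe[!is.na(hit)]
  }

  gc <- config$gc_fraction
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  seq <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(seq) <- config$replicon_name

  genome <- structure(
    list(replicons = data.frame(name = config$replicon_name,
                                length = as.numeric(L),
                                stringsAsFactors = FALSE),
         total_length = as.numeric(L)),
    class = "tn_genome")

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fasta = file.path(dir, "genome.fasta"),
                  gff3 = file.path(dir, "genes.gff3"),
                  truth = file.path(dir, "truth.tsv"))
    Biostrings::writeXStringSet(seq, paths$fasta)
    write_sim_gff3(genes, paths$gff3)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  structure(list(genome = genome, genes = genes, truth = truth,
                 sequence = seq, config = config, paths = paths),
            class = "tn_sim_genome")
}

write_sim_gff3 <- function(genes, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf(
    "%s\ttnseqr_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s",
    genes$replicon, genes$start, genes$end,
    ifelse(genes$strand == "reverse", "-", "+"),
    genes$gene_id, genes$gene_id), con)
  invisible(path)
}

#' Simulate a Tn5 insertion library
#'
#' Every base pair outside essential central intervals receives an
#' insertion site independently with probability `insertion_density`
#' (the uniform-insertion null of the one-sample model); essential
#' central intervals receive none (or a configurable leak). Reads per
#' site follow a shifted geometric with the configured mean; a random
#' `jackpot_fraction` of sites is multiplied by `jackpot_multiplier`.
#' Optionally the individual junction reads are emitted as legacy
#' Bowtie-format lines with correct strand geometry (forward reads start
#' at the site; reverse reads end at it).
#'
#' @param sim_genome `tn_sim_genome` from [simulate_genome()].
#' @param config Defaults to the genome's config.
#' @param alignment_path Optional path; when given, one Bowtie-format
#'   line per read is written there.
#' @param seed_offset Added to `config$seed` for this stage's RNG stream
#'   (use different offsets for independent replicate libraries).
#' @return A `tn_sim_library`: list with `sites` (truth site table:
#'   `replicon`, `position`, `read_count`), `config`, `alignment_path`.
#' @export
simulate_library <- function(sim_genome, config = sim_genome$config,
                             alignment_path = NULL, seed_offset = 1L) {
  stopifnot(inherits(sim_genome, "tn_sim_genome"))
  set.seed(config$seed + seed_offset)
  L <- config$genome_length
  pos <- which(runif(L) < config$insertion_density)

  ess_genes <- sim_genome$genes[sim_genome$truth$essential, , drop = FALSE]
  if (nrow(ess_genes) > 0 && length(pos) > 0) {
    central <- logical(L)
    for (i in seq_len(nrow(ess_genes)))
      central[ess_genes$central_start[i]:ess_genes$central_end[i]] <- TRUE
    masked <- central[pos]
    keep <- !masked | (runif(length(pos)) < config$essential_leak_rate)
    pos <- pos[keep]
  }
  nsite <- length(pos)
  counts <- 1 + rgeom(nsite, 1 / config$reads_per_site_mean)
  jack <- runif(nsite) < config$jackpot_fraction
  counts[jack] <- counts[jack] * config$jackpot_multiplier

  sites <- data.frame(replicon = rep(config$replicon_name, nsite),
                      position = as.numeric(pos),
                      read_count = as.numeric(counts),
                      stringsAsFactors = FALSE)
  if (!is.null(alignment_path))
    write_bowtie_reads(sites, sim_genome$genome, config$read_length,
                       alignment_path)
  structure(list(sites = sites, config = config,
                 alignment_path = alignment_path),
            class = "tn_sim_library")
}

#' Simulate selective outgrowth of a Tn5 library
#'
#' Models competitive growth of the pooled library for `doublings`
#' generations: the expected reads at each site are scaled by
#' `fitness(gene)^doublings` for sites inside genes (intergenic sites
#' have fitness 1), renormalized to the sequencing depth, and resampled
#' as a multinomial. A gene with per-doubling fitness `2^(-4/7)` is thus
#' depleted by an expected 4 log2 units after 7 doublings.
#'
#' @param sim_library `tn_sim_library` from [simulate_library()].
#' @param sim_genome The matching `tn_sim_genome`.
#' @param fitness Named vector of per-doubling fitness multipliers by
#'   `gene_id`; defaults to the truth table's `fitness` column (all 1).
#' @param doublings Number of doublings (default from the config, 7).
#' @param depth Total reads after outgrowth (default: input depth).
#' @param alignment_path,seed_offset As in [simulate_library()].
#' @return A `tn_sim_library` with post-outgrowth `sites` (zero-read
#'   sites dropped).
#' @export
simulate_outgrowth <- function(sim_library, sim_genome, fitness = NULL,
                               doublings = sim_library$config$doublings,
                               depth = NULL, alignment_path = NULL,
                               seed_offset = 2L) {
  stopifnot(inherits(sim_library, "tn_sim_library"),
            inherits(sim_genome, "tn_sim_genome"))
  config <- sim_library$config
  set.seed(config$seed + seed_offset)
  sites <- sim_library$sites
  if (is.null(fitness))
    fitness <- setNames(sim_genome$truth$fitness, sim_genome$truth$gene_id)

  site_fit <- rep(1, nrow(sites))
  genes <- sim_genome$genes
  gr_sites <- GenomicRanges::GRanges(
    sites$replicon, IRanges::IRanges(sites$position, sites$position))
  gr_genes <- GenomicRanges::GRanges(
    genes$replicon, IRanges::IRanges(genes$start, genes$end))
  ov <- GenomicRanges::findOverlaps(gr_sites, gr_genes)
  f <- fitness[genes$gene_id[S4Vectors::subjectHits(ov)]]
  f[is.na(f)] <- 1
  # a site under two overlapping genes takes the stronger selection
  site_fit[S4Vectors::queryHits(ov)] <-
    pmin(site_fit[S4Vectors::queryHits(ov)], f)

  expected <- sites$read_count * site_fit^doublings
  if (is.null(depth)) depth <- sum(sites$read_count)
  if (sum(expected) <= 0) stop("all sites have zero expected reads")
  newc <- as.numeric(rmultinom(1, size = depth,
                               prob = expected / sum(expected)))
  out <- sites
  out$read_count <- newc
  out <- out[out$read_count > 0, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(alignment_path))
    write_bowtie_reads(out, sim_genome$genome, config$read_length,
                       alignment_path)
  structure(list(sites = out, config = config,
                 alignment_path = alignment_path),
            class = "tn_sim_library")
}

#' @export
print.tn_sim_genome <- function(x, ...) {
  cat(sprintf(
    "Simulated genome: %s bp, %d genes (%d essential), seed %d\n",
    format(x$config$genome_length, big.mark = ","), nrow(x$genes),
    sum(x$truth$essential), x$config$seed))
  invisible(x)
}

#' @export
print.tn_sim_library <- function(x, ...) {
  cat(sprintf(
    "Simulated Tn5 library: %s sites, %s reads%s\n",
    format(nrow(x$sites), big.mark = ","),
    format(sum(x$sites$read_count), big.mark = ","),
    if (is.null(x$alignment_path)) ""
    else paste0(" (alignments: ", x$alignment_path, ")")))
  invisible(x)
}

# Emit one legacy Bowtie-format line per junction read. Forward reads
# have leftmost = site (0-based offset = site - 1); reverse reads end at
# the site (0-based offset = site - read_length). Strand is random where
# both orientations fit within the replicon.
write_bowtie_reads <- function(sites, genome, read_length, path) {
  rl <- setNames(genome$replicons$length, genome$replicons$name)
  idx <- rep.int(seq_len(nrow(sites)), sites$read_count)
  pos <- sites$position[idx]
  chr <- sites$replicon[idx]
  lim <- rl[chr]
  fwd_ok <- pos + read_length - 1 <= lim
  rev_ok <- pos >= read_length
  if (any(!fwd_ok & !rev_ok))
    stop("replicon shorter than the read length")
  fwd <- ifelse(fwd_ok & rev_ok, runif(length(pos)) < 0.5, fwd_ok)
  offset0 <- ifelse(fwd, pos - 1, pos - read_length)
  dt <- data.table::data.table(
    name = paste0("r", seq_along(pos)),
    strand = ifelse(fwd, "+", "-"),
    replicon = chr,
    offset = offset0,
    seq = strrep("A", read_length),
    qual = strrep("I", read_length),
    ceil = 0L)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
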