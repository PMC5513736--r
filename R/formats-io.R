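#' Read a genome index from a FASTA file
#'
#' Only replicon names and lengths are retained: downstream statistics need
#' the genome size (the denominator of the genome-wide insertion
#' probability) and per-replicon bounds, not the sequence itself. The
#' replicon name is the header token before the first whitespace.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return An object of class `tn_genome`: a list with `replicons`
#'   (data.frame of `name`, `length`) and `total_length` in base pairs.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">chr1 main", "ACGTACGT", ">p1", "ACGT"), fa)
#' read_genome(fa)
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0L)
    stop("FASTA file '", path, "' contains no records")
  nm <- sub("\\s.*$", "", names(seqs))
  len <- Biostrings::width(seqs)
  if (any(len == 0L))
    stop("zero-length FASTA record: ", nm[which(len == 0L)[1L]])
  if (anyDuplicated(nm))
    stop("duplicate replicon name in FASTA: ", nm[duplicated(nm)][1L])
  structure(
    list(replicons = data.frame(name = nm, length = as.numeric(len),
                                stringsAsFactors = FALSE),
         total_length = sum(as.numeric(len))),
    class = "tn_genome")
}

#' @export
print.tn_genome <- function(x, ...) {
  cat("Genome index:", nrow(x$replicons), "replicon(s),",
      format(x$total_length, big.mark = ","), "bp total\n")
  print(x$replicons, row.names = FALSE)
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Keeps features of the requested type and derives, for each gene, the
#' "central" subinterval left after trimming a fixed fraction off the 5'
#' and 3' ends. Insertions in the trimmed ends frequently leave gene
#' function intact, so the statistical tests operate on the central
#' interval. The trim is `floor(trim_fraction * length)` base pairs per
#' end, which keeps the central interval nonempty for any
#' `trim_fraction < 0.5`.
#'
#' @param path Path to a GFF3 file (1-based inclusive coordinates).
#' @param feature_type GFF3 type column value to keep (default `"gene"`).
#' @param id_attributes Attribute keys tried in order for the gene
#'   identifier (default `locus_tag`, then `ID`).
#' @param trim_fraction Fraction of the gene length trimmed from each end,
#'   in `[0, 0.5)`. Default 0.10 (the central 80% is analysed).
#' @return A data.frame of gene models: `gene_id`, `replicon`, `start`,
#'   `end`, `strand` (`"forward"`/`"reverse"`), `length`, `central_start`,
#'   `central_end`, `effective_length`.
#' @export
read_genes <- function(path, feature_type = "gene",
                       id_attributes = c("locus_tag", "ID"),
                       trim_fraction = 0.10) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  stopifnot(length(trim_fraction) == 1L, trim_fraction >= 0,
            trim_fraction < 0.5)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("malformed GFF3 '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  gr <- gr[as.character(gr$type) == feature_type]
  if (length(gr) == 0L)
    stop("no '", feature_type, "' features in ", path)
  mc <- S4Vectors::mcols(gr)
  ids <- rep(NA_character_, length(gr))
  for (attr in id_attributes) {
    if (attr %in% names(mc)) {
      v <- as.character(mc[[attr]])
      ids[is.na(ids) & !is.na(v)] <- v[is.na(ids) & !is.na(v)]
    }
  }
  if (anyNA(ids)) {
    bad <- which(is.na(ids))[1L]
    stop("feature ", as.character(GenomicRanges::seqnames(gr))[bad], ":",
         GenomicRanges::start(gr)[bad], "-", GenomicRanges::end(gr)[bad],
         " has none of the id attributes: ",
         paste(id_attributes, collapse = ", "))
  }
  std <- as.character(GenomicRanges::strand(gr))
  genes <- data.frame(
    gene_id  = ids,
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start    = GenomicRanges::start(gr),
    end      = GenomicRanges::end(gr),
    strand   = ifelse(std == "-", "reverse", "forward"),
    stringsAsFactors = FALSE)
  trim_gene_models(genes, trim_fraction)
}

#' Compute trimmed central intervals for gene models
#'
#' @param genes data.frame with `start` and `end` (1-based inclusive).
#' @param trim_fraction Fraction trimmed per end, in `[0, 0.5)`.
#' @return `genes` with `length`, `central_start`, `central_end` and
#'   `effective_length` columns added or recomputed.
#' @export
trim_gene_models <- function(genes, trim_fraction = 0.10) {
  stopifnot(all(genes$start <= genes$end))
  len <- genes$end - genes$start + 1
  trim <- floor(trim_fraction * len)
  genes$length <- len
  genes$central_start <- genes$start + trim
  genes$central_end <- genes$end - trim
  genes$effective_length <- len - 2 * trim
  genes
}

## --- alignment dialects ------------------------------------------------

# Column maps for the three legacy alignment text dialects. Positions are
# converted to a 1-based leftmost coordinate on input; bowtie reports
# 0-based offsets, SOAP and Eland 1-based positions.
dialect_defaults <- list(
  bowtie = list(name = 1L, strand = 2L, replicon = 3L, position = 4L,
                seq = 5L, position_base = 0L,
                strand_forward = "+", strand_reverse = "-",
                length_from = "seq"),
  soap   = list(name = 1L, seq = 2L, length = 6L, strand = 7L,
                replicon = 8L, position = 9L, position_base = 1L,
                strand_forward = "+", strand_reverse = "-",
                length_from = "column"),
  eland  = list(name = 1L, replicon = 7L, position = 8L, strand = 9L,
                position_base = 1L,
                strand_forward = "F", strand_reverse = "R",
                length_from = "config")
)

#' Read aligned transposon-junction reads
#'
#' Parses one of the three legacy alignment text dialects into a uniform
#' 1-based representation. Unparseable lines are skipped with a warning;
#' if more than `max_skip_fraction` of lines fail, the file is assumed to
#' be in the wrong dialect and an error is raised.
#'
#' @param path Path to the alignment file.
#' @param dialect `"bowtie"` (default), `"soap"` or `"eland"`.
#' @param columns Named list overriding the dialect's default column map
#'   (see Details).
#' @param read_length Aligned length used for the eland dialect, which does
#'   not report the sequence (default 50).
#' @param genome Optional `tn_genome`; when given, reads on unknown
#'   replicons or extending past a replicon end are skipped (and counted)
#'   like any other malformed line.
#' @param max_skip_fraction Skipped-line fraction above which parsing
#'   aborts (default 0.1).
#' @details Default column maps (tab-separated, 1-based column numbers):
#'   bowtie — name 1, strand 2 (`+`/`-`), reference 3, 0-based offset 4,
#'   sequence 5; SOAP — name 1, sequence 2, aligned length 6, strand 7,
#'   reference 8, 1-based position 9; Eland export — name 1, reference 7,
#'   1-based position 8, strand 9 (`F`/`R`).
#' @return A data.frame of aligned reads: `name`, `replicon`, `strand`
#'   (`"forward"`/`"reverse"`), `leftmost` (1-based), `aligned_length`,
#'   with attribute `skipped` = number of discarded lines.
#' @export
read_alignments <- function(path, dialect = c("bowtie", "soap", "eland"),
                            columns = NULL, read_length = 50L,
                            genome = NULL, max_skip_fraction = 0.1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  spec <- dialect_defaults[[dialect]]
  if (!is.null(columns)) spec <- modifyList(spec, columns)

  dt <- tryCatch(
    suppressWarnings(   # an empty file is a legitimate empty stream
      data.table::fread(path, sep = "\t", header = FALSE, quote = "",
                        fill = TRUE, colClasses = "character",
                        showProgress = FALSE)),
    error = function(e) NULL)
  empty <- data.frame(name = character(), replicon = character(),
                      strand = character(), leftmost = numeric(),
                      aligned_length = numeric(), stringsAsFactors = FALSE)
  if (is.null(dt) || nrow(dt) == 0L) {
    attr(empty, "skipped") <- 0L
    return(empty)
  }

  need <- max(spec$position, spec$strand, spec$replicon, spec$name,
              if (spec$length_from == "seq") spec$seq else 0L,
              if (spec$length_from == "column") spec$length else 0L)
  n <- nrow(dt)
  col <- function(i) if (i <= ncol(dt)) dt[[i]] else rep(NA_character_, n)

  nm <- col(spec$name)
  rep_ <- col(spec$replicon)
  strand_raw <- col(spec$strand)
  pos <- suppressWarnings(as.numeric(col(spec$position)))
  alen <- switch(spec$length_from,
    seq    = as.numeric(nchar(col(spec$seq))),
    column = suppressWarnings(as.numeric(col(spec$length))),
    config = rep(as.numeric(read_length), n))

  strand <- rep(NA_character_, n)
  strand[strand_raw == spec$strand_forward] <- "forward"
  strand[strand_raw == spec$strand_reverse] <- "reverse"

  leftmost <- pos + (1L - spec$position_base)
  ok <- !is.na(strand) & !is.na(leftmost) & leftmost >= 1 &
    !is.na(alen) & alen >= 1 & !is.na(rep_) & rep_ != ""
  if (!is.null(genome)) {
    rl <- setNames(genome$replicons$length, genome$replicons$name)
    lim <- rl[rep_]
    ok <- ok & !is.na(lim) & (leftmost + alen - 1 <= lim)
  }

  skipped <- sum(!ok)
  if (skipped > 0) {
    if (skipped / n > max_skip_fraction)
      stop(sprintf(
        "%d of %d lines in '%s' failed to parse as %s (> %.0f%%); wrong dialect?",
        skipped, n, path, dialect, 100 * max_skip_fraction))
    warning(sprintf("skipped %d unparseable line(s) in '%s'", skipped, path))
  }

  out <- data.frame(name = nm[ok], replicon = rep_[ok], strand = strand[ok],
                    leftmost = leftmost[ok], aligned_length = alen[ok],
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

## --- WIG and tables ----------------------------------------------------

#' Write insertion data as a WIG (wiggle) track
#'
#' Emits one `variableStep` block per replicon (span 1) with one
#' "position value" line per insertion site, positions ascending, suitable
#' for any genome browser.
#'
#' @param sites Insertion-site data.frame (`replicon`, `position`,
#'   `read_count`).
#' @param genome `tn_genome` the sites belong to (fixes block order and
#'   validates replicon names).
#' @param path Output file.
#' @param value `"reads"` writes the per-site read count, `"insertions"`
#'   writes a constant 1 per site.
#' @param name Track name written in the track header line.
#' @return `path`, invisibly.
#' @export
write_wig <- function(sites, genome, path, value = c("reads", "insertions"),
                      name = "tnseq") {
  value <- match.arg(value)
  bad <- setdiff(unique(sites$replicon), genome$replicons$name)
  if (length(bad))
    stop("site(s) on unknown replicon: ", paste(bad, collapse = ", "))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf('track type=wiggle_0 name="%s"', name), con)
  for (chr in genome$replicons$name) {
    s <- sites[sites$replicon == chr, , drop = FALSE]
    if (nrow(s) == 0L) next
    s <- s[order(s$position), , drop = FALSE]
    v <- if (value == "reads") s$read_count else rep(1, nrow(s))
    writeLines(c(sprintf("variableStep chrom=%s span=1", chr),
                 paste(format(s$position, scientific = FALSE, trim = TRUE),
                       format(v, scientific = FALSE, trim = TRUE))), con)
  }
  invisible(path)
}

#' Read a variableStep WIG track back into a site table
#'
#' Inverse of [write_wig()] for span-1 variableStep tracks; used for
#' round-trip checks and for re-importing browser tracks.
#'
#' @param path WIG file.
#' @return data.frame with `replicon`, `position`, `value`.
#' @export
read_wig <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^track", lines) & nzchar(lines)]
  is_head <- grepl("^variableStep", lines)
  if (!any(is_head) && length(lines))
    stop("no variableStep block in ", path)
  chr <- rep(NA_character_, length(lines))
  chr[is_head] <- sub('.*chrom=([^ ]+).*', '\\1', lines[is_head])
  chr <- cumsum_fill(chr)
  dat <- lines[!is_head]
  chr <- chr[!is_head]
  parts <- strsplit(dat, "[ \t]+")
  data.frame(
    replicon = chr,
    position = as.numeric(vapply(parts, `[`, "", 1L)),
    value = as.numeric(vapply(parts, `[`, "", 2L)),
    stringsAsFactors = FALSE)
}

# carry last non-NA value forward
cumsum_fill <- function(x) {
  idx <- cummax(ifelse(is.na(x), 0L, seq_along(x)))
  out <- x[idx]
  out[idx == 0L] <- NA_character_
  out
}

#' Write a per-gene results table
#'
#' Tab-delimited with a header row, one row per gene, preserving the input
#' (annotation) gene order. P-value columns (names starting `p_`, `fwer_`
#' or `adjp_`) are serialized in scientific notation with 7 significant
#' digits so the table round-trips to that precision.
#'
#' @param results A data.frame as returned by [one_sample_analysis()] or
#'   [two_sample_analysis()].
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  stopifnot(nrow(results) > 0L)
  out <- as.data.frame(results)
  pcols <- grep("^(p_|fwer_|adjp_)", names(out), value = TRUE)
  for (cn in pcols) {
    v <- out[[cn]]
    fmt <- formatC(v, digits = 6, format = "e")
    fmt[is.na(v)] <- "NA"
    out[[cn]] <- fmt
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path TSV file.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read the intermediate insertion-site table
#'
#' TSV with columns `replicon`, `position`, `read_count`; the same data
#' that feeds the WIG tracks.
#'
#' @param sites Site data.frame.
#' @param path TSV file.
#' @return `path` (write) or the site data.frame (read).
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites[, c("replicon", "position", "read_count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "numeric", "numeric"))
}
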