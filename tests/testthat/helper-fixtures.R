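# Tiny in-code fixtures for the I/O layer.

write_fasta_fixture <- function(records, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(lapply(names(records), function(h) {
    c(paste0(">", h), records[[h]])
  }))
  writeLines(lines, path)
  path
}

# genes: data.frame with replicon, start, end, strand ("+"/"-"), attrs
write_gff3_fixture <- function(genes, path = tempfile(fileext = ".gff3"),
                               type = "gene") {
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     genes$replicon, type, genes$start, genes$end,
                     genes$strand, genes$attrs))
  writeLines(lines, path)
  path
}

bowtie_line <- function(name, strand, chr, offset0, len = 50) {
  paste(name, strand, chr, offset0, strrep("A", len), strrep("I", len), 0,
        sep = "\t")
}

soap_line <- function(name, strand, chr, pos1, len = 50) {
  paste(name, strrep("A", len), strrep("I", len), 1, "a", len, strand, chr,
        pos1, sep = "\t")
}

eland_line <- function(name, strand, chr, pos1) {
  paste(name, strrep("A", 50), "U0", 1, 0, 0, chr, pos1, strand,
        sep = "\t")
}

write_lines_fixture <- function(lines, path = tempfile()) {
  writeLines(lines, path)
  path
}

# a small genome index without touching the FASTA reader
toy_genome <- function(names = "chrA", lengths = 1e5) {
  structure(list(
    replicons = data.frame(name = names, length = as.numeric(lengths),
                           stringsAsFactors = FALSE),
    total_length = sum(as.numeric(lengths))),
    class = "tn_genome")
}

toy_sites <- function(position, read_count, replicon = "chrA") {
  data.frame(replicon = rep(replicon, length.out = length(position)),
             position = as.numeric(position),
             read_count = as.numeric(read_count),
             stringsAsFactors = FALSE)
}

toy_library_summary <- function(avg_norm_insertions, p = 0.03,
                                genome_length = 1e5) {
  structure(list(
    total_insertions = round(p * genome_length),
    total_mapped_reads = 1e5,
    genome_length = genome_length,
    insertion_probability = p,
    density = 1 / p,
    avg_norm_insertions = avg_norm_insertions,
    n_genes = NA_integer_),
    class = "tn_library_summary")
}
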