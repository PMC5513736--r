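test_that("FASTA reading keeps names and lengths", {
  fa <- write_fasta_fixture(list(
    "chr1 main chromosome" = strrep("ACGT", 25),       # 100 bp
    "p1" = strrep("AC", 25)))                          # 50 bp
  g <- read_genome(fa)
  expect_equal(g$replicons$name, c("chr1", "p1"))
  expect_equal(g$replicons$length, c(100, 50))
  expect_equal(g$total_length, 150)

  # interleaved line widths concatenate
  fa2 <- write_fasta_fixture(list(x = c(strrep("A", 60), strrep("C", 13))))
  expect_equal(read_genome(fa2)$total_length, 73)
})

test_that("FASTA errors name the offending record", {
  fa <- write_fasta_fixture(list(ok = "ACGT", bad = ""))
  expect_error(read_genome(fa), "bad")
  expect_error(read_genome(tempfile()), "not found")
})

test_that("GFF3 gene models get floor-trimmed central intervals", {
  gff <- write_gff3_fixture(data.frame(
    replicon = "chrA", start = c(1L, 11L, 2001L), end = c(1000L, 20L, 3000L),
    strand = c("+", "-", "+"),
    attrs = c("ID=g1;locus_tag=LT_0001", "ID=g2;locus_tag=LT_0002",
              "ID=g3;locus_tag=LT_0003")))
  genes <- read_genes(gff, trim_fraction = 0.10)
  expect_equal(genes$gene_id, c("LT_0001", "LT_0002", "LT_0003"))
  # 1..1000: floor(0.1*1000)=100 trimmed per end
  expect_equal(genes$central_start[1], 101)
  expect_equal(genes$central_end[1], 900)
  expect_equal(genes$effective_length[1], 800)
  # 10 bp gene: floor(1) per end
  expect_equal(c(genes$central_start[2], genes$central_end[2]), c(12, 19))
  expect_equal(genes$strand[2], "reverse")
  # trim 0 is the identity
  g0 <- read_genes(gff, trim_fraction = 0)
  expect_equal(g0$central_start, g0$start)
  expect_equal(g0$central_end, g0$end)
  expect_equal(g0$effective_length, g0$length)
})

test_that("GFF3 feature type and id attribute selection work", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrA\tt\tgene\t1\t100\t.\t+\t.\tID=g1;locus_tag=LT1",
    "chrA\tt\tCDS\t1\t90\t.\t+\t.\tID=c1",
    "chrA\tt\tgene\t200\t300\t.\t+\t.\tID=g2"), path)
  genes <- read_genes(path)
  expect_equal(nrow(genes), 2L)           # CDS dropped
  expect_equal(genes$gene_id, c("LT1", "g2"))  # locus_tag first, ID fallback
  genes_id <- read_genes(path, id_attributes = "ID")
  expect_equal(genes_id$gene_id, c("g1", "g2"))
  expect_error(read_genes(path, id_attributes = "Name"), "id attributes")
  expect_error(read_genes(path, feature_type = "tRNA"), "no 'tRNA'")
})

test_that("bowtie offsets shift to 1-based; SOAP/Eland already 1-based", {
  bt <- write_lines_fixture(bowtie_line("r1", "+", "chrA", 1000))
  r <- read_alignments(bt, "bowtie")
  expect_equal(r$leftmost, 1001)
  expect_equal(r$strand, "forward")
  expect_equal(r$aligned_length, 50)

  so <- write_lines_fixture(soap_line("r1", "-", "chrA", 1001))
  r2 <- read_alignments(so, "soap")
  expect_equal(r2$leftmost, 1001)
  expect_equal(r2$strand, "reverse")

  el <- write_lines_fixture(eland_line("r1", "F", "chrA", 501))
  r3 <- read_alignments(el, "eland", read_length = 36)
  expect_equal(r3$leftmost, 501)
  expect_equal(r3$aligned_length, 36)
  expect_equal(r3$strand, "forward")
})

test_that("the same alignment in bowtie and SOAP dialects is identical", {
  bt <- write_lines_fixture(bowtie_line("r1", "+", "chrA", 1000, len = 50))
  so <- write_lines_fixture(soap_line("r1", "+", "chrA", 1001, len = 50))
  a <- read_alignments(bt, "bowtie")
  b <- read_alignments(so, "soap")
  attr(a, "skipped") <- attr(b, "skipped") <- NULL
  expect_identical(a, b)
})

test_that("unparseable lines are skipped, counted, and bounded", {
  good <- vapply(1:20, function(i)
    bowtie_line(paste0("r", i), "+", "chrA", 100 + i), "")
  f <- write_lines_fixture(c(good, "garbage line"))
  expect_warning(r <- read_alignments(f, "bowtie"), "skipped 1")
  expect_equal(nrow(r), 20L)
  expect_equal(attr(r, "skipped"), 1L)

  f2 <- write_lines_fixture(c(good[1:3], "junk1\tx", "junk2\tx"))
  expect_error(read_alignments(f2, "bowtie"), "wrong dialect")

  # empty file is an empty stream with zero skipped
  f3 <- write_lines_fixture(character())
  r3 <- read_alignments(f3, "bowtie")
  expect_equal(nrow(r3), 0L)
  expect_equal(attr(r3, "skipped"), 0L)
})

test_that("malformed input never yields out-of-range coordinates", {
  g <- toy_genome("chrA", 2000)
  set.seed(11)
  lines <- c(
    vapply(1:50, function(i)
      bowtie_line(paste0("r", i), sample(c("+", "-"), 1), "chrA",
                  sample(0:1950, 1)), ""),
    bowtie_line("over", "+", "chrA", 1990),      # runs past the end
    bowtie_line("neg", "+", "chrA", -12),
    bowtie_line("unknown", "+", "chrB", 10),
    "total garbage", "a\tb\tc")
  f <- write_lines_fixture(lines)
  suppressWarnings(r <- read_alignments(f, "bowtie", genome = g))
  expect_true(all(r$leftmost >= 1))
  expect_true(all(r$leftmost + r$aligned_length - 1 <= 2000))
  expect_equal(attr(r, "skipped"), 5L)
})

test_that("WIG output is blockwise, ascending, and round-trips", {
  g <- toy_genome(c("chrA", "chrB"), c(1000, 500))
  sites <- rbind(toy_sites(c(9, 5), c(40, 12)), toy_sites(33, 7, "chrB"))
  path <- tempfile(fileext = ".wig")
  write_wig(sites, g, path, value = "reads")
  lines <- readLines(path)
  expect_equal(lines[2], "variableStep chrom=chrA span=1")
  expect_equal(lines[3:4], c("5 12", "9 40"))  # ascending positions
  back <- read_wig(path)
  expect_equal(back[order(back$replicon, back$position), ]$value,
               c(12, 40, 7))

  # insertions track writes constant 1
  write_wig(sites, g, path, value = "insertions")
  expect_true(all(read_wig(path)$value == 1))

  # empty site list: header-only file
  write_wig(toy_sites(numeric(), numeric()), g, path)
  expect_equal(length(readLines(path)), 1L)

  expect_error(write_wig(toy_sites(1, 1, "nope"), g, path),
               "unknown replicon")
})

test_that("results tables round-trip with scientific-notation P values", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    insertions_central = c(0, 3, 17),
                    p_essential = c(3.14159265e-12, 0.5, 1),
                    fwer_essential = c(6.28318531e-9, 1, 1))
  path <- tempfile(fileext = ".tsv")
  write_results_table(res, path)
  lines <- readLines(path)
  expect_equal(length(lines), 4L)  # header + 3 rows
  expect_match(lines[2], "3\\.141593e-12")
  back <- read_results_table(path)
  expect_equal(back$p_essential, res$p_essential, tolerance = 1e-6)
  expect_equal(back$gene_id, res$gene_id)
  expect_error(write_results_table(res[0, ], path))
})

test_that("site tables round-trip exactly", {
  sites <- toy_sites(c(5, 900, 12345), c(10, 2, 99))
  path <- tempfile(fileext = ".tsv")
  write_site_table(sites, path)
  expect_identical(read_site_table(path), sites)
})
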