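Package: tnseqr
Title: Essential Gene Analysis for Transposon Insertion Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A workflow for analysing transposon insertion sequencing
    (Tn-seq) libraries, from aligned transposon-junction reads to
    statistically ranked essential and conditionally essential gene calls.
    Reads legacy Bowtie, SOAP and Eland alignment text, FASTA genomes and
    GFF3 gene models; maps junction reads to unique insertion sites with a
    minimum-read threshold; corrects PCR-jackpot bias by read capping and
    insertion-based read weighting; tests per-gene insertion deficits
    against a genome-wide binomial null (one-sample analysis) and read
    depletion between conditions by normalized fold change with Fisher,
    two-proportion and replicate t tests (two-sample analysis); applies
    Bonferroni and Benjamini-Hochberg corrections; writes WIG tracks and
    tab-delimited result tables. A built-in Tn5 library simulator with
    ground truth makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
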