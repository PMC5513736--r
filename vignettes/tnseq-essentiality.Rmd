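---
title: "Calling essential and conditionally essential genes from Tn-seq data"
author: "tnseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling essential and conditionally essential genes from Tn-seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnseqr)
```

## The measurement and its model

Transposon insertion sequencing (Tn-seq) pools tens of thousands of
transposon mutants, sequences the transposon/genome junctions, and asks
which loci tolerate disruption. `tnseqr` implements the analysis path
from aligned junction reads to per-gene statistical calls for a Tn5-style
library (near-random insertion, suitable for high-GC genomes where
TA-specific mariner transposons cannot be used).

The pipeline has four stages.

1. **Site mapping.** Each aligned read is reduced to its junction
   coordinate: the first aligned base, i.e. the leftmost base of a
   forward alignment and the rightmost base of a reverse alignment. The
   sequencing primer reads outward from the transposon end, so this is a
   geometric fact about the assay, not a convention; the simulator and
   the parser are tested against each other to pin it down. Sites are
   collapsed across strands, since disruption is a property of the
   position. A site only counts as a *unique insertion* if it carries at
   least `min_hits` reads (default 10) — fewer reads are treated as
   noise (index hopping, mapping error), and the threshold is applied
   before **every** downstream quantity, including the genome-wide
   insertion probability.

2. **Gene tallies.** Genes come from a GFF3 annotation; 10% of each
   gene's length (`trim_fraction = 0.10`, floor-rounded per end) is
   trimmed from both ends, because insertions near the termini often
   leave function intact. Statistics use the central interval's
   insertion count and its length. Trimming by `floor` keeps the central
   interval nonempty for every `trim_fraction < 0.5`; a gene that still
   ends up with zero effective length would be reported `untestable`
   rather than silently dropped.

3. **Bias corrections.** PCR jackpots inflate read counts at single
   sites, so per-site counts can be capped at a library-derived bound
   (mean + 2 population SDs of reads per site by default; mean or median
   as alternatives). Because the number of distinct insertions a gene
   tolerates is a stronger signal than its read total, gene read totals
   can additionally be *weighted* by relative insertion density:
   `reads * density(gene) / mean density over genes`, where density is
   central insertions per central bp. Capping acts on sites first, then
   tallies are aggregated, then weighting acts on gene totals. In
   two-library comparisons each library gets its own cap, since each has
   its own jackpot structure.

4. **Statistics** — the one- and two-sample analyses below, each
   followed by Bonferroni (FWER) and Benjamini–Hochberg (FDR)
   adjustments across all tested genes.

## One-sample analysis: essentiality against a uniform null

If insertions hit every base pair with equal probability
`p = (unique insertions) / (genome length)`, the number of unique
insertions in `n` base pairs is `X ~ Binomial(n, p)`. For each gene with
`k` central insertions over `n` effective bp we report the lower tail
`P(X <= k)` (essentiality: fewer insertions than the gene's length
predicts) and the upper tail `P(X >= k)` (improved fitness: more than
expected). The binomial length model is what keeps *small* genes honest:
at a density of one insertion per 30 bp, a 100-bp gene is quite likely
empty by chance, and its lower-tail probability says so. Note that
`P(X >= k)` is computed as `1 - P(X <= k - 1)`, keeping the `P(X = k)`
term in the upper tail; for `k = 0` it is exactly 1.

A gene is called **essential** when its essentiality FWER is below 0.01
*and* it has fewer than 4 unique central insertions. The insertion gate
is a buffer against insertions that slip into the central interval
without abolishing function; the strict `<` reading is the default, a
`<=` variant is available (`inclusive = TRUE`). Significant genes failing
the gate are `reduced_fitness`; genes significant in the upper tail are
`improved_fitness`.

Tails are computed with the regularized incomplete beta function
(`pbinom`), which is stable for gene- and genome-scale `n`; the test
suite verifies agreement with an arbitrary-precision-style log-space PMF
summation to below 1e-10 absolute over a grid spanning `n` up to 1e5 and
`p` down to 1e-4.

## Two-sample analysis: conditional essentiality

With a treatment library (grown under selection, e.g. ~7 doublings in a
minimal medium) and a reference library, each gene's bias-corrected read
total is normalized by its library's total over genes and compared as a
fold change:

```
FC_i = ((reads_treat_i + 1) / total_treat) / ((reads_ref_i + 1) / total_ref)
```

The pseudocount of one read keeps the ratio finite — genes that are
conditionally essential routinely have *zero* treatment reads — and is
applied only in the fold change, never in the significance tests, which
use the raw (rounded, if weighted) integer counts. The log fold change is
log2; the default call threshold of -2 means 16-fold depletion.

Significance comes from three tests per gene: Fisher's exact test on the
2x2 table [gene reads, rest-of-library reads] x [treatment, reference];
a pooled-variance two-proportion z-test (no continuity correction)
applied to read counts and, separately, to central insertion counts; and
a Welch t-test on per-replicate normalized gene fractions when both
conditions have at least two replicates. Each P-value family is BH
adjusted across genes. The default call gate is the insertion-proportion
test: a gene is `depleted` when `log2FC < -2` and its BH-adjusted
insertion-proportion P is below 0.05, and `conditionally_essential` when
it additionally has fewer than 4 central insertions left in the
treatment library; the mirror-image `enriched` call uses `log2FC > 2`.

## The simulator: what it emulates, and what it does not

`sim_config()` / `simulate_genome()` / `simulate_library()` /
`simulate_outgrowth()` generate a complete desk-scale experiment with
ground truth, serialized in the exact formats the pipeline consumes
(FASTA, GFF3, legacy Bowtie text). Defaults describe a Tn5 mutagenesis
of a high-GC bacterial chromosome:

| parameter | default | meaning |
|---|---|---|
| `genome_length` | 3e6 bp | one circular-chromosome-sized replicon |
| `gc_fraction` | 0.69 | i.i.d. base composition |
| `n_genes` | 2000 | non-overlapping genes, log-normal lengths, median ~900 bp |
| `essential_fraction` | 0.10 | genes whose central interval admits no insertion |
| `insertion_density` | 1/25 per bp | *true* site rate; see note below |
| `reads_per_site_mean` | 50 | shifted-geometric (min 1) reads per site |
| `jackpot_fraction`, `jackpot_multiplier` | 0.01, 100 | PCR jackpot sites |
| `read_length` | 50 bp | emitted junction reads |
| `doublings` | 7 | outgrowth generations |

A note on density: library summaries report *unique-insertion* density —
genome length over the number of sites with at least 10 reads. With
mean-50 geometric reads, a fraction `(1 - 1/50)^9 = 0.834` of true sites
survives the 10-read threshold, so the default true rate of 1/25 bp
realizes a reported density of about one unique insertion per 30 bp,
comparable to a dense real Tn5 library. Essential genes receive no
central insertions but their trimmed ends are mutagenized at the normal
rate — exactly the situation the 10% trim buffer exists for. Outgrowth
multiplies each site's expected reads by `fitness(gene)^doublings`
(intergenic fitness 1; a site under two overlapping genes takes the
stronger selection), renormalizes to the sequencing depth and resamples
the site counts as one multinomial draw: a gene with per-doubling
fitness `2^(-4/7)` is depleted by an expected 4 log2 units after 7
doublings.

The simulator is deliberately idealized. It does **not** model sequence
preference or GC/replication-origin insertion bias (the one-sample null
is exactly true by construction), sequencing error, multi-mapping
ambiguity, or aliquot-style technical replicates (replicate libraries
are independent site draws, not re-sequencings of one master pool).
Passing recovery tests therefore demonstrates the statistical machinery
and bookkeeping, not robustness to biases the generator never produces.

## Validation studies and their problem sizes

The test suite and `scripts/acceptance.R` run two seeded recovery
studies, sized to finish in minutes on one core:

* **One-sample recovery** — default configuration (3 Mb, 2000 genes, 10%
  essential). Calls at FWER < 0.01 with < 4 central insertions recover
  essentially all essential genes of effective length >= 600 bp with
  precision near 1, and an all-neutral null library yields essentially
  no essential calls (the Bonferroni gate guarantees the rate is far
  below 1%).

* **Two-sample recovery** — 200 genes at 16-fold expected depletion,
  five seeds. Measured detection at the default gates is ~0.88–0.89 with
  zero observed false discoveries, and the median log2 fold change of
  depleted genes (computed on raw normalized reads, without the site
  threshold) sits at about -3.8, i.e. the injected -4 effect minus the
  renormalization shift from the rest of the library. The missing
  detection has a concrete cause worth knowing about: with heavy-tailed
  (geometric) reads per site, a 16-fold-depleted site keeps >= 10 reads
  whenever its pre-selection count was large (probability roughly
  0.06–0.09 per site), so a mid-sized depleted gene typically retains
  1–3 "surviving" insertions. A two-sided proportion test on, say, 2
  surviving vs 24 reference insertions gives a raw P around 0.02–0.05,
  which does not always clear the BH cutoff. Depletion measured on
  *reads* (Fisher or the read-proportion test) flags these genes
  unambiguously; the insertion-based gate is the more conservative
  default because it is immune to amplification artifacts.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout (GFF3 convention);
  Bowtie's 0-based offsets are shifted on input. SOAP and Eland column
  layouts vary between pipeline versions, so the column maps are
  configurable with documented defaults; unparseable lines are skipped
  and counted, and more than 10% of them aborts parsing as a
  wrong-dialect guard.
* The cap statistic uses the population (n-divisor) standard deviation —
  a descriptive summary of the full site population, not an estimate
  from a sample.
* Weighted read totals stay real-valued and are rounded half-up only
  where a count test (Fisher, proportions) needs integers.
* Insertion density for weighting uses the central interval, consistent
  with the statistics computed on it.
* Degenerate inputs have defined behaviour: a pooled proportion of 0 or
  1 yields P = 1 (no evidence); constant replicate vectors yield P = 1
  at equal means; an empty site list is an error at the library-summary
  stage (the library is unusable), but an empty alignment file parses to
  an empty stream.
* All simulator stages draw from streams derived from one integer seed,
  so a configuration is reproducible byte-for-byte, and the CLI writes a
  manifest (parameters, dialect maps, input MD5 checksums, version) from
  which any output can be regenerated.

## Limitations

* The one-sample null assumes uniform insertion; it is not suitable for
  site-specific transposons (e.g. mariner's TA requirement), where
  per-gene insertion opportunity must replace raw length.
* Slow-growing mutants deplete like essential ones over an outgrowth;
  calls are about fitness under the assayed condition, not molecular
  indispensability.
* The Fisher and proportion tests treat reads as independent draws,
  which understates variance for jackpot-prone libraries; the
  insertion-based gate and the capping/weighting corrections are the
  mitigations offered.
* Intergenic regions and sub-gene essential domains are out of scope;
  tallies are per annotated gene.
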