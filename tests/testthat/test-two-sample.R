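test_that("fold change normalizes by library totals with a pseudocount", {
  eq <- fold_change(100, 1e4, 200, 2e4, pseudocount = 0)
  expect_equal(eq$fc, 1)
  expect_equal(eq$log2fc, 0)

  fc <- fold_change(31, 1e6, 511, 1e6)
  expect_equal(fc$fc, 1 / 16)
  expect_equal(fc$log2fc, -4)

  # the pseudocount floors genes with zero treatment reads
  z <- fold_change(0, 1e6, 1023, 1e6)
  expect_equal(z$fc, 1 / 1024)
  expect_equal(z$log2fc, -10)

  expect_error(fold_change(1, 0, 1, 10), "positive")
})

test_that("Fisher exact P matches the enumeration oracle and is symmetric", {
  # identical proportions carry no signal
  expect_equal(fisher_test(10, 990, 20, 1980), 1)
  expect_equal(fisher_test(1, 9, 11, 3),
               oracle_fisher_two_sided(1, 9, 11, 3), tolerance = 1e-12)
  expect_equal(fisher_test(1, 9, 11, 3), 2.759e-3, tolerance = 1e-3)
  # transposing the table leaves P unchanged
  expect_equal(fisher_test(7, 2, 5, 11), fisher_test(7, 5, 2, 11))
  expect_error(fisher_test(-1, 2, 3, 4), "nonnegative")
})

test_that("pooled two-proportion z-test matches hand formula and prop.test", {
  eq <- proportions_test(30, 300, 10, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  # x1=10, x2=40 over 1e6 each: pbar = 2.5e-5, z = -4.2426
  r <- proportions_test(10, 1e6, 40, 1e6)
  pbar <- 2.5e-5
  z_hand <- (1e-5 - 4e-5) / sqrt(pbar * (1 - pbar) * 2e-6)
  expect_equal(r$z, z_hand)
  expect_equal(r$z, -4.2426, tolerance = 1e-4)
  expect_equal(r$p, 2.2e-5, tolerance = 2e-2)
  # chi-square two-proportion test without continuity is the same P
  expect_equal(r$p, prop.test(c(10, 40), c(1e6, 1e6),
                              correct = FALSE)$p.value)

  # swapping samples flips z but not p
  s <- proportions_test(40, 1e6, 10, 1e6)
  expect_equal(s$z, -r$z)
  expect_equal(s$p, r$p)

  # degenerate pooled proportion: no evidence
  expect_equal(proportions_test(0, 100, 0, 50)$p, 1)
  expect_equal(proportions_test(100, 100, 50, 50)$p, 1)
  expect_error(proportions_test(5, 4, 1, 10), "0 <= x <= n")
})

test_that("replicate t-test needs replicates and matches the Welch formula", {
  expect_true(is.na(replicate_ttest(1, c(1, 2))))
  expect_equal(replicate_ttest(c(1, 2, 3) * 1e-6, c(1, 2, 3) * 1e-6), 1)
  expect_equal(replicate_ttest(c(2, 2), c(2, 2)), 1)
  expect_equal(replicate_ttest(c(2, 2), c(3, 3)), 0)

  a <- c(1, 1.1, 0.9) * 1e-6
  b <- c(2, 2.1, 1.9) * 1e-6
  se <- sqrt(var(a) / 3 + var(b) / 3)
  tstat <- (mean(a) - mean(b)) / se
  df <- (var(a) / 3 + var(b) / 3)^2 /
    ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(replicate_ttest(a, b), 2 * pt(-abs(tstat), df))
})

test_that("self-comparison yields zero discoveries", {
  cfg <- sim_config(seed = 903, genome_length = 2e5, n_genes = 120)
  sg <- simulate_genome(cfg)
  sl <- simulate_library(sg)
  res <- two_sample_analysis(sl$sites, sl$sites, sg$genes, sg$genome)
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$p_fisher > 1 - 1e-9))  # exact-test float roundoff
  expect_true(all(res$p_prop_reads == 1))
  expect_true(all(res$p_prop_insertions == 1))
  expect_true(all(res$call == "neutral"))
})

test_that("label swap negates log2fc and maps depleted to enriched", {
  cfg <- sim_config(seed = 904, genome_length = 3e5, n_genes = 180,
                    essential_fraction = 0)
  sg <- simulate_genome(cfg)
  set.seed(21)
  dep <- sample(sg$truth$gene_id, 45)
  fit <- setNames(rep(1, 180), sg$truth$gene_id)
  fit[dep] <- 2^(-4 / 7)
  sl <- simulate_library(sg)
  og <- simulate_outgrowth(sl, sg, fitness = fit)

  fwdr <- two_sample_analysis(og$sites, sl$sites, sg$genes, sg$genome)
  revr <- two_sample_analysis(sl$sites, og$sites, sg$genes, sg$genome)
  expect_equal(revr$log2fc, -fwdr$log2fc)
  expect_equal(revr$p_prop_insertions, fwdr$p_prop_insertions)
  down <- fwdr$call %in% c("depleted", "conditionally_essential")
  expect_true(all(revr$call[down] == "enriched"))
  expect_true(all(fwdr$call[revr$call == "enriched"] %in%
                    c("depleted", "conditionally_essential")))
})

test_that("16-fold simulated depletion shows a ~-4 median log2fc in reads", {
  cfg <- sim_config(seed = 905, genome_length = 6e5, n_genes = 300,
                    essential_fraction = 0)
  sg <- simulate_genome(cfg)
  set.seed(33)
  dep <- sample(sg$truth$gene_id, 100)
  fit <- setNames(rep(1, 300), sg$truth$gene_id)
  fit[dep] <- 2^(-4 / 7)
  sl <- simulate_library(sg)
  og <- simulate_outgrowth(sl, sg, fitness = fit)
  # pure read depletion: no site threshold, no capping, no weighting
  res <- two_sample_analysis(og$sites, sl$sites, sg$genes, sg$genome,
                             min_hits = 1, capping = "none",
                             weighting = FALSE)
  expect_equal(median(res$log2fc[res$gene_id %in% dep]), -4,
               tolerance = 0.125)  # within +/- 0.5 on an absolute scale
  expect_equal(median(res$log2fc[!res$gene_id %in% dep]), 0,
               tolerance = 0.5)
})

test_that("conditional-essentiality calls follow the three gates", {
  base <- data.frame(
    log2fc = c(-3, -3, -1.5, 3, -3),
    adjp_prop_insertions = c(0.01, 0.01, 0.001, 0.01, 0.2),
    insertions_central_treat = c(1, 7, 0, 30, 0))
  out <- classify_conditional(base)
  expect_equal(out$call,
               c("conditionally_essential",  # all gates met
                 "depleted",                 # 7 central insertions remain
                 "neutral",                  # fold-change gate fails
                 "enriched",
                 "neutral"))                 # significance gate fails
  expect_error(classify_conditional(base, statistic = "wilcoxon"),
               "unknown")
})

test_that("replicates feed summed counts and a t-test column", {
  cfg <- sim_config(seed = 906, genome_length = 1.5e5, n_genes = 80)
  sg <- simulate_genome(cfg)
  reps_t <- lapply(3:4, function(o) simulate_library(sg, seed_offset = o)$sites)
  reps_r <- lapply(5:6, function(o) simulate_library(sg, seed_offset = o)$sites)
  res <- two_sample_analysis(reps_t, reps_r, sg$genes, sg$genome)
  expect_false(all(is.na(res$p_ttest)))
  expect_true(all(res$p_ttest >= 0 & res$p_ttest <= 1, na.rm = TRUE))
  # independent draws of the same null library: no discoveries
  expect_true(all(res$call == "neutral"))
})
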