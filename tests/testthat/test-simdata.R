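test_that("simulate_counts is bitwise reproducible from its seed", {
  cfg <- sim_config(n_genes = 200, seed = 42)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_counts(sim_config(n_genes = 200, seed = 43))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("degenerate all-conserved mixture plants no effects", {
  cfg <- sim_config(n_genes = 100, category_proportions = c(conserved = 1), seed = 3)
  tr <- simulate_counts(cfg)$truth
  expect_true(all(tr$cis_log2 == 0))
  expect_true(all(tr$trans_log2 == 0))
  expect_true(all(tr$category == "conserved"))
})

test_that("planted effects respect the category structure", {
  tr <- sim_fixture(n_genes = 1000, seed = 9)$truth
  expect_true(all(tr$cis_log2[tr$category %in% c("conserved", "trans_only")] == 0))
  expect_true(all(tr$trans_log2[tr$category %in% c("conserved", "cis_only")] == 0))
  expect_true(all(abs(tr$cis_log2[tr$category %in% c("cis_only", "cis_trans")]) >= 1))
  # deterministic apportionment: planted counts are exact
  expect_equal(unname(table(tr$category)[c("conserved", "cis_only", "trans_only", "cis_trans")]),
               c(700, 150, 100, 50), ignore_attr = TRUE)
})

test_that("mean structure: empirical ratios converge to planted effects at high depth", {
  # near-deterministic regime: Poisson noise, baseline 2^19 >> 1e5
  cfg <- sim_config(n_genes = 50, category_proportions = c(cis_only = 1),
                    baseline_log2_mean = 19, baseline_log2_sd = 0,
                    dispersion = 0, cis_effect_log2 = 1, trans_effect_log2 = 0,
                    seed = 5)
  sim <- simulate_counts(cfg)
  ch <- sim$counts$channels
  sf <- sim$size_factors
  r <- ncol(ch$F1_A)
  # undo per-library scaling, then pool
  unscale <- function(name) {
    m <- ch[[name]]
    rowSums(sweep(m, 2, sf[paste0(name, "_rep", seq_len(r))], "/"))
  }
  f1_ratio <- unscale("F1_B") / unscale("F1_A")
  f0_ratio <- unscale("F0_B") / unscale("F0_A")
  expect_true(all(abs(f1_ratio / 2^sim$truth$cis_log2 - 1) < 0.01))
  expect_true(all(abs(f0_ratio / 2^(sim$truth$cis_log2 + sim$truth$trans_log2) - 1) < 0.01))
})

test_that("simulate_reads plants allele counts exactly and conserves reads", {
  tr <- data.frame(gene_id = "g1", cis_log2 = 0)
  rr <- simulate_reads(tr, snps_per_gene = 1, read_length = 60, depth = 100,
                       n_replicates = 1, seed = 2, dir = tempfile())
  expect_equal(unname(rr$truth_counts$A[1, 1]), 50L)
  expect_equal(unname(rr$truth_counts$B[1, 1]), 50L)
  n_lines <- length(readLines(rr$fastq[1]))
  expect_equal(n_lines / 4, sum(rr$truth_counts$A) + sum(rr$truth_counts$B))
})

test_that("simulate_reads with zero depth emits empty FASTQ and zero counts", {
  tr <- data.frame(gene_id = c("g1", "g2"), cis_log2 = c(0, 1))
  rr <- simulate_reads(tr, depth = 0, n_replicates = 2, seed = 1, dir = tempfile())
  expect_true(all(rr$truth_counts$A == 0L) && all(rr$truth_counts$B == 0L))
  expect_equal(length(readLines(rr$fastq[1])), 0L)
})

test_that("simulate_reads rejects a window longer than the read", {
  tr <- data.frame(gene_id = "g1", cis_log2 = 0)
  expect_error(simulate_reads(tr, snps_per_gene = 10, read_length = 20, seed = 1),
               class = "ct_config_error")
})

test_that("null motif fixture is exchangeable; zero length gives zero hits", {
  h <- simulate_motif_hits(50, 50, c("M1", "M2"), planted_motif = "M1",
                           fg_rate_multiplier = 1, bg_hit_rate = 1e-3,
                           seq_len = 2000, seed = 4)
  # multiplier 1: same marginal rate in both sets for every motif
  pooled_rate <- function(df, m) mean(df[[m]])
  for (m in c("M1", "M2")) {
    expect_lt(abs(pooled_rate(h$foreground, m) - pooled_rate(h$background, m)), 1.5)
  }
  h0 <- simulate_motif_hits(10, 10, "M1", bg_hit_rate = 1e-3, seq_len = 0, seed = 1)
  expect_true(all(h0$foreground$M1 == 0) && all(h0$background$M1 == 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(category_proportions = c(conserved = 0.5, cis_only = 0.4)),
               class = "ct_config_error")
  expect_error(sim_config(dispersion = -1), class = "ct_config_error")
  expect_error(sim_config(size_factor_range = c(2, 1)), class = "ct_config_error")
  expect_error(sim_config(n_genes = 0), class = "ct_config_error")
})
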