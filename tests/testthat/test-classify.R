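# classification of pooled-count archetypes through the three exact tests
records_for <- function(f0, f1) {
  data.frame(gene_id = "g",
             p_f0 = binomial_exact_test(f0[1], sum(f0)),
             p_f1 = binomial_exact_test(f1[1], sum(f1)),
             p_ct = as.numeric(fisher_ratio_test(f0, f1)),
             q_f0 = binomial_exact_test(f0[1], sum(f0)),
             q_f1 = binomial_exact_test(f1[1], sum(f1)),
             q_ct = as.numeric(fisher_ratio_test(f0, f1)),
             log2_f0_ratio = log2((f0[2] + 0.5) / (f0[1] + 0.5)),
             log2_f1_ratio = log2((f1[2] + 0.5) / (f1[1] + 0.5)))
}

test_that("archetypal pooled counts are assigned their expected categories", {
  # equal F0 and F1 imbalance -> cis_only (ratios homogeneous)
  expect_equal(as.character(classify_genes(records_for(c(1000, 100), c(500, 50)))$category),
               "cis_only")
  # F0 imbalance, balanced F1, heterogeneous ratios -> trans_only
  expect_equal(as.character(classify_genes(records_for(c(1000, 100), c(500, 500)))$category),
               "trans_only")
  # everything null -> conserved
  expect_equal(as.character(classify_genes(records_for(c(100, 100), c(100, 100)))$category),
               "conserved")
  # imbalance in both generations but of different strength -> cis_trans
  cls <- classify_genes(records_for(c(2000, 100), c(500, 250)))
  expect_match(as.character(cls$category), "^cis_trans")
  expect_equal(as.character(cls$collapsed), "cis_trans")
  # F0 balanced, F1 imbalanced with heterogeneous ratios -> compensatory
  cls2 <- classify_genes(records_for(c(500, 500), c(600, 200)))
  expect_equal(as.character(cls2$category), "compensatory")
  expect_equal(as.character(cls2$collapsed), "not_divergent")
})

test_that("cis_trans subtypes split on relative magnitude and sign of the ratios", {
  r <- records_for(c(2000, 100), c(500, 250))  # |log2 f0| > |log2 f1|, same sign
  expect_equal(as.character(classify_genes(r)$category), "cis_trans_enhancing")
  r2 <- records_for(c(700, 400), c(2000, 100))  # |log2 f1| > |log2 f0|
  expect_equal(as.character(classify_genes(r2)$category), "cis_trans_compensating")
})

test_that("alpha is validated and strict inequality is applied at the threshold", {
  r <- records_for(c(100, 100), c(100, 100))
  expect_error(classify_genes(r, alpha = 0), class = "ct_config_error")
  expect_error(classify_genes(r, alpha = 1), class = "ct_config_error")
  r$q_f0 <- 0.01; r$q_f1 <- 0.5; r$q_ct <- 0.5  # exactly at alpha: not significant
  expect_equal(as.character(classify_genes(r, alpha = 0.01)$category), "conserved")
})

test_that("label swap A<->B leaves p-values and categories invariant, negates ratios", {
  sim <- sim_fixture(n_genes = 400, seed = 19)
  res <- classify_counts(sim$counts)
  ch <- sim$counts$channels
  swapped <- allele_count_set(list(F0_A = ch$F0_B, F0_B = ch$F0_A,
                                   F1_A = ch$F1_B, F1_B = ch$F1_A),
                              sim$counts$gene_ids, "swapped")
  res2 <- classify_counts(swapped)
  expect_equal(res2$table$p_f0, res$table$p_f0, tolerance = 1e-12)
  expect_equal(res2$table$p_f1, res$table$p_f1, tolerance = 1e-12)
  expect_equal(res2$table$p_ct, res$table$p_ct, tolerance = 1e-12)
  expect_equal(res2$table$log2_f0_ratio, -res$table$log2_f0_ratio, tolerance = 1e-12)
  expect_equal(res2$table$log2_f1_ratio, -res$table$log2_f1_ratio, tolerance = 1e-12)
  expect_equal(as.character(res2$table$category), as.character(res$table$category))
})

test_that("scatter coordinates: cis genes hug the diagonal, trans genes the x-axis", {
  sim <- sim_fixture(n_genes = 1500, seed = 23)
  res <- classify_counts(sim$counts)
  m <- merge(res$table, sim$truth, by = "gene_id")
  cis <- m$category.y == "cis_only"; trans <- m$category.y == "trans_only"
  resid_diag_cis <- mean(abs(m$log2_f1_ratio - m$log2_f0_ratio)[cis])
  resid_axis_trans <- mean(abs(m$log2_f1_ratio[trans]))
  # each set concentrates on its own locus, far from the other's
  expect_lt(resid_diag_cis, 0.2)
  expect_lt(resid_axis_trans, 0.2)
  expect_gt(mean(abs(m$log2_f0_ratio[trans])), 0.8)
  expect_gt(mean(abs(m$log2_f1_ratio[cis])), 0.8)
})

test_that("summary proportions count categories over divergent genes only", {
  sim <- sim_fixture(n_genes = 1000, seed = 29)
  res <- classify_counts(sim$counts)
  tab <- res$table
  n_div <- sum(tab$category %in% c("cis_only", "trans_only",
                                   "cis_trans_enhancing", "cis_trans_compensating"))
  expect_equal(res$summary$n_divergent, n_div)
  expect_equal(res$summary$pct_cis + res$summary$pct_trans + res$summary$pct_cis_trans,
               100, tolerance = 1e-9)
  expect_equal(res$summary$n_universe, nrow(tab))
})

test_that("genes with empty pooled channels get NA tests, never errors", {
  mk <- function(v) matrix(as.integer(v), nrow = 2, ncol = 3, byrow = FALSE)
  acs <- allele_count_set(
    list(F0_A = mk(c(500, 40, 500, 40, 500, 40)), F0_B = mk(c(480, 35, 480, 35, 480, 35)),
         F1_A = mk(rep(c(250, 0), 3)), F1_B = mk(rep(c(240, 0), 3))),
    c("ok", "noF1"), "edge")
  res <- classify_counts(acs, normalize = FALSE)
  r <- res$table[res$table$gene_id == "noF1", ]
  expect_true(is.na(r$p_f1))
  expect_true(r$category %in% c("ambiguous", "conserved"))
})
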