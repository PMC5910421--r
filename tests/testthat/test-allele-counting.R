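write_fastq <- function(seqs, path = tempfile(fileext = ".fastq")) {
  if (length(seqs)) {
    writeLines(paste0("@r", seq_along(seqs), "\n", seqs, "\n+\n",
                      strrep("I", nchar(seqs))), path)
  } else file.create(path)
  path
}

demo_table <- function() {
  data.frame(gene_id = c("g1", "g2"),
             allele_A_seq = c("AATCGGCTAGCTTAC", "TTGACCTCAAAGGGT"),
             allele_B_seq = c("AATCGGCTCGCTTAC", "TTGACCGCAAAGGGT"),
             stringsAsFactors = FALSE)
}

test_that("exact window matches are counted for the right gene and allele", {
  tb <- demo_table()
  fq <- write_fastq(c(tb$allele_A_seq[1],                       # bare window
                      paste0("GG", tb$allele_B_seq[1], "TT"),   # embedded
                      "GGGGGGGGGGGGGGGGGGGG"))                  # matches nothing
  ac <- count_alleles(fq, tb)
  expect_equal(unname(ac$counts_A[, 1]), c(1L, 0L))
  expect_equal(unname(ac$counts_B[, 1]), c(1L, 0L))
  expect_equal(ac$summary$matched, 2L)
  expect_equal(ac$summary$total_reads, 3L)
})

test_that("reverse-complement matching is on by default and can be disabled", {
  tb <- demo_table()
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(tb$allele_A_seq[1])))
  fq <- write_fastq(paste0("AA", rc, "CC"))
  expect_equal(sum(count_alleles(fq, tb)$counts_A), 1L)
  expect_equal(sum(count_alleles(fq, tb, search_revcomp = FALSE)$counts_A), 0L)
})

test_that("a read matching both alleles of one gene is discarded as a conflict", {
  tb <- demo_table()
  fq <- write_fastq(paste0(tb$allele_A_seq[1], "NNNN", tb$allele_B_seq[1]))
  ac <- suppressWarnings(count_alleles(fq, tb))
  expect_equal(sum(ac$counts_A) + sum(ac$counts_B), 0L)
  expect_equal(ac$summary$conflicts, 1L)
})

test_that("counting is order-independent and satisfies the accounting identity", {
  tr <- data.frame(gene_id = sprintf("g%02d", 1:10),
                   cis_log2 = c(rep(0, 5), runif(5, -2, 2)))
  rr <- simulate_reads(tr, snps_per_gene = 2, read_length = 70, depth = 30,
                       n_replicates = 1, seed = 8, dir = tempfile())
  ac <- count_alleles(rr$fastq, rr$snp_table)
  # permute records and recount
  lines <- readLines(rr$fastq[1])
  rec <- split(lines, rep(seq_len(length(lines) / 4), each = 4))
  perm <- tempfile(fileext = ".fastq")
  writeLines(unlist(rec[rev(seq_along(rec))]), perm)
  ac2 <- count_alleles(perm, rr$snp_table)
  expect_equal(unname(ac$counts_A), unname(ac2$counts_A))
  expect_equal(unname(ac$counts_B), unname(ac2$counts_B))
  # error-free reads: every read matched, none conflicted
  expect_equal(sum(ac$counts_A) + sum(ac$counts_B) + ac$summary$conflicts,
               ac$summary$total_reads)
  expect_equal(ac$summary$matched, ac$summary$total_reads)
})

test_that("round trip: counts on simulated reads equal planted truth exactly", {
  tr <- data.frame(gene_id = sprintf("g%02d", 1:15),
                   cis_log2 = c(rep(0, 5), runif(10, -2, 2)))
  rr <- simulate_reads(tr, snps_per_gene = 2, read_length = 80, depth = 40,
                       n_replicates = 3, seed = 21, dir = tempfile())
  ac <- count_alleles(rr$fastq, rr$snp_table)
  expect_identical(unname(ac$counts_A), unname(rr$truth_counts$A))
  expect_identical(unname(ac$counts_B), unname(rr$truth_counts$B))
})

test_that("malformed FASTQ records fail hard with the record index", {
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "not_a_header", "ACGT", "+", "IIII"), bad)
  expect_error(count_alleles(bad, demo_table()), "record 2", class = "ct_input_error")
  writeLines(c("@r1", "ACGT", "+", "III"), bad)
  expect_error(count_alleles(bad, demo_table()), "record 1", class = "ct_input_error")
  writeLines(c("@r1", "ACGT", "+"), bad)
  expect_error(count_alleles(bad, demo_table()), "multiple of 4", class = "ct_input_error")
})

test_that("SNP table validation enforces its invariants", {
  tb <- demo_table()
  tb$allele_B_seq[1] <- tb$allele_A_seq[1]
  expect_error(validate_snp_table(tb), class = "ct_input_error")
  tb <- demo_table(); tb$allele_A_seq[1] <- "acgtacgtacgtacg"
  expect_error(validate_snp_table(tb), class = "ct_input_error")
  tb <- demo_table(); tb$allele_B_seq[2] <- "TTTTCC"
  expect_error(validate_snp_table(tb), class = "ct_input_error")
  expect_error(count_alleles(tempfile(), demo_table()[0, ]), class = "ct_config_error")
})

test_that("allelic balance test matches the closed-form t and applies verdicts", {
  # fractions (0.9, 0.92, 0.91) from counts out of 100
  r <- allelic_balance_test(c(90L, 92L, 91L), c(10L, 8L, 9L))
  fr <- c(0.9, 0.92, 0.91)
  t_exp <- (mean(fr) - 0.5) / (sd(fr) / sqrt(3))
  p_exp <- 2 * pt(abs(t_exp), df = 2, lower.tail = FALSE)
  expect_equal(r$t_statistic, t_exp, tolerance = 1e-12)
  expect_equal(r$p_value, p_exp, tolerance = 1e-12)
  expect_equal(r$verdict, "allele_biased")

  # zero variance at the null: p = 1 by convention, balanced
  r0 <- allelic_balance_test(c(50L, 50L, 50L), c(50L, 50L, 50L))
  expect_equal(r0$p_value, 1)
  expect_equal(r0$verdict, "balanced")
  # zero variance off the null: p = 0, biased
  r1 <- allelic_balance_test(c(60L, 60L), c(40L, 40L))
  expect_equal(r1$p_value, 0)
  expect_equal(r1$verdict, "allele_biased")

  # fewer than two usable replicates
  expect_equal(allelic_balance_test(10L, 5L)$verdict, "insufficient_data")
  expect_equal(allelic_balance_test(c(10L, 0L), c(5L, 0L))$verdict, "insufficient_data")
})

test_that("allelic balance report separates cis-like from trans-like genes", {
  tr <- data.frame(gene_id = c("cis_gene", "trans_gene"), cis_log2 = c(2, 0))
  rr <- simulate_reads(tr, snps_per_gene = 2, read_length = 80, depth = 500,
                       n_replicates = 3, seed = 13, dir = tempfile())
  rep <- allelic_balance_report(count_alleles(rr$fastq, rr$snp_table))
  expect_equal(rep$verdict[rep$gene_id == "cis_gene"], "allele_biased")
  expect_equal(rep$verdict[rep$gene_id == "trans_gene"], "balanced")
})
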