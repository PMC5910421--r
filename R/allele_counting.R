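# Read-level validation of allele assignment: exact matching of short
# allele-discriminating SNP windows in raw FASTQ, as done for targeted
# amplicon sequencing, plus a per-gene t-test of allelic balance.

#' Read and validate a SNP amplicon table
#'
#' The table lists, per gene, the two allele-discriminating subsequences
#' (equal length, uppercase ACGT, differing at >= 1 base). A window that
#' occurs as a substring of another gene's windows would make counting
#' ambiguous; this is checked and reported as a warning, not an error.
#'
#' @param path tab-separated file with columns gene_id, allele_A_seq,
#'   allele_B_seq.
#' @return validated data.frame of class \code{snp_amplicon_table}.
#' @export
read_snp_table <- function(path) {
  if (!file.exists(path)) ct_input_error(sprintf("SNP table not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_snp_table(df)
}

#' @rdname read_snp_table
#' @param df data.frame to validate in place of a file.
#' @export
validate_snp_table <- function(df) {
  need <- c("gene_id", "allele_A_seq", "allele_B_seq")
  if (!is.data.frame(df) || !all(need %in% names(df))) {
    ct_input_error("SNP table needs columns gene_id, allele_A_seq, allele_B_seq")
  }
  if (nrow(df) == 0L) ct_config_error("SNP table is empty")
  seqs <- c(df$allele_A_seq, df$allele_B_seq)
  if (any(!grepl("^[ACGT]+$", seqs))) {
    ct_input_error("allele windows must be uppercase ACGT only")
  }
  if (any(nchar(df$allele_A_seq) != nchar(df$allele_B_seq))) {
    ct_input_error("allele_A_seq and allele_B_seq must have equal length per gene")
  }
  if (any(df$allele_A_seq == df$allele_B_seq)) {
    ct_input_error("allele windows must differ per gene")
  }
  # cross-gene containment check (quadratic but tables are small)
  n <- nrow(df)
  if (n > 1L) {
    for (g in seq_len(n)) {
      others <- c(df$allele_A_seq[-g], df$allele_B_seq[-g])
      if (any(vapply(c(df$allele_A_seq[g], df$allele_B_seq[g]),
                     function(w) any(grepl(w, others, fixed = TRUE)), logical(1)))) {
        warning(sprintf("window of gene %s is contained in another gene's window; counts may be ambiguous",
                        df$gene_id[g]))
      }
    }
  }
  class(df) <- c("snp_amplicon_table", "data.frame")
  df
}

# Validating 4-line FASTQ reader; returns a character vector of sequences.
# Errors name the record index, since a truncated or shifted record silently
# corrupts every later count.
read_fastq_seqs <- function(path) {
  if (!file.exists(path)) ct_input_error(sprintf("FASTQ not found: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0L) return(character(0))
  if (length(lines) %% 4L != 0L) {
    ct_input_error(sprintf("%s: truncated FASTQ, %d lines is not a multiple of 4 (record %d incomplete)",
                           path, length(lines), length(lines) %/% 4L + 1L))
  }
  idx <- seq(1L, length(lines), by = 4L)
  bad_hdr <- !startsWith(lines[idx], "@")
  if (any(bad_hdr)) {
    ct_input_error(sprintf("%s: malformed FASTQ record %d (header does not start with '@')",
                           path, which(bad_hdr)[1]))
  }
  bad_plus <- !startsWith(lines[idx + 2L], "+")
  if (any(bad_plus)) {
    ct_input_error(sprintf("%s: malformed FASTQ record %d (separator line does not start with '+')",
                           path, which(bad_plus)[1]))
  }
  bad_len <- nchar(lines[idx + 1L]) != nchar(lines[idx + 3L])
  if (any(bad_len)) {
    ct_input_error(sprintf("%s: malformed FASTQ record %d (sequence and quality lengths differ)",
                           path, which(bad_len)[1]))
  }
  lines[idx + 1L]
}

#' Count allele-discriminating windows in FASTQ reads
#'
#' A read increments allele A of gene g iff the gene's allele-A window occurs
#' as an exact substring of the read (and symmetrically for allele B). By
#' default the reverse complement of each window is also searched, since
#' amplicon sequencing reads either strand; \code{search_revcomp = FALSE}
#' restricts to forward orientation. A read matching both alleles of the same
#' gene is discarded for that gene and counted in a per-replicate conflict
#' tally. A read matching windows of two different genes counts for both
#' (each gene's counter is independent) and triggers a warning.
#'
#' @param fastq_paths character vector of FASTQ files (plain or gzip), one
#'   per replicate library.
#' @param table SNP amplicon table (see [read_snp_table()]); a plain
#'   data.frame is validated on the fly.
#' @param search_revcomp also match the reverse complement of each window.
#' @return object of class \code{allele_counts}: list with integer matrices
#'   \code{counts_A}, \code{counts_B} (gene x replicate), per-replicate
#'   vectors \code{conflicts} and \code{total_reads}, and \code{summary}
#'   (list: total_reads, matched, conflicts).
#' @export
count_alleles <- function(fastq_paths, table, search_revcomp = TRUE) {
  table <- validate_snp_table(as.data.frame(table))
  n_rep <- length(fastq_paths)
  if (n_rep == 0L) ct_config_error("no FASTQ files given")
  n <- nrow(table)
  cnt_A <- matrix(0L, n, n_rep, dimnames = list(table$gene_id, NULL))
  cnt_B <- cnt_A
  conflicts <- integer(n_rep)
  total <- integer(n_rep)
  matched_reads <- 0L
  multi_gene_seen <- FALSE

  rc <- function(w) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(w)))
  patterns_A <- table$allele_A_seq
  patterns_B <- table$allele_B_seq
  patterns_A_rc <- rc(patterns_A)
  patterns_B_rc <- rc(patterns_B)

  for (k in seq_len(n_rep)) {
    seqs <- read_fastq_seqs(fastq_paths[k])
    total[k] <- length(seqs)
    if (length(seqs) == 0L) next
    subject <- Biostrings::DNAStringSet(seqs)
    gene_hits <- matrix(FALSE, length(seqs), 0)
    hit <- function(pat) Biostrings::vcountPattern(pat, subject, fixed = TRUE) > 0
    any_gene_match <- rep(0L, length(seqs))
    read_matched <- rep(FALSE, length(seqs))
    for (g in seq_len(n)) {
      hA <- hit(patterns_A[g])
      hB <- hit(patterns_B[g])
      if (search_revcomp) {
        hA <- hA | hit(patterns_A_rc[g])
        hB <- hB | hit(patterns_B_rc[g])
      }
      both <- hA & hB
      conflicts[k] <- conflicts[k] + sum(both)
      cnt_A[g, k] <- sum(hA & !both)
      cnt_B[g, k] <- sum(hB & !both)
      this_gene <- hA | hB
      any_gene_match <- any_gene_match + as.integer(this_gene)
      read_matched <- read_matched | this_gene
    }
    if (any(any_gene_match > 1L)) multi_gene_seen <- TRUE
    matched_reads <- matched_reads + sum(read_matched)
  }
  if (multi_gene_seen) {
    warning("some reads matched windows of more than one gene; counted for each gene independently")
  }
  structure(list(counts_A = cnt_A, counts_B = cnt_B,
                 conflicts = conflicts, total_reads = total,
                 summary = list(total_reads = sum(total),
                                matched = matched_reads,
                                conflicts = sum(conflicts))),
            class = "allele_counts")
}

#' One-sample t-test of allelic balance for one gene
#'
#' Tests whether the per-replicate allele-A fractions depart from 0.5
#' (two-tailed one-sample t-test), the statistic used to validate cis- vs
#' trans-regulation calls by targeted sequencing: a cis-regulated gene shows
#' allele-biased F1 expression, a trans-regulated gene does not.
#'
#' Verdicts: \code{allele_biased} if p < \code{bias_alpha} (default 0.001,
#' the display threshold), \code{balanced} if p >= \code{balanced_alpha}
#' (default 0.05), \code{indeterminate} in between, and
#' \code{insufficient_data} when fewer than two replicates have nonzero
#' totals. Zero-variance fractions make the t-statistic undefined; by
#' convention p = 1 when the common fraction equals 0.5 and p = 0 otherwise,
#' which keeps the decision rule continuous.
#'
#' @param counts_A,counts_B per-replicate nonnegative integer counts.
#' @param bias_alpha,balanced_alpha verdict thresholds (see above).
#' @return list: fraction_A (per usable replicate), t_statistic, p_value,
#'   verdict, n_usable.
#' @export
allelic_balance_test <- function(counts_A, counts_B,
                                 bias_alpha = 0.001, balanced_alpha = 0.05) {
  if (length(counts_A) != length(counts_B)) {
    ct_config_error("counts_A and counts_B must have equal length")
  }
  tot <- counts_A + counts_B
  usable <- tot > 0
  fr <- counts_A[usable] / tot[usable]
  if (sum(usable) < 2L) {
    return(list(fraction_A = fr, t_statistic = NA_real_, p_value = NA_real_,
                verdict = "insufficient_data", n_usable = sum(usable)))
  }
  if (stats::sd(fr) == 0) {
    p <- if (abs(mean(fr) - 0.5) < .Machine$double.eps^0.5) 1 else 0
    tstat <- NA_real_
  } else {
    tt <- stats::t.test(fr, mu = 0.5, alternative = "two.sided")
    p <- tt$p.value
    tstat <- unname(tt$statistic)
  }
  verdict <- if (p < bias_alpha) "allele_biased"
             else if (p >= balanced_alpha) "balanced"
             else "indeterminate"
  list(fraction_A = fr, t_statistic = tstat, p_value = p,
       verdict = verdict, n_usable = sum(usable))
}

#' Per-gene allelic balance report from counted reads
#'
#' Applies [allelic_balance_test()] to every gene of a [count_alleles()]
#' result.
#'
#' @param ac an \code{allele_counts} object.
#' @inheritParams allelic_balance_test
#' @return data.frame: gene_id, mean_fraction_A, sd_fraction_A, t_statistic,
#'   p_value, verdict.
#' @export
allelic_balance_report <- function(ac, bias_alpha = 0.001, balanced_alpha = 0.05) {
  stopifnot(inherits(ac, "allele_counts"))
  genes <- rownames(ac$counts_A)
  rows <- lapply(seq_along(genes), function(g) {
    r <- allelic_balance_test(ac$counts_A[g, ], ac$counts_B[g, ],
                              bias_alpha, balanced_alpha)
    data.frame(gene_id = genes[g],
               mean_fraction_A = if (length(r$fraction_A)) mean(r$fraction_A) else NA_real_,
               sd_fraction_A = if (length(r$fraction_A) > 1) stats::sd(r$fraction_A) else NA_real_,
               t_statistic = r$t_statistic,
               p_value = r$p_value,
               verdict = r$verdict,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
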