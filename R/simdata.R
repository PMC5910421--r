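#' Simulation configuration for the F0/F1 count generator
#'
#' Bundles and validates the parameters of the four-channel count simulator.
#' The generative model mirrors an F1-hybrid allele-specific expression
#' design: two parental strains (F0 A and B) and the two alleles of their F1
#' hybrid measured in the same libraries. A gene's divergence decomposes into
#' a cis component (carried by the allele, so it survives into the F1 allelic
#' ratio) and a trans component (carried by the cellular environment, shared
#' by both F1 alleles and therefore absent from the F1 allelic ratio).
#'
#' Per gene with baseline mean \eqn{\mu}, library size factor \eqn{s}:
#' \deqn{E[F0_A] = s\mu,\quad E[F0_B] = s\mu 2^{c+t},\quad
#'       E[F1_A] = s\mu/2,\quad E[F1_B] = (s\mu/2) 2^{c}}
#' where \eqn{c} and \eqn{t} are the planted cis and trans log2 effects.
#' Counts are negative binomial with variance \eqn{\mu + \alpha\mu^2}
#' (\code{dispersion} = \eqn{\alpha}; 0 degenerates to Poisson).
#'
#' @param n_genes number of genes.
#' @param n_replicates libraries per group (default 3, as in a typical
#'   pooled-library design).
#' @param category_proportions named numeric vector over
#'   \code{c("conserved","cis_only","trans_only","cis_trans")}, summing to 1.
#'   Defaults plant 20\% divergent genes split 84/8/8 between cis-only,
#'   trans-only and cis-trans.
#' @param baseline_log2_mean,baseline_log2_sd mean and sd of per-gene log2
#'   baseline expression (counts per replicate library).
#' @param dispersion negative-binomial overdispersion \eqn{\alpha} (>= 0).
#' @param cis_effect_log2,trans_effect_log2 magnitude of the planted effects,
#'   either a single positive value or a length-2 range sampled uniformly;
#'   the sign of each gene's effect is drawn +/- with equal probability.
#' @param size_factor_range length-2 positive range for per-library scaling.
#' @param seed master seed; all three generators derive their streams from it.
#' @return an object of class \code{sim_config}.
#' @seealso [simulate_counts()], [simulate_reads()], [simulate_motif_hits()]
#' @export
sim_config <- function(n_genes = 1000L,
                       n_replicates = 3L,
                       category_proportions = c(conserved = 0.80,
                                                cis_only = 0.168,
                                                trans_only = 0.016,
                                                cis_trans = 0.016),
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 1.5,
                       dispersion = 0.01,
                       cis_effect_log2 = c(0.5, 2),
                       trans_effect_log2 = c(0.5, 2),
                       size_factor_range = c(0.7, 1.4),
                       seed = 1L) {
  cats <- c("conserved", "cis_only", "trans_only", "cis_trans")
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1) {
    ct_config_error("n_genes must be a positive integer")
  }
  if (!is.numeric(n_replicates) || length(n_replicates) != 1L || n_replicates < 1) {
    ct_config_error("n_replicates must be a positive integer")
  }
  if (is.null(names(category_proportions)) ||
      !all(names(category_proportions) %in% cats)) {
    ct_config_error(paste("category_proportions must be named with a subset of:",
                          paste(cats, collapse = ", ")))
  }
  props <- setNames(numeric(4), cats)
  props[names(category_proportions)] <- category_proportions
  if (any(props < 0) || abs(sum(props) - 1) > 1e-9) {
    ct_config_error("category_proportions must be nonnegative and sum to 1 (tol 1e-9)")
  }
  if (!is.numeric(dispersion) || length(dispersion) != 1L || dispersion < 0) {
    ct_config_error("dispersion must be a single nonnegative number")
  }
  if (!is.numeric(baseline_log2_sd) || baseline_log2_sd < 0) {
    ct_config_error("baseline_log2_sd must be nonnegative")
  }
  check_effect <- function(x, name) {
    if (!is.numeric(x) || !length(x) %in% c(1L, 2L) || any(x < 0)) {
      ct_config_error(sprintf("%s must be a nonnegative scalar or range", name))
    }
    if (length(x) == 2L && x[2] < x[1]) {
      ct_config_error(sprintf("%s range must be nondecreasing", name))
    }
  }
  check_effect(cis_effect_log2, "cis_effect_log2")
  check_effect(trans_effect_log2, "trans_effect_log2")
  if (!is.numeric(size_factor_range) || length(size_factor_range) != 2L ||
      any(size_factor_range <= 0) || size_factor_range[2] < size_factor_range[1]) {
    ct_config_error("size_factor_range must be a positive nondecreasing pair")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 category_proportions = props,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 dispersion = dispersion,
                 cis_effect_log2 = cis_effect_log2,
                 trans_effect_log2 = trans_effect_log2,
                 size_factor_range = size_factor_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

CHANNELS <- c("F0_A", "F0_B", "F1_A", "F1_B")

#' Construct a four-channel allele count set
#'
#' Container for the four gene-by-replicate count matrices of an F0/F1
#' allele-specific expression experiment.
#'
#' @param channels named list of four nonnegative integer matrices
#'   (\code{F0_A}, \code{F0_B}, \code{F1_A}, \code{F1_B}) sharing dimensions
#'   and gene order.
#' @param gene_ids character vector of gene identifiers (rows).
#' @param condition_label free-text condition tag, e.g. \code{"PFC_unstressed"}.
#' @return an object of class \code{allele_count_set}.
#' @export
allele_count_set <- function(channels, gene_ids, condition_label = "unlabelled") {
  if (!is.list(channels) || !setequal(names(channels), CHANNELS)) {
    ct_input_error("channels must be a named list F0_A, F0_B, F1_A, F1_B")
  }
  channels <- channels[CHANNELS]
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L) ct_input_error("all four channel matrices must share dimensions")
  for (ch in CHANNELS) {
    m <- channels[[ch]]
    if (!is.numeric(m) || any(m < 0) || any(m != floor(m))) {
      ct_input_error(sprintf("channel %s must contain nonnegative integers", ch))
    }
    rownames(channels[[ch]]) <- gene_ids
  }
  if (length(gene_ids) != nrow(channels[[1]])) {
    ct_input_error("gene_ids length must match the number of matrix rows")
  }
  structure(list(gene_ids = as.character(gene_ids),
                 channels = channels,
                 condition_label = condition_label),
            class = "allele_count_set")
}

#' @export
print.allele_count_set <- function(x, ...) {
  cat(sprintf("allele_count_set: %d genes x %d replicates x 4 channels [%s]\n",
              length(x$gene_ids), ncol(x$channels[[1]]), x$condition_label))
  invisible(x)
}

#' Simulate four-channel F0/F1 counts with planted ground truth
#'
#' Draws per-gene baselines, assigns regulatory categories by deterministic
#' largest-remainder apportionment of \code{category_proportions} (so planted
#' category counts are exact), plants cis/trans log2 effects, and draws
#' negative-binomial counts under the mean structure described in
#' [sim_config()]. Category-to-gene assignment, effect signs and magnitudes,
#' library size factors and counts are all drawn from a private RNG stream
#' seeded from \code{config$seed}, so runs are bitwise reproducible.
#'
#' @param config a [sim_config()] object.
#' @param condition_label condition tag stored on the returned count set.
#' @return list with elements \code{counts} (an \code{allele_count_set}),
#'   \code{truth} (data.frame: gene_id, category, cis_log2, trans_log2,
#'   baseline_mean) and \code{size_factors} (the planted per-library scaling,
#'   one per channel-replicate column, named like the count columns).
#' @export
simulate_counts <- function(config, condition_label = "simulated") {
  if (!inherits(config, "sim_config")) {
    ct_config_error("config must be built with sim_config()")
  }
  n <- config$n_genes
  r <- config$n_replicates
  with_seed(config$seed, {
    gene_ids <- sprintf("gene_%05d", seq_len(n))
    cats <- c("conserved", "cis_only", "trans_only", "cis_trans")
    counts_per_cat <- apportion(n, config$category_proportions[cats])
    category <- sample(rep(cats, times = counts_per_cat))

    draw_effect <- function(spec_mag, active) {
      mag <- if (length(spec_mag) == 2L) runif(n, spec_mag[1], spec_mag[2]) else rep(spec_mag, n)
      sgn <- sample(c(-1, 1), n, replace = TRUE)
      ifelse(active, mag * sgn, 0)
    }
    cis_log2 <- draw_effect(config$cis_effect_log2,
                            category %in% c("cis_only", "cis_trans"))
    trans_log2 <- draw_effect(config$trans_effect_log2,
                              category %in% c("trans_only", "cis_trans"))
    baseline <- 2^rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)

    n_lib <- 4L * r
    sf <- runif(n_lib, config$size_factor_range[1], config$size_factor_range[2])
    lib_names <- paste0(rep(CHANNELS, each = r), "_rep", rep(seq_len(r), times = 4))
    names(sf) <- lib_names

    # expected counts per channel before library scaling
    mu_channel <- cbind(F0_A = baseline,
                        F0_B = baseline * 2^(cis_log2 + trans_log2),
                        F1_A = baseline / 2,
                        F1_B = (baseline / 2) * 2^cis_log2)

    draw <- function(mu) {
      if (config$dispersion == 0) rpois(length(mu), mu)
      else rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    }
    channels <- setNames(vector("list", 4), CHANNELS)
    for (ci in seq_along(CHANNELS)) {
      ch <- CHANNELS[ci]
      m <- matrix(0L, nrow = n, ncol = r,
                  dimnames = list(gene_ids, paste0(ch, "_rep", seq_len(r))))
      for (k in seq_len(r)) {
        s <- sf[paste0(ch, "_rep", k)]
        m[, k] <- draw(s * mu_channel[, ci])
      }
      channels[[ch]] <- m
    }
    truth <- data.frame(gene_id = gene_ids,
                        category = category,
                        cis_log2 = cis_log2,
                        trans_log2 = trans_log2,
                        baseline_mean = baseline,
                        stringsAsFactors = FALSE)
    list(counts = allele_count_set(channels, gene_ids, condition_label),
         truth = truth,
         size_factors = sf)
  })
}

DNA_BASES <- c("A", "C", "G", "T")

#' Simulate error-free F1 amplicon reads carrying allele-discriminating SNPs
#'
#' Emulates a targeted amplicon-sequencing validation: per gene, an amplicon
#' of length \code{read_length} is built for each allele, identical except at
#' \code{snps_per_gene} SNP positions inside a short discriminating window.
#' Per replicate, exactly \code{depth} reads are emitted per gene, split
#' between the alleles deterministically according to the allelic ratio
#' implied by the gene's planted cis effect
#' (\eqn{P(B) = 2^{c}/(1+2^{c})}, counts rounded): the planted counts are the
#' truth the read counter must recover exactly. Reads have zero sequencing
#' error and constant quality 'I' (Phred+33, Q40).
#'
#' @param truth truth data.frame from [simulate_counts()] (uses gene_id and
#'   cis_log2), or any data.frame with those columns.
#' @param snps_per_gene number of discriminating SNPs per gene window.
#' @param read_length read (= amplicon) length in bases; must not be shorter
#'   than the discriminating window.
#' @param depth reads per gene per replicate.
#' @param n_replicates number of FASTQ files (replicate libraries).
#' @param seed RNG seed for sequence generation and read shuffling.
#' @param dir directory where FASTQ files are written.
#' @return list with \code{fastq} (paths, one per replicate),
#'   \code{snp_table} (data.frame gene_id, allele_A_seq, allele_B_seq),
#'   and \code{truth_counts} (list of gene x replicate matrices \code{A},
#'   \code{B} of emitted reads per allele).
#' @export
simulate_reads <- function(truth, snps_per_gene = 2L, read_length = 100L,
                           depth = 100L, n_replicates = 3L, seed = 1L,
                           dir = tempfile("reads_")) {
  if (!is.data.frame(truth) || !all(c("gene_id", "cis_log2") %in% names(truth))) {
    ct_config_error("truth must be a data.frame with gene_id and cis_log2 columns")
  }
  if (depth < 0) ct_config_error("depth must be nonnegative")
  window_len <- max(15L, 6L + 3L * as.integer(snps_per_gene))
  if (read_length < window_len) {
    ct_config_error(sprintf(
      "read_length (%d) is shorter than the %d-base SNP-discriminating window",
      read_length, window_len))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(truth)
  with_seed(seed, {
    # per-gene allele windows and full amplicons
    snp_pos <- round(seq(4, window_len - 3, length.out = snps_per_gene))
    win_A <- character(n); win_B <- character(n)
    amp_A <- character(n); amp_B <- character(n)
    for (g in seq_len(n)) {
      w <- sample(DNA_BASES, window_len, replace = TRUE)
      wB <- w
      for (p in snp_pos) wB[p] <- sample(setdiff(DNA_BASES, w[p]), 1)
      start <- sample.int(read_length - window_len + 1L, 1)
      flank5 <- sample(DNA_BASES, start - 1L, replace = TRUE)
      flank3 <- sample(DNA_BASES, read_length - window_len - start + 1L, replace = TRUE)
      win_A[g] <- paste(w, collapse = "")
      win_B[g] <- paste(wB, collapse = "")
      amp_A[g] <- paste(c(flank5, w, flank3), collapse = "")
      amp_B[g] <- paste(c(flank5, wB, flank3), collapse = "")
    }
    p_B <- 2^truth$cis_log2 / (1 + 2^truth$cis_log2)
    n_B <- as.integer(round(depth * p_B))
    n_A <- as.integer(depth) - n_B
    cnt_A <- matrix(0L, n, n_replicates, dimnames = list(truth$gene_id, NULL))
    cnt_B <- cnt_A
    fastq <- character(n_replicates)
    qual <- strrep("I", read_length)
    for (k in seq_len(n_replicates)) {
      seqs <- c(rep(amp_A, times = n_A), rep(amp_B, times = n_B))
      cnt_A[, k] <- n_A
      cnt_B[, k] <- n_B
      ord <- if (length(seqs)) sample.int(length(seqs)) else integer(0)
      seqs <- seqs[ord]
      path <- file.path(dir, sprintf("F1_rep%d.fastq", k))
      if (length(seqs)) {
        rec <- paste0("@read_", seq_along(seqs), "\n", seqs, "\n+\n", qual)
        writeLines(rec, path)
      } else {
        file.create(path)
      }
      fastq[k] <- path
    }
    snp_table <- data.frame(gene_id = truth$gene_id,
                            allele_A_seq = win_A,
                            allele_B_seq = win_B,
                            stringsAsFactors = FALSE)
    list(fastq = fastq, snp_table = snp_table,
         truth_counts = list(A = cnt_A, B = cnt_B))
  })
}

#' Simulate motif-hit tables with an optionally planted enrichment
#'
#' Per gene and motif, hit counts are Poisson with rate
#' \code{bg_hit_rate * seq_len}; for the planted motif only, the foreground
#' rate is multiplied by \code{fg_rate_multiplier}. With multiplier 1 (or no
#' planted motif) foreground and background are exchangeable for every motif,
#' giving a null fixture for the enrichment statistic.
#'
#' @param n_fg,n_bg number of foreground / background genes.
#' @param motif_ids character vector of motif identifiers.
#' @param planted_motif one of \code{motif_ids}, or \code{NULL} for a pure null.
#' @param fg_rate_multiplier foreground rate multiplier for the planted motif.
#' @param bg_hit_rate background hit rate per scanned base.
#' @param seq_len scanned sequence length per gene (bases).
#' @param seed RNG seed.
#' @return list with data.frames \code{foreground} and \code{background},
#'   each with columns gene_id, set_label, scanned_length and one hit-count
#'   column per motif.
#' @export
simulate_motif_hits <- function(n_fg, n_bg, motif_ids,
                                planted_motif = NULL,
                                fg_rate_multiplier = 1,
                                bg_hit_rate = 2e-4,
                                seq_len = 5000L,
                                seed = 1L) {
  if (bg_hit_rate < 0 || fg_rate_multiplier <= 0) {
    ct_config_error("bg_hit_rate must be >= 0 and fg_rate_multiplier > 0")
  }
  if (!is.null(planted_motif) && !planted_motif %in% motif_ids) {
    ct_config_error("planted_motif must be one of motif_ids")
  }
  if (seq_len < 0) ct_config_error("seq_len must be nonnegative")
  with_seed(seed, {
    mk <- function(n_set, label, prefix, planted_mult) {
      hits <- sapply(motif_ids, function(m) {
        rate <- bg_hit_rate * seq_len *
          if (!is.null(planted_motif) && m == planted_motif) planted_mult else 1
        pmin(rpois(n_set, rate), max(seq_len, 0L))
      })
      if (n_set == 1L) hits <- matrix(hits, nrow = 1, dimnames = list(NULL, motif_ids))
      df <- data.frame(gene_id = sprintf("%s_%04d", prefix, seq_len(n_set)),
                       set_label = label,
                       scanned_length = as.integer(seq_len),
                       stringsAsFactors = FALSE)
      cbind(df, as.data.frame(hits))
    }
    fg <- mk(n_fg, "foreground", "fg", fg_rate_multiplier)
    bg <- mk(n_bg, "background", "bg", 1)
    list(foreground = fg, background = bg)
  })
}
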