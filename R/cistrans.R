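# Core cis/trans statistics: per-gene binomial exact tests for F0 divergence
# and F1 allelic imbalance, a Fisher exact test contrasting the F0 and F1
# allelic ratios, BH-FDR per test family, and the McManus-style category
# assignment.
#
# Logic of the design: a cis-acting difference travels with the allele, so it
# shows up both between the parents (F0) and between the two alleles inside
# the F1 hybrid; a trans-acting difference is shared by both F1 alleles, so
# it shows up between the parents but NOT in the F1 allelic ratio, making the
# F0 and F1 ratios heterogeneous.

#' Two-sided binomial exact test
#'
#' Exact two-sided p-value by the point-mass rule: the sum of all binomial
#' point masses not exceeding the mass of the observed count. At the null
#' proportion 0.5 the distribution is symmetric and the rule reduces to a
#' closed form; for other null proportions the masses are summed directly
#' (with a 1e-7 relative tie tolerance, the convention used by exact-test
#' implementations to stabilize floating-point ties).
#'
#' @param k observed successes (vectorized).
#' @param n number of trials (vectorized, >= 1).
#' @param p0 null success probability (default 0.5).
#' @return two-sided p-value(s) in [0, 1].
#' @export
binomial_exact_test <- function(k, n, p0 = 0.5) {
  if (any(n < 1)) ct_config_error("binomial exact test undefined for n = 0")
  if (any(k < 0 | k > n)) ct_config_error("k must satisfy 0 <= k <= n")
  stopifnot_scalar_prob(p0, "p0")
  if (p0 == 0.5) return(binom_half_two_sided(k, n))
  mapply(function(ki, ni) {
    d <- stats::dbinom(0:ni, ni, p0)
    min(1, sum(d[d <= d[ki + 1L] * (1 + 1e-7)]))
  }, k, n)
}

# closed form for p0 = 0.5: by symmetry {mass(j) <= mass(k)} =
# {j <= k'} U {j >= n - k'} with k' = min(k, n - k); exact, no tie tolerance.
binom_half_two_sided <- function(k, n) {
  kp <- pmin(k, n - k)
  ifelse(2 * kp == n, 1, pmin(1, 2 * stats::pbinom(kp, n, 0.5)))
}

#' Two-sided Fisher exact test for F0-vs-F1 ratio heterogeneity
#'
#' Exact two-sided p-value on the 2x2 table [[f0_A, f0_B], [f1_A, f1_B]] by
#' the point-mass rule on the conditional hypergeometric distribution. A
#' table with a zero margin carries no information about ratio heterogeneity;
#' by convention its p-value is 1 (flagged via the \code{degenerate}
#' attribute).
#'
#' @param f0 integer pair (A, B): pooled parental counts.
#' @param f1 integer pair (A, B): pooled F1 allele counts.
#' @return two-sided p-value with attribute \code{degenerate} (logical).
#' @export
fisher_ratio_test <- function(f0, f1) {
  if (length(f0) != 2L || length(f1) != 2L || any(c(f0, f1) < 0) ||
      any(c(f0, f1) != floor(c(f0, f1)))) {
    ct_config_error("f0 and f1 must be nonnegative integer pairs")
  }
  r <- fisher_two_sided_vec(f0[1], f0[2], f1[1], f1[2])
  structure(r$p, degenerate = r$degenerate)
}

# Vectorized two-sided Fisher exact over tables [[a, b], [c, d]], by the
# point-mass rule: p = sum of hypergeometric masses <= observed mass
# (relative tie tolerance 1 + 1e-7). The hypergeometric pmf is unimodal, so
# the sublevel set {x : d(x) <= thresh} is a union of a left tail {x <= x1}
# and a right tail {x >= x2}; both boundaries are found by vectorized binary
# search and the tails summed with phyper, giving O(log support) work per
# table instead of a full support scan.
fisher_two_sided_vec <- function(a, b, c, d, eps = 1e-7) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  R1 <- a + b; R2 <- c + d; C1 <- a + c; C2 <- b + d
  N <- R1 + R2
  degenerate <- R1 == 0 | R2 == 0 | C1 == 0 | C2 == 0
  p <- rep(1, length(a))
  ok <- which(!degenerate)
  if (length(ok)) {
    m <- C1[ok]; nn <- C2[ok]; k <- R1[ok]
    lo <- pmax(0, k - nn)
    hi <- pmin(k, m)
    thresh <- stats::dhyper(a[ok], m, nn, k) * (1 + eps)
    mode <- pmax(lo, pmin(floor((k + 1) * (m + 1) / (N[ok] + 2)), hi))
    # left boundary: largest x in [lo-1, mode] with d(x) <= thresh
    # (d nondecreasing on [lo, mode]; lo-1 is the empty-tail sentinel)
    L <- lo - 1; Rb <- mode
    repeat {
      act <- which(L < Rb)
      if (!length(act)) break
      mid <- ceiling((L[act] + Rb[act]) / 2)
      hit <- stats::dhyper(mid, m[act], nn[act], k[act]) <= thresh[act]
      L[act][hit] <- mid[hit]
      Rb[act][!hit] <- mid[!hit] - 1
    }
    x1 <- L
    # right boundary: smallest x in [mode, hi+1] with d(x) <= thresh
    L2 <- mode; R2b <- hi + 1
    repeat {
      act <- which(L2 < R2b)
      if (!length(act)) break
      mid <- floor((L2[act] + R2b[act]) / 2)
      hit <- stats::dhyper(mid, m[act], nn[act], k[act]) <= thresh[act]
      R2b[act][hit] <- mid[hit]
      L2[act][!hit] <- mid[!hit] + 1
    }
    x2 <- L2
    p[ok] <- pmin(1, stats::phyper(x1, m, nn, k) +
                     stats::phyper(x2 - 1, m, nn, k, lower.tail = FALSE))
  }
  list(p = p, degenerate = degenerate)
}

# full-support scan variant of the same rule; retained as the slow reference
# path for equivalence testing of the binary-search implementation
fisher_two_sided_scan <- function(a, b, c, d, eps = 1e-7) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  R1 <- a + b; R2 <- c + d; C1 <- a + c; C2 <- b + d
  degenerate <- R1 == 0 | R2 == 0 | C1 == 0 | C2 == 0
  p <- rep(1, length(a))
  ok <- which(!degenerate)
  if (length(ok)) {
    lo <- pmax(0, C1[ok] - R2[ok])
    hi <- pmin(R1[ok], C1[ok])
    len <- hi - lo + 1
    g <- rep.int(seq_along(ok), len)
    x <- sequence(as.integer(len), from = as.integer(lo))
    dall <- stats::dhyper(x, C1[ok][g], C2[ok][g], R1[ok][g])
    dobs <- stats::dhyper(a[ok], C1[ok], C2[ok], R1[ok])
    keep <- dall <= dobs[g] * (1 + eps)
    p[ok] <- pmin(1, as.numeric(rowsum(dall * keep, g)))
  }
  list(p = p, degenerate = degenerate)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with enforced monotonicity. Missing p-values
#' (NA/NaN) propagate as NA and are excluded from the ranking (they do not
#' count toward the number of tests).
#'
#' @param p numeric vector of p-values in [0, 1] (NAs allowed).
#' @return q-values, same length and order as \code{p}.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) ct_config_error("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

CATEGORY_LEVELS <- c("conserved", "cis_only", "trans_only",
                     "cis_trans_enhancing", "cis_trans_compensating",
                     "compensatory", "ambiguous")

#' Assign regulatory categories from per-gene test records
#'
#' With S0 = significant F0 divergence (q_f0 < alpha), S1 = significant F1
#' allelic imbalance (q_f1 < alpha) and SC = significant F0-vs-F1 ratio
#' heterogeneity (q_ct < alpha):
#' \itemize{
#'   \item cis_only: S0 & S1 & !SC (divergence explained by the allele alone)
#'   \item trans_only: S0 & !S1 & SC (divergence absent from the F1 ratio)
#'   \item cis_trans: S0 & S1 & SC, subtyped enhancing when the F0 ratio
#'     exceeds the F1 ratio in magnitude with the same sign (trans reinforces
#'     cis), compensating otherwise
#'   \item compensatory: !S0 & S1 & SC (cis and trans cancel in F0)
#'   \item conserved: !S0 & !S1 & !SC
#'   \item ambiguous: every other combination
#' }
#' Missing q-values are treated as not significant. The collapsed reporting
#' scheme maps cis_only -> cis, trans_only -> trans, both cis_trans subtypes
#' -> cis_trans, and everything else -> not_divergent.
#'
#' @param records data.frame with columns q_f0, q_f1, q_ct, log2_f0_ratio,
#'   log2_f1_ratio.
#' @param alpha FDR threshold (default 0.01; strict <).
#' @return data.frame: category, collapsed (factors with fixed levels).
#' @export
classify_genes <- function(records, alpha = 0.01) {
  stopifnot_scalar_prob(alpha, "alpha")
  need <- c("q_f0", "q_f1", "q_ct", "log2_f0_ratio", "log2_f1_ratio")
  if (!all(need %in% names(records))) {
    ct_input_error(paste("records must contain:", paste(need, collapse = ", ")))
  }
  sig <- function(q) !is.na(q) & q < alpha
  S0 <- sig(records$q_f0); S1 <- sig(records$q_f1); SC <- sig(records$q_ct)
  lf0 <- records$log2_f0_ratio; lf1 <- records$log2_f1_ratio
  enhancing <- abs(lf0) > abs(lf1) & sign(lf0) == sign(lf1)
  category <- rep("ambiguous", nrow(records))
  category[S0 & S1 & !SC] <- "cis_only"
  category[S0 & !S1 & SC] <- "trans_only"
  category[S0 & S1 & SC] <- ifelse(enhancing[S0 & S1 & SC],
                                   "cis_trans_enhancing", "cis_trans_compensating")
  category[!S0 & S1 & SC] <- "compensatory"
  category[!S0 & !S1 & !SC] <- "conserved"
  collapsed <- rep("not_divergent", nrow(records))
  collapsed[category == "cis_only"] <- "cis"
  collapsed[category == "trans_only"] <- "trans"
  collapsed[category %in% c("cis_trans_enhancing", "cis_trans_compensating")] <- "cis_trans"
  data.frame(category = factor(category, levels = CATEGORY_LEVELS),
             collapsed = factor(collapsed,
                                levels = c("cis", "trans", "cis_trans", "not_divergent")))
}

#' Full cis/trans classification of a four-channel count set
#'
#' The end-to-end per-condition analysis: expressed-gene filter on raw
#' counts, median-of-ratios normalization (one factor per channel-replicate
#' column), pooling of normalized counts across replicates (rounded
#' half-to-even to integers, as exact tests need integer counts), the three
#' exact tests per gene, BH-FDR within each of the three families at
#' \code{alpha}, and category assignment via [classify_genes()].
#'
#' Log2 ratios are reported B over A with a pseudocount of 0.5 on each
#' pooled count (display only; tests use the unpseudocounted integers).
#'
#' @param acs an \code{allele_count_set} of raw counts.
#' @param alpha per-family FDR threshold (default 0.01).
#' @param min_count expression-filter cutoff (default 10; see
#'   [expression_filter()]).
#' @param normalize apply median-of-ratios normalization before pooling.
#' @param fallback passed to [size_factors()].
#' @return object of class \code{cistrans_result}: list with \code{table}
#'   (per-gene data.frame: gene_id, pooled counts, p/q triplets, log ratios,
#'   category, collapsed), \code{summary} (list: n_universe, n_divergent,
#'   n_ambiguous, pct_divergent, pct_cis, pct_trans, pct_cis_trans),
#'   \code{size_factors}, \code{alpha}, \code{condition_label}.
#' @export
classify_counts <- function(acs, alpha = 0.01, min_count = 10,
                            normalize = TRUE, fallback = FALSE) {
  stopifnot(inherits(acs, "allele_count_set"))
  stopifnot_scalar_prob(alpha, "alpha")
  filt <- expression_filter(acs, threshold = min_count)
  keep <- filt$mask
  sub <- allele_count_set(lapply(acs$channels, function(m) m[keep, , drop = FALSE]),
                          acs$gene_ids[keep], acs$condition_label)
  if (filt$n_universe == 0L) ct_input_error("no gene passes the expression filter")
  sf <- NULL
  if (normalize) {
    combined <- do.call(cbind, sub$channels)
    sf <- size_factors(combined, fallback = fallback)
    # Rescale factors to geometric mean 1 within each generation's channel
    # pair (F0_A+F0_B, F1_A+F1_B). Relative factors -- and therefore every
    # ratio the tests look at -- are unchanged, but each test's pooled
    # counts stay on their own raw count scale: a single global constraint
    # would shrink F0 counts by ~sqrt(2) and inflate F1 counts by the same
    # factor (the F1 allele channels run at half depth), which under- and
    # over-disperses them relative to the binomial sampling the exact tests
    # assume.
    r <- ncol(sub$channels[[1]])
    pair_cols <- list(F0 = seq_len(2 * r), F1 = 2 * r + seq_len(2 * r))
    sf_test <- sf
    for (cols in pair_cols) sf_test[cols] <- sf[cols] / geomean(sf[cols])
    mats <- sub$channels
    offset <- 0L
    for (ch in names(mats)) {
      idx <- offset + seq_len(ncol(mats[[ch]]))
      mats[[ch]] <- sweep(mats[[ch]], 2, sf_test[idx], "/")
      offset <- offset + ncol(mats[[ch]])
    }
  } else {
    mats <- sub$channels
  }
  # round half-to-even to integers (exact tests need integer counts), then pool
  pooled <- vapply(mats, function(m) rowSums(round(m)), numeric(filt$n_universe))
  if (filt$n_universe == 1L) pooled <- matrix(pooled, nrow = 1,
                                              dimnames = list(NULL, CHANNELS))
  f0A <- pooled[, "F0_A"]; f0B <- pooled[, "F0_B"]
  f1A <- pooled[, "F1_A"]; f1B <- pooled[, "F1_B"]

  n_f0 <- f0A + f0B; n_f1 <- f1A + f1B
  p_f0 <- rep(NA_real_, length(f0A))
  p_f1 <- rep(NA_real_, length(f0A))
  ok0 <- n_f0 > 0; ok1 <- n_f1 > 0
  p_f0[ok0] <- binom_half_two_sided(f0A[ok0], n_f0[ok0])
  p_f1[ok1] <- binom_half_two_sided(f1A[ok1], n_f1[ok1])
  fis <- fisher_two_sided_vec(f0A, f0B, f1A, f1B)
  p_ct <- fis$p
  p_ct[fis$degenerate] <- NA_real_

  records <- data.frame(gene_id = sub$gene_ids,
                        f0_A = f0A, f0_B = f0B, f1_A = f1A, f1_B = f1B,
                        p_f0 = p_f0, p_f1 = p_f1, p_ct = p_ct,
                        q_f0 = bh_fdr(p_f0), q_f1 = bh_fdr(p_f1),
                        q_ct = bh_fdr(p_ct),
                        log2_f0_ratio = log2((f0B + 0.5) / (f0A + 0.5)),
                        log2_f1_ratio = log2((f1B + 0.5) / (f1A + 0.5)),
                        stringsAsFactors = FALSE)
  cls <- classify_genes(records, alpha = alpha)
  table <- cbind(records, cls)

  divergent_cats <- c("cis_only", "trans_only",
                      "cis_trans_enhancing", "cis_trans_compensating")
  n_div <- sum(table$category %in% divergent_cats)
  n_amb <- sum(table$category == "ambiguous")
  denom_universe <- filt$n_universe - n_amb
  pct <- function(x) if (n_div > 0) 100 * x / n_div else NA_real_
  summary <- list(
    n_universe = filt$n_universe,
    n_divergent = n_div,
    n_ambiguous = n_amb,
    pct_divergent = if (denom_universe > 0) 100 * n_div / denom_universe else NA_real_,
    pct_cis = pct(sum(table$category == "cis_only")),
    pct_trans = pct(sum(table$category == "trans_only")),
    pct_cis_trans = pct(sum(table$category %in%
                              c("cis_trans_enhancing", "cis_trans_compensating"))))
  structure(list(table = table, summary = summary, size_factors = sf,
                 alpha = alpha, condition_label = acs$condition_label),
            class = "cistrans_result")
}

#' @export
print.cistrans_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("cistrans_result [%s]: %d genes in universe, %d divergent (%.1f%%)\n",
              x$condition_label, s$n_universe, s$n_divergent, s$pct_divergent))
  cat(sprintf("  of divergent: cis %.1f%%, trans %.1f%%, cis-trans %.1f%%\n",
              s$pct_cis, s$pct_trans, s$pct_cis_trans))
  invisible(x)
}

#' Condition summary for cross-condition comparison
#'
#' Extracts the per-condition quantities needed by the comparison stage:
#' category percentages over divergent genes and the cis/trans gene
#' identifier sets.
#'
#' @param res a \code{cistrans_result}.
#' @return object of class \code{condition_summary}.
#' @export
condition_summary <- function(res) {
  stopifnot(inherits(res, "cistrans_result"))
  tab <- res$table
  structure(list(
    condition_label = res$condition_label,
    n_universe = res$summary$n_universe,
    n_divergent = res$summary$n_divergent,
    pct_cis = res$summary$pct_cis,
    pct_trans = res$summary$pct_trans,
    pct_cis_trans = res$summary$pct_cis_trans,
    cis_gene_ids = tab$gene_id[tab$collapsed == "cis"],
    trans_gene_ids = tab$gene_id[tab$collapsed == "trans"],
    cis_trans_gene_ids = tab$gene_id[tab$collapsed == "cis_trans"],
    universe_ids = tab$gene_id), class = "condition_summary")
}
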