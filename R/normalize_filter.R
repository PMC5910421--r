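# Median-of-ratios library-size normalization and the expressed-gene filter
# that defines the analysis universe.

#' Median-of-ratios size factors
#'
#' Per library j, the size factor is the median over reference genes of
#' count[g, j] / geomean_g, where geomean_g is the geometric mean of gene g
#' across libraries and the reference genes are those with all-positive
#' counts. Factors are then rescaled so their geometric mean is 1, which
#' pins the overall scale (normalized counts stay on the raw count scale).
#'
#' @param count_matrix gene x library matrix of nonnegative counts.
#' @param fallback if no gene has all-positive counts (common in very sparse
#'   data), compute the per-gene reference as the geometric mean over the
#'   positive entries only, using every gene with at least one positive count.
#' @return numeric vector of positive size factors, one per library, with
#'   geometric mean 1; named after the matrix columns.
#' @export
size_factors <- function(count_matrix, fallback = FALSE) {
  m <- as.matrix(count_matrix)
  if (any(m < 0)) ct_input_error("counts must be nonnegative")
  if (ncol(m) == 1L) return(setNames(1, colnames(m)))
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    if (!fallback) {
      ct_input_error(paste("no gene has all-positive counts across libraries;",
                           "rerun with fallback = TRUE to use a positive-count",
                           "pseudo-reference"))
    }
    keep <- rowSums(m > 0) > 0
    logref <- apply(m[keep, , drop = FALSE], 1,
                    function(x) mean(log(x[x > 0])))
    sub <- m[keep, , drop = FALSE]
  } else {
    sub <- m[all_pos, , drop = FALSE]
    logref <- rowMeans(log(sub))
  }
  sf <- apply(sub, 2, function(col) {
    r <- log(col) - logref
    exp(stats::median(r[is.finite(r)]))
  })
  sf <- sf / geomean(sf)
  setNames(sf, colnames(m))
}

#' Normalize a four-channel count set
#'
#' Computes one size factor per channel-replicate column (all 4 x r columns
#' jointly through [size_factors()], so the halved depth of the F1 allele
#' channels is absorbed by their factors and does not distort the F1 allelic
#' ratio) and divides each column by its factor.
#'
#' @param acs an \code{allele_count_set}.
#' @param fallback passed to [size_factors()].
#' @return list: \code{channels} (real-valued normalized matrices),
#'   \code{size_factors} (named per column), \code{gene_ids},
#'   \code{condition_label}.
#' @export
normalize_counts <- function(acs, fallback = FALSE) {
  stopifnot(inherits(acs, "allele_count_set"))
  combined <- do.call(cbind, acs$channels)
  sf <- size_factors(combined, fallback = fallback)
  norm <- acs$channels
  offset <- 0L
  for (ch in names(norm)) {
    idx <- offset + seq_len(ncol(norm[[ch]]))
    norm[[ch]] <- sweep(norm[[ch]], 2, sf[idx], "/")
    offset <- offset + ncol(norm[[ch]])
  }
  list(channels = norm, size_factors = sf,
       gene_ids = acs$gene_ids, condition_label = acs$condition_label)
}

#' Expressed-gene filter defining the analysis universe
#'
#' A gene is kept iff in at least one of the four strain channels (F0 A,
#' F0 B, F1 allele A, F1 allele B) its mean raw count across replicate
#' libraries strictly exceeds \code{threshold} reads. The count of retained
#' genes is the analysis universe for the cis/trans classification.
#'
#' @param acs an \code{allele_count_set} (raw counts).
#' @param threshold expression cutoff in reads (default 10; strict >).
#' @return list: \code{mask} (logical per gene), \code{n_universe}
#'   (retained-gene count).
#' @export
expression_filter <- function(acs, threshold = 10) {
  stopifnot(inherits(acs, "allele_count_set"))
  means <- vapply(acs$channels, rowMeans, numeric(length(acs$gene_ids)))
  if (length(acs$gene_ids) == 1L) means <- matrix(means, nrow = 1)
  mask <- apply(means > threshold, 1, any)
  list(mask = unname(mask), n_universe = sum(mask))
}
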