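# Transcription-factor binding-site enrichment with the dual statistic used
# by oPOSSUM-style tools: a nucleotide-level binomial Z-score (are there more
# hits per scanned base in the foreground than expected from the background
# rate?) and a gene-level Fisher score (-ln of the one-tailed Fisher exact
# p-value on gene presence/absence). A motif is called significantly
# enriched only when both exceed their cutoffs (defaults Z > 10, Fisher > 7,
# both strict).

#' Nucleotide-level binomial Z-score for motif enrichment
#'
#' With background hit rate p = bg_hits / bg_len, the expected foreground
#' hit count is mu = fg_len * p and
#' \deqn{z = (fg\_hits - \mu) / \sqrt{fg\_len\, p (1 - p)}.}
#' When the background has no hits, p is continuity-corrected to
#' 0.5 / bg_len so z stays finite. z is signed (negative = depletion).
#'
#' @param fg_hits,bg_hits total motif hit counts (vectorized over motifs).
#' @param fg_len,bg_len total scanned bases in foreground / background.
#' @return Z-score(s).
#' @export
motif_z_score <- function(fg_hits, fg_len, bg_hits, bg_len) {
  if (any(fg_len <= 0) || any(bg_len <= 0)) {
    ct_config_error("scanned lengths must be positive")
  }
  p <- bg_hits / bg_len
  p <- ifelse(p <= 0, 0.5 / bg_len, pmin(p, 1 - 0.5 / bg_len))
  mu <- fg_len * p
  (fg_hits - mu) / sqrt(fg_len * p * (1 - p))
}

#' Gene-level Fisher score for motif enrichment
#'
#' One-tailed (enrichment direction) Fisher exact p-value on the 2x2 table
#' [[fg_with, fg_without], [bg_with, bg_without]] via the hypergeometric
#' upper tail, reported as -ln(p).
#'
#' @param fg_with,fg_total genes with >= 1 hit / total genes, foreground.
#' @param bg_with,bg_total same for the background (vectorized over motifs).
#' @return Fisher score(s) = -ln(one-tailed p), >= 0.
#' @export
motif_fisher_score <- function(fg_with, fg_total, bg_with, bg_total) {
  if (any(fg_total <= 0) || any(bg_total <= 0)) {
    ct_config_error("gene totals must be positive")
  }
  if (any(fg_with > fg_total) || any(bg_with > bg_total)) {
    ct_config_error("genes with hits cannot exceed the total")
  }
  # P(X >= fg_with), X ~ Hypergeometric(with, without, fg_total)
  p <- stats::phyper(fg_with - 1, fg_with + bg_with,
                     (fg_total - fg_with) + (bg_total - bg_with),
                     fg_total, lower.tail = FALSE)
  -log(pmax(p, .Machine$double.xmin))
}

#' Score motif enrichment of a foreground gene set against a background
#'
#' Computes both statistics per motif from [simulate_motif_hits()]-style hit
#' tables: the Z-score from hits and scanned lengths pooled over genes, the
#' Fisher score from gene-level presence (>= 1 hit). A motif is significant
#' iff Z > \code{z_cut} and Fisher > \code{f_cut}, both strict. Results are
#' ordered by Fisher score, descending (the ranking statistic).
#'
#' @param fg,bg data.frames with columns gene_id, scanned_length and one
#'   hit-count column per motif (same motif set in both).
#' @param z_cut,f_cut significance cutoffs (defaults 10 and 7).
#' @return data.frame: motif, fg_hits, bg_hits, fg_genes_with_hit,
#'   bg_genes_with_hit, z_score, fisher_score, significant; sorted by
#'   fisher_score descending.
#' @export
motif_enrich <- function(fg, bg, z_cut = 10, f_cut = 7) {
  meta <- c("gene_id", "set_label", "scanned_length")
  motifs_fg <- setdiff(names(fg), meta)
  motifs_bg <- setdiff(names(bg), meta)
  if (!setequal(motifs_fg, motifs_bg) || length(motifs_fg) == 0L) {
    ct_input_error("foreground and background must share a nonempty motif set")
  }
  if (!"scanned_length" %in% names(fg) || !"scanned_length" %in% names(bg)) {
    ct_input_error("hit tables need a scanned_length column")
  }
  if (any(fg$scanned_length <= 0) || any(bg$scanned_length <= 0)) {
    ct_config_error("scanned_length must be positive")
  }
  motifs <- motifs_fg
  fg_len <- sum(fg$scanned_length); bg_len <- sum(bg$scanned_length)
  fg_hits <- vapply(motifs, function(m) sum(fg[[m]]), numeric(1))
  bg_hits <- vapply(motifs, function(m) sum(bg[[m]]), numeric(1))
  fg_with <- vapply(motifs, function(m) sum(fg[[m]] > 0), numeric(1))
  bg_with <- vapply(motifs, function(m) sum(bg[[m]] > 0), numeric(1))
  z <- motif_z_score(fg_hits, fg_len, bg_hits, bg_len)
  f <- motif_fisher_score(fg_with, nrow(fg), bg_with, nrow(bg))
  out <- data.frame(motif = motifs,
                    fg_hits = fg_hits, bg_hits = bg_hits,
                    fg_genes_with_hit = fg_with, bg_genes_with_hit = bg_with,
                    z_score = z, fisher_score = f,
                    significant = z > z_cut & f > f_cut,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$fisher_score), , drop = FALSE]
}
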