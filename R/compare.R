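# Cross-condition comparison of regulatory architecture: unique trans-gene
# sets after excluding the intersection, and category-proportion contrasts
# (e.g. trans fraction in amygdala vs prefrontal cortex, or stressed vs
# unstressed cortex).

#' Restrict two classification results to their shared gene universe
#'
#' Set operations and proportion contrasts are only well defined over a
#' common universe; this keeps the genes retained by BOTH conditions'
#' expression filters and recomputes each condition's summary on that
#' intersection (tests and categories are not recomputed; genes outside the
#' intersection are dropped).
#'
#' @param a,b \code{cistrans_result} objects.
#' @return list of two \code{condition_summary} objects on the shared
#'   universe.
#' @export
shared_universe <- function(a, b) {
  stopifnot(inherits(a, "cistrans_result"), inherits(b, "cistrans_result"))
  common <- intersect(a$table$gene_id, b$table$gene_id)
  restrict <- function(res) {
    res$table <- res$table[res$table$gene_id %in% common, , drop = FALSE]
    divergent_cats <- c("cis_only", "trans_only",
                        "cis_trans_enhancing", "cis_trans_compensating")
    n_div <- sum(res$table$category %in% divergent_cats)
    n_amb <- sum(res$table$category == "ambiguous")
    res$summary$n_universe <- nrow(res$table)
    res$summary$n_divergent <- n_div
    res$summary$n_ambiguous <- n_amb
    res$summary$pct_divergent <-
      if (nrow(res$table) - n_amb > 0) 100 * n_div / (nrow(res$table) - n_amb) else NA_real_
    pct <- function(x) if (n_div > 0) 100 * x / n_div else NA_real_
    res$summary$pct_cis <- pct(sum(res$table$category == "cis_only"))
    res$summary$pct_trans <- pct(sum(res$table$category == "trans_only"))
    res$summary$pct_cis_trans <- pct(sum(res$table$category %in%
                                           c("cis_trans_enhancing", "cis_trans_compensating")))
    condition_summary(res)
  }
  list(a = restrict(a), b = restrict(b))
}

check_same_universe <- function(a, b) {
  if (!inherits(a, "condition_summary") || !inherits(b, "condition_summary")) {
    ct_config_error("inputs must be condition_summary objects")
  }
  if (!setequal(a$universe_ids, b$universe_ids)) {
    ct_input_error(paste("condition summaries come from different gene universes;",
                         "restrict with shared_universe() first"))
  }
}

#' Unique and shared trans-regulated gene sets between two conditions
#'
#' Splits the trans-gene identifier sets of two conditions into
#' condition-exclusive sets and their intersection (the sets fed to
#' downstream enrichment). The three sets are disjoint and their union
#' reconstructs the originals.
#'
#' @param a,b \code{condition_summary} objects over the same universe.
#' @return list: \code{a_only}, \code{b_only}, \code{shared} (character
#'   vectors of gene ids).
#' @export
unique_trans_sets <- function(a, b) {
  check_same_universe(a, b)
  shared <- intersect(a$trans_gene_ids, b$trans_gene_ids)
  list(a_only = setdiff(a$trans_gene_ids, shared),
       b_only = setdiff(b$trans_gene_ids, shared),
       shared = shared)
}

#' Category-proportion contrast between two conditions
#'
#' Per collapsed category (cis, trans, cis_trans), the fold ratio of the two
#' conditions' percentages among divergent genes, plus a two-sided Fisher
#' exact test on the 2x2 table [in category vs not] x [condition a vs b]
#' over each condition's divergent genes. The test is an uncertainty
#' statement added by this package (the proportions themselves carry none).
#'
#' @param a,b \code{condition_summary} objects over the same universe.
#' @return data.frame: category, pct_a, pct_b, fold_ratio (a over b;
#'   Inf when b has no such gene), p_value.
#' @export
proportion_contrast <- function(a, b) {
  check_same_universe(a, b)
  if (a$n_divergent == 0 || b$n_divergent == 0) {
    ct_config_error("both conditions need at least one divergent gene")
  }
  cats <- c(cis = "cis_gene_ids", trans = "trans_gene_ids",
            cis_trans = "cis_trans_gene_ids")
  rows <- lapply(names(cats), function(cat) {
    ka <- length(a[[cats[[cat]]]]); kb <- length(b[[cats[[cat]]]])
    pa <- 100 * ka / a$n_divergent; pb <- 100 * kb / b$n_divergent
    ratio <- if (pb == 0) Inf else pa / pb
    tab <- matrix(c(ka, a$n_divergent - ka, kb, b$n_divergent - kb), nrow = 2)
    p <- stats::fisher.test(tab)$p.value
    data.frame(category = cat, pct_a = pa, pct_b = pb,
               fold_ratio = ratio, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "conditions") <- c(a = a$condition_label, b = b$condition_label)
  out
}
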