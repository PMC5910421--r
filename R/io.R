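# File contracts and end-to-end orchestration. All tables are tab-separated
# with a single header row; floats are serialized with 6 significant digits;
# gene order is preserved from input, so reruns are byte-identical and
# diff-able.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == floor(x) & abs(x) < 1e15 & is.finite(x),
                format(x, scientific = FALSE, trim = TRUE),
                format(signif(x, 6), trim = TRUE)))
}

write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
    if (is.factor(out[[j]])) out[[j]] <- as.character(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a four-channel count set as tab-separated text
#'
#' One row per gene; columns \code{gene_id} then \code{<channel>_rep<k>} for
#' the four channels F0_A, F0_B, F1_A, F1_B. The reader validates the header
#' and count values and reports the offending file/column/line on failure.
#'
#' @param acs an \code{allele_count_set}.
#' @param path output / input file path.
#' @return \code{write_count_set}: the path, invisibly.
#' @export
write_count_set <- function(acs, path) {
  stopifnot(inherits(acs, "allele_count_set"))
  df <- data.frame(gene_id = acs$gene_ids, stringsAsFactors = FALSE)
  for (ch in CHANNELS) {
    m <- acs$channels[[ch]]
    colnames(m) <- paste0(ch, "_rep", seq_len(ncol(m)))
    df <- cbind(df, as.data.frame(m, row.names = NULL))
  }
  write_tsv(df, path)
}

#' @rdname write_count_set
#' @param condition_label condition tag attached to the read count set.
#' @export
read_count_set <- function(path, condition_label = NULL) {
  if (!file.exists(path)) ct_input_error(sprintf("count file not found: %s", path))
  df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
                 error = function(e) ct_input_error(sprintf("%s: cannot parse: %s",
                                                            path, conditionMessage(e))))
  if (nrow(df) == 0L || !"gene_id" %in% names(df)) {
    ct_input_error(sprintf("%s: expected a nonempty table with a gene_id column", path))
  }
  channels <- setNames(vector("list", 4), CHANNELS)
  for (ch in CHANNELS) {
    cols <- grep(sprintf("^%s_rep[0-9]+$", ch), names(df), value = TRUE)
    if (length(cols) == 0L) {
      ct_input_error(sprintf("%s: no columns found for channel %s (expected %s_rep<k>)",
                             path, ch, ch))
    }
    cols <- cols[order(as.integer(sub(".*_rep", "", cols)))]
    m <- as.matrix(df[cols])
    if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m != floor(m))) {
      bad <- which(!is.finite(m) | m < 0 | m != floor(m), arr.ind = TRUE)[1, ]
      ct_input_error(sprintf("%s: column %s line %d is not a nonnegative integer",
                             path, cols[bad[2]], bad[1] + 1L))
    }
    channels[[ch]] <- m
  }
  reps <- unique(vapply(channels, ncol, integer(1)))
  if (length(reps) != 1L) {
    ct_input_error(sprintf("%s: channels have unequal replicate counts", path))
  }
  allele_count_set(channels, df$gene_id,
                   condition_label %||% tools::file_path_sans_ext(basename(path)))
}

#' Write simulation truth / SNP tables as tab-separated text
#'
#' @param df the truth or SNP data.frame.
#' @param path output file.
#' @export
write_table_tsv <- function(df, path) write_tsv(df, path)

#' Pipeline run configuration
#'
#' @param counts path to a four-channel count table (see [read_count_set()]).
#' @param out output directory (created if missing).
#' @param alpha per-family FDR threshold in (0, 1).
#' @param min_count expression-filter cutoff (>= 0).
#' @param normalize apply median-of-ratios normalization.
#' @param condition_label condition tag (defaults to the count file name).
#' @param seed recorded in the run log (the classification itself is
#'   deterministic given its inputs).
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(counts, out, alpha = 0.01, min_count = 10,
                       normalize = TRUE, condition_label = NULL, seed = 1L) {
  stopifnot_scalar_prob(alpha, "alpha")
  if (!is.numeric(min_count) || length(min_count) != 1L || min_count < 0) {
    ct_config_error("min_count must be a single nonnegative number")
  }
  structure(list(counts = counts, out = out, alpha = alpha,
                 min_count = min_count, normalize = isTRUE(normalize),
                 condition_label = condition_label, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the classification pipeline end to end
#'
#' Reads the count table, classifies every gene, and writes to the output
#' directory: \code{classification.tsv} (the per-gene table),
#' \code{summary.json} (n_universe, n_divergent, pct_cis, pct_trans,
#' pct_cis_trans, ...; plus the size factors and run parameters),
#' \code{scatter.tsv} (log2 F0 ratio vs log2 F1 ratio with the category, the
#' coordinates of the classic cis/trans scatter), and \code{run.log}. Given
#' identical inputs and parameters the outputs are byte-identical.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages (they also go to the log file).
#' @return the \code{cistrans_result}, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  say("run_pipeline: counts=%s alpha=%g min_count=%g normalize=%s seed=%d",
      config$counts, config$alpha, config$min_count, config$normalize, config$seed)
  acs <- read_count_set(config$counts, config$condition_label)
  say("read %d genes x %d replicates [%s]",
      length(acs$gene_ids), ncol(acs$channels[[1]]), acs$condition_label)
  res <- classify_counts(acs, alpha = config$alpha, min_count = config$min_count,
                         normalize = config$normalize)
  s <- res$summary
  say("universe %d, divergent %d (%.2f%%): cis %.2f%% trans %.2f%% cis-trans %.2f%%",
      s$n_universe, s$n_divergent, s$pct_divergent, s$pct_cis, s$pct_trans,
      s$pct_cis_trans)
  write_tsv(res$table, file.path(config$out, "classification.tsv"))
  write_tsv(res$table[, c("gene_id", "log2_f0_ratio", "log2_f1_ratio",
                          "category", "collapsed")],
            file.path(config$out, "scatter.tsv"))
  payload <- c(s, list(alpha = res$alpha,
                       condition_label = res$condition_label,
                       size_factors = as.list(res$size_factors %||% list())))
  jsonlite::write_json(payload, file.path(config$out, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(log_lines, log_path)
  invisible(res)
}
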