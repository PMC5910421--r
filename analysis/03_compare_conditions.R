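#!/usr/bin/env Rscript
# Cross-condition contrasts over the shared gene universe: amygdala vs
# unstressed PFC, and stressed vs unstressed PFC. Reports per-category fold
# ratios with Fisher tests, and writes the unique/shared trans gene sets
# (one id per line, consumable by enrichment tools).

suppressMessages(library(cistrans))

reclassify <- function(lab) {
  acs <- read_count_set(sprintf("results/data/counts_%s.tsv", lab), lab)
  classify_counts(acs)
}
pfc <- reclassify("pfc")
amy <- reclassify("amygdala")
str <- reclassify("stressed_pfc")
dir.create("results/compare", showWarnings = FALSE, recursive = TRUE)

contrast <- function(a, b, name) {
  su <- shared_universe(a, b)
  pc <- proportion_contrast(su$a, su$b)
  message(sprintf("-- %s (universe %d) --", name, length(su$a$universe_ids)))
  for (i in seq_len(nrow(pc))) {
    message(sprintf("  %-9s %5.1f%% vs %5.1f%%  fold %.2f  p = %.3g",
                    pc$category[i], pc$pct_a[i], pc$pct_b[i],
                    pc$fold_ratio[i], pc$p_value[i]))
  }
  sets <- unique_trans_sets(su$a, su$b)
  base <- file.path("results/compare", name)
  writeLines(sets$a_only, paste0(base, "_trans_a_only.txt"))
  writeLines(sets$b_only, paste0(base, "_trans_b_only.txt"))
  writeLines(sets$shared, paste0(base, "_trans_shared.txt"))
  jsonlite::write_json(
    list(conditions = attr(pc, "conditions"), contrast = pc,
         n_trans_a_only = length(sets$a_only),
         n_trans_b_only = length(sets$b_only),
         n_trans_shared = length(sets$shared)),
    paste0(base, "_contrast.json"), auto_unbox = TRUE, digits = 6, pretty = TRUE)
  invisible(pc)
}

contrast(amy, pfc, "amygdala_vs_pfc")
contrast(str, pfc, "stressed_vs_unstressed_pfc")
message("wrote contrasts and trans gene sets to results/compare/")
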