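#!/usr/bin/env Rscript
# Classify each simulated condition: expression filter, median-of-ratios
# normalization, the three exact tests per gene, BH-FDR at 0.01 per family,
# category assignment. Writes per-condition run directories under results/.

suppressMessages(library(cistrans))

for (lab in c("pfc", "amygdala", "stressed_pfc")) {
  counts <- sprintf("results/data/counts_%s.tsv", lab)
  if (!file.exists(counts)) stop("run analysis/01_simulate_conditions.R first")
  res <- run_pipeline(run_config(counts, sprintf("results/classify_%s", lab),
                                 alpha = 0.01, min_count = 10,
                                 condition_label = lab))
  s <- res$summary
  message(sprintf(
    "%s: universe %d, divergent %d (%.1f%%) -> cis %.1f%% / trans %.1f%% / cis-trans %.1f%%",
    lab, s$n_universe, s$n_divergent, s$pct_divergent,
    s$pct_cis, s$pct_trans, s$pct_cis_trans))
}
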