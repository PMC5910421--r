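#!/usr/bin/env Rscript
# Simulate the three-condition study: four-channel F0/F1 counts for an
# unstressed prefrontal-cortex-like condition, an unstressed amygdala-like
# condition, and a stressed prefrontal-cortex-like condition. Each plants
# 20% divergent genes with condition-specific cis/trans/cis-trans splits
# (84/8/8, 55/32/13, 59/25/15 to the nearest percent). Writes count tables
# and truth tables under results/data/.

suppressMessages(library(cistrans))
seed <- 20260926L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

splits <- list(
  pfc          = c(cis = 0.84, trans = 0.08, ct = 0.08),
  amygdala     = c(cis = 0.55, trans = 0.32, ct = 0.13),
  stressed_pfc = c(cis = 0.59 / 0.99, trans = 0.25 / 0.99, ct = 0.15 / 0.99))

for (i in seq_along(splits)) {
  lab <- names(splits)[i]
  sp <- splits[[i]]
  props <- c(conserved = 0.8, cis_only = 0.2 * sp[["cis"]],
             trans_only = 0.2 * sp[["trans"]], cis_trans = 0.2 * sp[["ct"]])
  cfg <- sim_config(n_genes = 5000, category_proportions = props,
                    baseline_log2_mean = 9, baseline_log2_sd = 0.5,
                    dispersion = 0, cis_effect_log2 = c(1, 2),
                    trans_effect_log2 = c(1, 2), seed = seed + i)
  sim <- simulate_counts(cfg, lab)
  write_count_set(sim$counts, sprintf("results/data/counts_%s.tsv", lab))
  write_table_tsv(sim$truth, sprintf("results/data/truth_%s.tsv", lab))
  message(sprintf("%s: %d genes, planted divergent %.0f%% (cis %.0f%% / trans %.0f%% / cis-trans %.0f%% of divergent)",
                  lab, cfg$n_genes, 100 * (1 - props[["conserved"]]),
                  100 * sp[["cis"]], 100 * sp[["trans"]], 100 * sp[["ct"]]))
}
message("wrote count and truth tables to results/data/")
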