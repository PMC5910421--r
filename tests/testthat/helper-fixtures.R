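# Small fixture builders shared across test files.

# hand-built count set: 4 genes x 2 replicates
tiny_count_set <- function() {
  mk <- function(v) matrix(as.integer(v), nrow = 4, ncol = 2)
  allele_count_set(list(F0_A = mk(c(100, 12, 0, 200, 100, 12, 0, 200)),
                        F0_B = mk(c(100, 0, 0, 50, 100, 0, 0, 50)),
                        F1_A = mk(c(50, 0, 0, 100, 50, 0, 0, 100)),
                        F1_B = mk(c(50, 0, 0, 25, 50, 0, 0, 25))),
                   sprintf("g%d", 1:4), "tiny")
}

# simulated fixture under the Poisson regime used by the property tests
sim_fixture <- function(n_genes = 800, seed = 1, dispersion = 0,
                        props = c(conserved = 0.7, cis_only = 0.15,
                                  trans_only = 0.1, cis_trans = 0.05),
                        mean_log2 = 9, sd_log2 = 0.5,
                        effects = c(1, 2), label = "fixture") {
  cfg <- sim_config(n_genes = n_genes, category_proportions = props,
                    baseline_log2_mean = mean_log2, baseline_log2_sd = sd_log2,
                    dispersion = dispersion,
                    cis_effect_log2 = effects, trans_effect_log2 = effects,
                    seed = seed)
  simulate_counts(cfg, label)
}
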