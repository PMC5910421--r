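Package: cistrans
Title: Cis/Trans Regulatory-Divergence Analysis from F0/F1 Allele-Specific Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies genes into cis, trans and cis-trans regulatory-divergence
    categories from four-channel read counts (two parental F0 strains and the two
    alleles of their F1 hybrid) using per-gene binomial exact tests, a Fisher exact
    ratio-heterogeneity test and Benjamini-Hochberg FDR control; contrasts category
    proportions across tissues or conditions; scores transcription-factor binding-site
    enrichment with a dual Z-score/Fisher-score statistic; and validates allele
    assignment from raw reads by exact SNP-window counting. Ships a synthetic-data
    generator with planted ground truth (negative-binomial counts, error-free reads,
    Poisson motif hits) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
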