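---
title: "Classifying cis and trans regulatory divergence from F0/F1 allele-specific expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cis and trans regulatory divergence from F0/F1 allele-specific expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The design and its logic

Cross two genetically distant inbred strains (the F0 parents, here called A
and B) and measure, by RNA-seq, four count channels per gene: expression in
each parent, and the expression of each parental allele inside the F1 hybrid
(allele-resolved via strain-discriminating SNPs). The two F1 alleles sit in
the same nuclei, so every diffusible regulator acts on both equally:

* a **cis-acting** difference (enhancer variant, local epigenetic mark)
  travels with the allele — it appears both as a parental (F0) expression
  difference and as an allelic imbalance inside the F1;
* a **trans-acting** difference (transcription factor abundance, ncRNA)
  is shared by both F1 alleles — it appears between the parents but leaves
  the F1 allelic ratio at 1:1, making the F0 and F1 ratios *heterogeneous*.

`cistrans` implements this decomposition as three per-gene exact tests on
pooled counts, FDR control per test family, and a category assignment, plus
the surrounding stages: an expressed-gene filter, median-of-ratios
normalization, cross-condition contrasts, a dual-statistic motif-site
enrichment score, read-level validation by exact SNP-window counting, and a
synthetic-data generator that plants ground truth for all of it.

## Statistical model

Let $(a_0, b_0)$ be the pooled, normalized, integer parental counts of a
gene and $(a_1, b_1)$ the pooled F1 allele counts.

1. **F0 divergence**: two-sided binomial exact test of $a_0$ out of
   $a_0+b_0$ against $p_0 = 1/2$ (after per-library normalization, equal
   expression corresponds to a balanced split).
2. **F1 allelic imbalance** (cis evidence): the same test on $(a_1, b_1)$.
3. **Ratio heterogeneity** (trans evidence): two-sided Fisher exact test on
   $[[a_0, b_0], [a_1, b_1]]$.

Both exact tests use the point-mass rule: the two-sided $p$ is the sum of
all outcome probabilities not exceeding the observed outcome's probability
(with the customary $1 + 10^{-7}$ relative tie tolerance; at $p_0 = 1/2$
the binomial case reduces to an exact symmetric closed form). The Fisher
test exploits unimodality of the hypergeometric pmf: the two tail
boundaries are located by binary search and summed with `phyper`, so
genome-scale batches cost logarithmic work per gene; an exhaustive-scan
implementation is retained internally and the two are held equal to
$10^{-12}$ in the tests, with both checked against brute-force enumeration
oracles on all tables with margins up to 30.

Each family of raw p-values is Benjamini–Hochberg adjusted separately and
thresholded at $q < \alpha$ (default $\alpha = 0.01$, strict, per family —
a joint correction across families is deliberately not applied). With
$S_0, S_1, S_C$ the three significance indicators:

| $S_0$ | $S_1$ | $S_C$ | category |
|---|---|---|---|
| 1 | 1 | 0 | cis_only |
| 1 | 0 | 1 | trans_only |
| 1 | 1 | 1 | cis_trans (enhancing / compensating) |
| 0 | 1 | 1 | compensatory |
| 0 | 0 | 0 | conserved |
| — | — | — | ambiguous (all other patterns) |

cis-trans genes are subtyped *enhancing* when the F0 log-ratio exceeds the
F1 log-ratio in magnitude with the same sign (trans reinforces cis) and
*compensating* otherwise. The collapsed reporting scheme maps cis_only →
cis, trans_only → trans, both cis_trans subtypes → cis_trans, everything
else → not_divergent. Summary percentages are computed over divergent genes
(the four $S_0$-true resolved categories); ambiguous genes are excluded
from both the category denominators and the divergent-fraction denominator.
Missing q-values (a gene with an empty pooled channel) count as not
significant rather than erroring.

Log2 ratios are reported B over A with a pseudocount of 0.5 per pooled
count — display coordinates for the classic scatter only; tests always use
the unpseudocounted integers.

## Normalization and filtering

A gene enters the analysis universe if, in at least one of the four
channels, its mean raw count across replicate libraries strictly exceeds
`min_count` (default 10 reads). The filter is applied to raw counts, is
monotone in every count, and fixes the denominator for the divergent
fraction.

Size factors use the median-of-ratios method: per library, the median over
all-positive genes of the count over the gene's geometric mean, rescaled to
geometric mean 1 (`size_factors()`; a positive-count pseudo-reference
fallback is available for sparse data). Each of the $4 \times r$
channel-replicate columns gets its own factor, because the F1 allele
channels run at roughly half the read depth of the F0 channels — a shared
factor per library would systematically distort the F1 allelic ratio.

One consequence required a design choice. A *single* global geometric-mean
constraint parks the F0/F1 depth gap inside the factors themselves
(F0 columns ≈ $\sqrt2$, F1 columns ≈ $1/\sqrt2$), so normalized F0 counts
shrink and F1 counts inflate relative to their raw scale. Scaled counts
fed to an exact test are no longer binomially dispersed — dividing a count
by $s$ divides its mean by $s$ but its variance by $s^2$ — and the raw
p-value distribution becomes visibly non-uniform under the null.
`classify_counts()` therefore rescales the factors to geometric mean 1
*within each generation's channel pair* (F0_A+F0_B, F1_A+F1_B) before
pooling. Relative factors, and hence every ratio the three tests compare,
are identical; each test's pooled counts simply stay on their own raw
count scale. The reported size-factor vector keeps the conventional global
geometric-mean-1 normalization.

Normalized counts are rounded half-to-even to integers (exact tests need
integers) and summed across replicates per channel before testing.
Replicate-to-replicate variance therefore does not enter the tests
directly — see Limitations.

## The synthetic-data generator

`simulate_counts()` draws, per gene, a log-normal baseline $\mu$
(`baseline_log2_mean`, `baseline_log2_sd`), assigns a category, plants cis
and trans log2 effects $c, t$, and samples negative-binomial counts
(variance $\mu + \alpha\mu^2$; $\alpha = 0$ gives Poisson) around the mean
structure

$$E[F0_A] = s\mu, \quad E[F0_B] = s\mu\,2^{c+t}, \quad
  E[F1_A] = s\mu/2, \quad E[F1_B] = (s\mu/2)\,2^{c},$$

with an independent planted size factor $s$ per channel-replicate column.
Choices worth knowing:

* **Category counts are exact.** Proportions are apportioned by largest
  remainder and assigned to genes by a seeded permutation, not drawn
  multinomially, so a planted 8% trans fraction is exactly 8% and contrast
  experiments measure estimation error, not planting noise.
* **Effects** are drawn uniformly from a magnitude range (default
  $[0.5, 2]$ log2 units — a fixture choice, not an empirical claim about
  mouse brain) with random sign, and attached to the B allele.
* **Defaults**: 3 replicate libraries per group (a pooled-library design),
  baseline log2 mean 8 and sd 1.5 (a few hundred reads per gene per
  library), dispersion 0.01 (low, as expected when each library pools
  several inbred animals), size factors in $[0.7, 1.4]$, and 80%
  conserved genes with the divergent remainder split 84/8/8 between
  cis-only, trans-only and cis-trans.
* **Not simulated**: reciprocal-cross/parent-of-origin effects (the design
  pools cross directions), mapping bias, sequencing error, isoform
  structure.
* Each generator derives a private RNG stream from its seed and restores
  the caller's RNG state, so outputs are bitwise reproducible and adding
  genes to one stage never perturbs another.

`simulate_reads()` emulates targeted amplicon sequencing: per gene, two
equal-length allele windows differing at `snps_per_gene` SNPs are embedded
in an amplicon of read length; per replicate, exactly `depth` error-free
reads are emitted, split between alleles deterministically by the allelic
ratio $2^{c}/(1+2^{c})$ implied by the planted cis effect. The emitted
counts are the ground truth the counter must recover exactly.
`simulate_motif_hits()` draws Poisson hit counts at a background rate per
scanned base, multiplying the rate for one planted motif in the foreground
set only.

### What the simulation does and does not establish

The independent negative-binomial draws per channel mean that even the F1
allelic ratio is overdispersed relative to binomial sampling when
$\alpha > 0$ — in real hybrids much of the biological variance is shared
between the two alleles of a library, so this is conservative for the F1
test. More importantly, the pooled exact tests model count-level sampling
only. The package's calibration and recovery properties are therefore
assessed in the generator's Poisson regime ($\alpha = 0$), where the
binomial/hypergeometric conditioning is exact: FDR calibration and raw-p
uniformity on 5,000 all-conserved genes over 50 seeds (equal library
depths, baseline log2 mean 12 — deep counts, so that the discrete atom of
exact p-values at 1, of size about $0.9/\sqrt{n}$, sits below the
resolution of a 5,000-gene uniformity check); category recovery on 2,000
genes over 20 seeds (effects of at least 1 log2 unit, pooled depth above
500 per channel); and a planted four-fold trans-fraction contrast on 5,000
genes over 50 seed pairs. Passing them shows the machinery is correct
under its own sampling assumptions; it does not show robustness to
overdispersed real data (see Limitations).

## Cross-condition comparison

Set operations and proportion contrasts are defined over the genes
retained by *both* conditions' filters (`shared_universe()`), after which
`unique_trans_sets()` partitions the trans gene sets into
condition-exclusive sets and their intersection, and
`proportion_contrast()` reports, per collapsed category, the fold ratio of
percentages among divergent genes. The paper-style contrast itself carries
no uncertainty statement; the accompanying two-sided Fisher test on
[category vs not] × [condition] over divergent genes is an addition of
this package and is labelled as such in the output.

## Motif-site enrichment

For each motif, two statistics compare a foreground gene set against a
background, consuming precomputed hit tables (motif scanning against a
real database is out of scope):

* **Z-score** (nucleotide level): with background rate
  $p = \mathrm{hits}_{bg}/\mathrm{len}_{bg}$, expected foreground hits
  $\mu = \mathrm{len}_{fg}\,p$, and
  $z = (\mathrm{hits}_{fg} - \mu)/\sqrt{\mathrm{len}_{fg}\,p(1-p)}$.
  A hitless background is continuity-corrected to half a hit. $z$ is
  signed; it scales as $\sqrt2$ when counts and lengths double at fixed
  rates.
* **Fisher score** (gene level): $-\ln$ of the one-tailed (enrichment)
  Fisher exact p on presence/absence counts.

A motif is significantly enriched only when $z > 10$ **and** the Fisher
score exceeds 7, both strict — deliberately extreme cutoffs; the null
false-positive rate at these cutoffs is below 1% by a wide margin.
Results rank by Fisher score.

## Read-level validation

`count_alleles()` reproduces the command-line practice of counting exact
occurrences of allele-discriminating subsequences directly in FASTQ: a
read increments allele A of gene g iff the gene's A window occurs as an
exact substring (matching by `Biostrings::vcountPattern`). Because
amplicon sequencing reads either strand, the reverse complement of each
window is searched too by default; `search_revcomp = FALSE` restores the
orientation-naive behavior. A read matching both alleles of one gene is
discarded into a conflict tally; a read matching two different genes
counts for both (per-gene counters are independent) with a warning.
Malformed FASTQ records fail hard with the record index.

`allelic_balance_test()` then applies a two-tailed one-sample t-test of
the per-replicate allele-A fractions against 0.5. Conventions at the
edges: fewer than two replicates with reads is `insufficient_data`;
zero-variance fractions give $p = 1$ at the null and $p = 0$ off it
(continuity of the decision rule); verdicts are `allele_biased` below
0.001 (the display threshold), `balanced` at or above 0.05, and
`indeterminate` between.

## Numerical and interface conventions

* Ties at $q = \alpha$ and at both enrichment cutoffs: strict inequality.
* Degenerate Fisher tables (a zero margin) return $p = 1$, flagged.
* BH adjustment propagates NA p-values and excludes them from the ranking.
* All tables are tab-separated with one header row, floats at 6
  significant digits, gene order preserved — reruns are byte-identical.
  Configuration errors and input-format errors are distinct condition
  classes (`ct_config_error`, `ct_input_error`).
* The analysis workflow under `analysis/` (simulate → classify → compare →
  enrich → validate) is the package's own worked study at 5,000 genes per
  condition; every computation in it lives in exported functions.

## Limitations

* **Replicate variance.** Pooling counts across replicates before exact
  testing discards between-library variance; with overdispersed data the
  tests are anticonservative and cis genes leak into cis_trans (the Fisher
  test picks up noise as ratio heterogeneity). A replicate-aware
  beta-binomial or count GLM would address this but is a different method
  from the one implemented here.
* The expressed-gene universe of any real dataset depends on filtering
  semantics the threshold phrase alone does not pin down; here the rule is
  fixed as channel-mean, strict inequality.
* Exact substring counting tolerates zero mismatches; real amplicon reads
  with sequencing errors would undercount both alleles equally.
* The enrichment module consumes hit tables; it does not scan sequences,
  construct conserved-region backgrounds, or correct for GC content.
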