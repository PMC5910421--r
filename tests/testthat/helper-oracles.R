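# Independent brute-force oracles for the exact tests, kept deliberately
# separate from the package's computation paths.

# Two-sided binomial p-value at p0 = 1/2 by exact dyadic arithmetic:
# choose(n, j) is an exact integer for n <= 30 and division by 2^n is exact
# in doubles, so point masses and their comparisons involve no rounding.
oracle_binom_half <- function(k, n) {
  w <- choose(n, 0:n)
  sum(w[w <= w[k + 1]]) / 2^n
}

# Two-sided Fisher p-value by full-table enumeration with integer weights
# w(x) = choose(R1, x) * choose(R2, C1 - x) (proportional to the
# hypergeometric masses). Weight comparisons use a 1e-12 relative band to
# absorb the ~1 ulp error of products near 2^53.
oracle_fisher_two_sided <- function(a, b, c, d) {
  R1 <- a + b; R2 <- c + d; C1 <- a + c
  if (R1 == 0 || R2 == 0 || C1 == 0 || (b + d) == 0) return(1)
  x <- max(0, C1 - R2):min(R1, C1)
  w <- choose(R1, x) * choose(R2, C1 - x)
  wobs <- choose(R1, a) * choose(R2, c)
  sum(w[w <= wobs * (1 + 1e-12)]) / sum(w)
}

# one-tailed (enrichment) Fisher p by explicit upper-tail mass summation
oracle_fisher_upper <- function(fg_with, fg_total, bg_with, bg_total) {
  tot_with <- fg_with + bg_with
  tot_without <- (fg_total - fg_with) + (bg_total - bg_with)
  x <- fg_with:min(fg_total, tot_with)
  sum(stats::dhyper(x, tot_with, tot_without, fg_total))
}
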