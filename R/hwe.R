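# Exact test of Hardy-Weinberg equilibrium, used as a site-level QC filter.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test for a biallelic site: conditional on the observed
#' allele counts, enumerates every possible heterozygote count (which must
#' share the parity of the minor-allele count), computes each configuration's
#' conditional probability, and sums the probabilities of all configurations
#' no more probable than the observed one. No installed package in this stack
#' provides the genotype-count exact test, so it is computed directly; the
#' enumeration is over at most `n_minor/2 + 1` terms.
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative genotype counts.
#' @return The exact two-sided p-value.
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25) # perfect HWE proportions
#' hwe_exact_test(50, 0, 50)  # maximal heterozygote deficit
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != trunc(counts))) {
    abort("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) abort("all genotype counts are zero")

  n_alt <- 2 * n_hom_alt + n_het          # alternative allele count
  n_minor <- min(n_alt, 2 * n - n_alt)
  if (n_minor == 0) return(1)             # monomorphic: only one configuration

  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(n_het = h | allele counts), Levene/Haldane conditional distribution
  log_prob <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    lgamma(n + 1) - lgamma(hom_min + 1) - lgamma(h + 1) - lgamma(hom_maj + 1) +
      h * log(2) + lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}
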