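# Shared in-code fixtures for the test suite.

# A single-site long genotype table for one trio plus optional extra samples,
# with every QC metric at a comfortably passing value unless overridden.
tiny_site <- function(gt = c(p = "het", f = "hom_ref", m = "hom_ref"),
                      gq = 60, dp = 40, alt_frac = c(p = 0.5, f = 0, m = 0),
                      site_qual = 100, mq = 60, strand_bias = 5,
                      chrom = "1", pos = 1000) {
  ids <- c("p", "f", "m")
  tibble::tibble(
    chrom = chrom, pos = pos, ref = "A", alt = "G",
    site_qual = site_qual, mq = mq, strand_bias = strand_bias,
    sample_id = ids, gt = unname(gt[ids]),
    gq = rep_len(gq, 3), dp = rep_len(dp, 3),
    alt_reads = round(rep_len(dp, 3) * unname(alt_frac[ids]))
  )
}

tiny_trio <- function() {
  tibble::tibble(trio_id = "t1", proband_id = "p", father_id = "f",
                 mother_id = "m", family_history = "sporadic")
}

# Small expression dataset: `n_genes` iid-noise genes over one prenatal
# stratum, with an optional perfectly co-expressed pair planted.
tiny_expression <- function(n_genes = 6, n_samples = 10, seed = 1,
                            planted_pair = FALSE) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    if (planted_pair) m[2, ] <- m[1, ] * 2 + 3  # monotone copy of gene 1
    meta <- tibble::tibble(
      sample_id = colnames(m), region = "frontal", subregion = "VFC",
      age_value = seq(9, 30, length.out = n_samples), age_unit = "pcw")
    expression_dataset(m, meta)
  })
}

# Exhaustive-enumeration oracle for the empirical set test: exact probability
# that a uniformly drawn size-m subset has statistic >= (or <=) the observed.
exact_subset_tail <- function(values, m, observed,
                              direction = "greater_equal",
                              stat_fun = mean) {
  combos <- utils::combn(length(values), m)
  stats <- apply(combos, 2, function(ix) stat_fun(values[ix]))
  if (direction == "greater_equal") mean(stats >= observed)
  else mean(stats <= observed)
}
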