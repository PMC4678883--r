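# Genotype- and site-level QC, de novo calling, QA metrics, mutation rate.
#
# All functions operate on a long genotype tibble (one row per sample x site)
# with columns: chrom, pos, ref, alt, site_qual, mq, strand_bias, sample_id,
# gt, gq, dp, alt_reads. `gt` is one of hom_ref / het / hom_alt / missing.

genotype_cols <- c("chrom", "pos", "ref", "alt", "site_qual", "mq",
                   "strand_bias", "sample_id", "gt", "gq", "dp", "alt_reads")

#' Genotype-level QC: set failing calls to missing
#'
#' A non-missing call is eliminated (set to `missing`) when any of these
#' holds: genotype quality below `min_gq` (Phred < 30); depth below `min_dp`
#' (< 10X); a reference-homozygous call supported by >= 5% alternative-allele
#' reads; a heterozygous call supported by <= 25% alternative reads; an
#' alternative-homozygous call supported by <= 70% alternative reads.
#' Boundary values pass only where the inequality is strict (GQ 30 and DP 10
#' pass; a hom_ref allele fraction of exactly 5% fails). A non-missing call
#' with zero depth fails the depth rule rather than erroring.
#'
#' @param genotypes Long genotype tibble (see above).
#' @param min_gq,min_dp,max_ref_ab,min_het_ab,min_hom_ab QC thresholds:
#'   calls fail when `gq < min_gq`, `dp < min_dp`, hom_ref allele balance
#'   `>= max_ref_ab`, het allele balance `<= min_het_ab`, or hom_alt allele
#'   balance `<= min_hom_ab`.
#' @return The tibble with failing calls set to `gt = "missing"` and a
#'   `gt_filter` column naming the first rule each call failed (`NA` = pass).
#'   Applying the filter twice equals applying it once.
#' @export
filter_genotypes <- function(genotypes, min_gq = 30, min_dp = 10,
                             max_ref_ab = 0.05, min_het_ab = 0.25,
                             min_hom_ab = 0.70) {
  check_columns(genotypes, genotype_cols, "`genotypes`")
  g <- as_tibble(genotypes)
  if (!"gt_filter" %in% names(g)) g$gt_filter <- NA_character_
  live <- g$gt != "missing"
  ab <- ifelse(g$dp > 0, g$alt_reads / g$dp, NA_real_)

  reason <- rep(NA_character_, nrow(g))
  rule <- function(cond, label) ifelse(live & is.na(reason) & cond, label, reason)
  reason <- rule(g$gq < min_gq, "low_gq")
  reason <- rule(g$dp < min_dp, "low_dp")
  reason <- rule(g$gt == "hom_ref" & !is.na(ab) & ab >= max_ref_ab, "ref_alt_fraction")
  reason <- rule(g$gt == "het" & !is.na(ab) & ab <= min_het_ab, "het_alt_fraction")
  reason <- rule(g$gt == "hom_alt" & !is.na(ab) & ab <= min_hom_ab, "hom_alt_fraction")

  g$gt <- ifelse(!is.na(reason), "missing", g$gt)
  g$gt_filter <- dplyr::coalesce(g$gt_filter, reason)
  g
}

#' Per-site QC metrics and pass/fail status
#'
#' Computes, for every site of an (already genotype-filtered) table, the call
#' rate (fraction of samples with a non-missing genotype), the exact
#' Hardy-Weinberg p-value, and the pass/fail status against the site filters:
#' sites fail on Phred site quality < 50, mapping quality < 20, strand
#' bias over 60, call rate < 60%, or HWE p < 1e-5. Boundary values pass. By default
#' HWE uses founders only (trio parents), since probands are not independent
#' of their parents; set `hwe_samples = "all"` to use every sample.
#'
#' @param genotypes Long genotype tibble after [filter_genotypes()].
#' @param trios Trio tibble (`trio_id, proband_id, father_id, mother_id`);
#'   required for `hwe_samples = "founders"`.
#' @param min_site_qual,min_mq,max_strand_bias,min_call_rate,min_hwe_p Site
#'   filter thresholds.
#' @param hwe_samples `"founders"` (default) or `"all"`.
#' @return One row per site with metrics, `fail_reason` (first failing rule or
#'   `NA`), and logical `pass`.
#' @export
site_qc_table <- function(genotypes, trios = NULL, min_site_qual = 50,
                          min_mq = 20, max_strand_bias = 60,
                          min_call_rate = 0.60, min_hwe_p = 1e-5,
                          hwe_samples = c("founders", "all")) {
  hwe_samples <- match.arg(hwe_samples)
  check_columns(genotypes, genotype_cols, "`genotypes`")
  g <- as_tibble(genotypes)
  if (hwe_samples == "founders") {
    if (is.null(trios)) abort("`trios` is required when hwe_samples = 'founders'")
    founders <- unique(c(trios$father_id, trios$mother_id))
  } else {
    founders <- unique(g$sample_id)
  }

  per_site <- g |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt,
             .data$site_qual, .data$mq, .data$strand_bias) |>
    summarise(
      call_rate = mean(.data$gt != "missing"),
      hwe_p = {
        f <- .data$gt[.data$sample_id %in% founders & .data$gt != "missing"]
        if (length(f) == 0) 1
        else hwe_exact_test(sum(f == "hom_ref"), sum(f == "het"),
                            sum(f == "hom_alt"))
      },
      .groups = "drop"
    )

  per_site |>
    mutate(
      fail_reason = dplyr::case_when(
        .data$site_qual < min_site_qual ~ "low_site_qual",
        .data$mq < min_mq ~ "low_mq",
        .data$strand_bias > max_strand_bias ~ "strand_bias",
        .data$call_rate < min_call_rate ~ "low_call_rate",
        .data$hwe_p < min_hwe_p ~ "hwe",
        .default = NA_character_
      ),
      pass = is.na(.data$fail_reason)
    )
}

#' Site-level QC: drop failing sites
#'
#' Applies the site filters of [site_qc_table()] and returns the genotypes of
#' the passing sites only. Idempotent.
#'
#' @inheritParams site_qc_table
#' @param ... Threshold arguments passed to [site_qc_table()].
#' @return The filtered genotype tibble, with the [site_qc_table()] attached
#'   as attribute `"site_qc"`.
#' @export
filter_variants <- function(genotypes, trios = NULL, ...) {
  qc <- site_qc_table(genotypes, trios, ...)
  keep <- semi_join(as_tibble(genotypes),
                    filter(qc, .data$pass),
                    by = c("chrom", "pos", "ref", "alt"))
  attr(keep, "site_qc") <- qc
  keep
}

#' Call de novo variants from trio genotypes
#'
#' A DNV is emitted for a trio at a site when the proband call is `het` or
#' `hom_alt` and both parents are `hom_ref`. A trio with any missing member
#' call at a site emits nothing there. Run [filter_genotypes()] and
#' [filter_variants()] first.
#'
#' @param genotypes Long genotype tibble after QC.
#' @param trios Trio tibble with `trio_id, proband_id, father_id, mother_id`
#'   (and optionally `family_history`).
#' @param gene_map Optional tibble `chrom, pos, gene, functional_class` used
#'   to annotate records; unmapped records get `NA`.
#' @return A tibble of DNV records: `chrom, pos, ref, alt, trio_id,
#'   proband_gt, gene, functional_class`, ordered by position then trio.
#' @export
call_dnvs <- function(genotypes, trios, gene_map = NULL) {
  check_columns(genotypes, genotype_cols, "`genotypes`")
  check_columns(trios, c("trio_id", "proband_id", "father_id", "mother_id"),
                "`trios`")
  g <- select(as_tibble(genotypes), dplyr::all_of(
    c("chrom", "pos", "ref", "alt", "sample_id", "gt")))
  absent <- setdiff(unique(c(trios$proband_id, trios$father_id,
                             trios$mother_id)), unique(g$sample_id))
  if (length(absent) > 0L) {
    abort(sprintf("trio member(s) absent from genotype table: %s",
                  paste(absent, collapse = ", ")))
  }
  member <- function(ids, nm) {
    g |>
      inner_join(tibble(sample_id = ids, trio_id = trios$trio_id),
                 by = "sample_id", relationship = "many-to-many") |>
      select(dplyr::all_of(c("chrom", "pos", "ref", "alt", "trio_id", "gt"))) |>
      rename(!!nm := "gt")
  }
  joined <- member(trios$proband_id, "gt_proband") |>
    inner_join(member(trios$father_id, "gt_father"),
               by = c("chrom", "pos", "ref", "alt", "trio_id")) |>
    inner_join(member(trios$mother_id, "gt_mother"),
               by = c("chrom", "pos", "ref", "alt", "trio_id"))

  out <- joined |>
    filter(.data$gt_proband %in% c("het", "hom_alt"),
           .data$gt_father == "hom_ref", .data$gt_mother == "hom_ref") |>
    mutate(proband_gt = .data$gt_proband) |>
    select(dplyr::all_of(c("chrom", "pos", "ref", "alt", "trio_id",
                           "proband_gt"))) |>
    arrange(.data$chrom, .data$pos, .data$trio_id)

  if (!is.null(gene_map)) {
    out <- left_join(out, distinct(gene_map, .data$chrom, .data$pos,
                                   .data$gene, .data$functional_class),
                     by = c("chrom", "pos"))
  } else {
    out$gene <- NA_character_
    out$functional_class <- NA_character_
  }
  out
}

#' Cohort QA metrics: variant count, dbSNP coverage, Ti/Tv
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine substitutions
#' (A<->G, C<->T); all other single-base substitutions are transversions.
#' The Ti/Tv ratio is computed over SNVs only. `dbsnp_fraction` is the share
#' of sites matching `known_sites` on chromosome, position and alleles.
#'
#' @param sites Tibble with `chrom, pos, ref, alt` (one row per site).
#' @param known_sites Optional tibble with the same columns (e.g. dbSNP).
#' @return A one-row tibble: `n_variants, dbsnp_fraction, ti_tv_ratio`.
#' @export
qa_metrics <- function(sites, known_sites = NULL) {
  check_columns(sites, c("chrom", "pos", "ref", "alt"), "`sites`")
  s <- distinct(as_tibble(sites), .data$chrom, .data$pos, .data$ref, .data$alt)
  snv <- filter(s, nchar(.data$ref) == 1, nchar(.data$alt) == 1,
                .data$ref %in% c("A", "C", "G", "T"),
                .data$alt %in% c("A", "C", "G", "T"))
  pair <- paste(pmin(snv$ref, snv$alt), pmax(snv$ref, snv$alt))
  n_ti <- sum(pair %in% c("A G", "C T"))
  n_tv <- nrow(snv) - n_ti
  titv <- if (n_tv == 0) {
    if (n_ti > 0) warn("no transversions: Ti/Tv ratio is infinite")
    if (n_ti > 0) Inf else NA_real_
  } else n_ti / n_tv
  dbsnp <- if (is.null(known_sites) || nrow(known_sites) == 0) 0 else {
    nrow(semi_join(s, known_sites, by = c("chrom", "pos", "ref", "alt"))) / nrow(s)
  }
  tibble(n_variants = nrow(s), dbsnp_fraction = dbsnp, ti_tv_ratio = titv)
}

#' Per-base per-generation de novo mutation rate
#'
#' `n_dnvs / (2 * callable_bases * n_trios)`: each proband carries two copies
#' of every callable base. The callable-base denominator (capture target vs.
#' well-covered subset) materially changes the estimate and must be supplied
#' explicitly.
#'
#' @param n_dnvs DNV count.
#' @param n_trios Number of trios.
#' @param callable_bases Callable bases per haploid genome.
#' @return The mutation rate per base per generation.
#' @export
#' @examples
#' mutation_rate(57, 45, 3.0e7)
mutation_rate <- function(n_dnvs, n_trios, callable_bases) {
  stopifnot(is.numeric(n_dnvs), n_dnvs >= 0)
  if (n_trios <= 0 || callable_bases <= 0) {
    abort("`n_trios` and `callable_bases` must be positive")
  }
  n_dnvs / (2 * callable_bases * n_trios)
}
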