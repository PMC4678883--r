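# Evidence integration: GWAS locus overlap, per-gene evidence ranking, and
# DNV burden vs. cognition regression.

#' Overlap genes with GWAS locus intervals
#'
#' A gene hits a locus when their intervals intersect on the same chromosome.
#' Coordinates are 1-based fully closed on both sides, so touching endpoints
#' count as overlap. Both tables must be on the same genome assembly (the
#' caller's responsibility).
#'
#' @param genes Tibble `gene, chrom, start, end`.
#' @param loci Tibble `chrom, start, end, label`.
#' @return A tibble of hits `gene, chrom, gene_start, gene_end, label,
#'   locus_start, locus_end`, one row per (gene, locus) pair.
#' @export
gwas_overlap <- function(genes, loci) {
  check_columns(genes, c("gene", "chrom", "start", "end"), "`genes`")
  check_columns(loci, c("chrom", "start", "end", "label"), "`loci`")
  if (any(genes$start > genes$end) || any(loci$start > loci$end)) {
    abort("malformed interval: start > end")
  }
  inner_join(
    rename(as_tibble(genes), gene_start = "start", gene_end = "end"),
    rename(as_tibble(loci), locus_start = "start", locus_end = "end"),
    by = "chrom", relationship = "many-to-many") |>
    filter(.data$gene_start <= .data$locus_end,
           .data$locus_start <= .data$gene_end) |>
    arrange(.data$gene, .data$label)
}

#' Convert BED intervals to 1-based closed coordinates
#'
#' BED is 0-based half-open; the pipeline works in 1-based fully closed
#' coordinates, so `start` gains 1 and `end` is kept.
#'
#' @param bed Tibble with `chrom, start, end` (0-based half-open) and any
#'   further columns.
#' @return The tibble in 1-based closed coordinates.
#' @export
bed_to_closed <- function(bed) {
  check_columns(bed, c("chrom", "start", "end"), "`bed`")
  mutate(as_tibble(bed), start = .data$start + 1)
}

#' Integrate per-gene evidence flags into a ranking
#'
#' Joins boolean evidence flags (by convention: intolerance-score
#' significance, constrained-list membership, brain-critical-exon membership,
#' co-expression hub status, overlap with prior DNV studies, GWAS locus
#' overlap) on gene symbol, counts the supporting evidences per gene, and
#' assigns a dense rank by count descending. Output rows are ordered by rank
#' then alphabetically, which makes the operation deterministic and
#' idempotent.
#'
#' @param flags Named list of character vectors (genes carrying each flag) or
#'   a tibble with a `gene` column and one logical column per evidence line.
#' @param genes Optional gene universe for the table; defaults to the union
#'   of flagged genes.
#' @return A tibble `gene, <one logical column per flag>, evidence_count,
#'   rank`.
#' @export
#' @examples
#' integrate_evidence(list(rvis = c("A", "B"), hub = "A"))
integrate_evidence <- function(flags, genes = NULL) {
  if (is.data.frame(flags)) {
    check_columns(flags, "gene", "`flags`")
    if (anyDuplicated(flags$gene)) abort("duplicate gene rows in `flags`")
    tbl <- as_tibble(flags)
    if (!is.null(genes)) {
      tbl <- left_join(tibble(gene = unique(genes)), tbl, by = "gene")
    }
    flag_cols <- setdiff(names(tbl), "gene")
    tbl <- mutate(tbl, across(dplyr::all_of(flag_cols),
                              \(x) dplyr::coalesce(as.logical(x), FALSE)))
  } else {
    if (is.null(names(flags)) || any(names(flags) == "")) {
      abort("`flags` must be a named list or a data frame")
    }
    genes <- unique(genes %||% unlist(flags, use.names = FALSE))
    tbl <- tibble(gene = genes)
    for (nm in names(flags)) tbl[[nm]] <- tbl$gene %in% flags[[nm]]
    flag_cols <- names(flags)
  }
  tbl |>
    mutate(evidence_count = rowSums(across(dplyr::all_of(flag_cols)))) |>
    mutate(rank = dense_rank(desc(.data$evidence_count))) |>
    arrange(.data$rank, .data$gene)
}

#' Regress cognitive measures on per-subject DNV burden
#'
#' Ordinary least squares of each outcome on the subject's DNV count
#' (intercept included), with a two-sided t-test on the slope. Subjects with
#' a missing outcome are dropped per outcome; the nominal p-values are
#' reported uncorrected, reflecting the exploratory nature of such burden
#' analyses.
#'
#' @param dnv_counts Tibble `subject_id, n_dnvs`.
#' @param measures Tibble with `subject_id` and one numeric column per
#'   cognitive outcome.
#' @return A tibble with one row per outcome: `outcome, slope, slope_se,
#'   p_value, n`.
#' @export
cognition_regression <- function(dnv_counts, measures) {
  check_columns(dnv_counts, c("subject_id", "n_dnvs"), "`dnv_counts`")
  check_columns(measures, "subject_id", "`measures`")
  outcomes <- setdiff(names(measures), "subject_id")
  if (length(outcomes) == 0) abort("no outcome columns in `measures`")
  joined <- inner_join(as_tibble(dnv_counts), as_tibble(measures),
                       by = "subject_id")
  purrr::map(outcomes, function(oc) {
    d <- joined[!is.na(joined[[oc]]) & !is.na(joined$n_dnvs), ]
    if (nrow(d) < 3) abort(sprintf("outcome '%s': fewer than 3 complete subjects", oc))
    if (stats::var(d$n_dnvs) == 0) {
      abort(sprintf("outcome '%s': DNV counts have zero variance", oc))
    }
    fit <- summary(lm(d[[oc]] ~ d$n_dnvs))
    co <- fit$coefficients["d$n_dnvs", ]
    tibble(outcome = oc, slope = co[["Estimate"]],
           slope_se = co[["Std. Error"]], p_value = co[["Pr(>|t|)"]],
           n = nrow(d))
  }) |> list_rbind()
}
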