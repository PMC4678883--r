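# Readers and writers for the pipeline's file formats: VCF trio genotypes,
# PED pedigrees, annotation/score/list TSVs, expression matrices, truth JSON.

#' Path to a packaged example file
#'
#' @param file Name of a file under `inst/extdata`; `NULL` lists them.
#' @return A file path (or a character vector of available names).
#' @export
#' @examples
#' dnvnet_example()
dnvnet_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "dnvnet"))
  } else {
    path <- system.file("extdata", file, package = "dnvnet")
    if (path == "") abort(sprintf("no packaged file called '%s'", file))
    path
  }
}

#' Read an annotated DNV table
#'
#' Reads a TSV of de novo variants with the seven predictor columns
#' (semicolon-delimited per-transcript codes, `"."` for missing) and a
#' `max_af` column (`"."` for absent from all reference panels). The packaged
#' `dnv_predictor_profiles.tsv` holds the 47 Sanger-validated non-synonymous
#' DNVs of a 45-trio schizophrenia exome cohort in this layout.
#'
#' @param path Path to the TSV.
#' @return A tibble, one row per variant; `max_af` parsed to numeric with
#'   `NA` for missing.
#' @export
read_dnv_annotations <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    pos = readr::col_double(),
    max_af = readr::col_character(),
    .default = readr::col_character()
  ))
  check_columns(x, c("chrom", "pos", "ref", "alt", "gene", "max_af",
                     "functional_class", predictor_columns()),
                "annotated DNV table")
  mutate(x, max_af = suppressWarnings(
    as.numeric(dplyr::na_if(.data$max_af, "."))))
}

#' Write trio genotypes to VCF
#'
#' Writes a long genotype table (one row per sample x site) as VCF v4.2 with
#' FORMAT `GT:GQ:DP:AD` and INFO fields `MQ` (mapping quality) and `FS`
#' (strand bias, Phred-scaled). vcfR gzip-compresses output, so `path` should
#' end in `.vcf.gz`.
#'
#' @param genotypes Long tibble with columns `chrom, pos, ref, alt, site_qual,
#'   mq, strand_bias, sample_id, gt, gq, dp, alt_reads`; `gt` one of
#'   `hom_ref`, `het`, `hom_alt`, `missing`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(genotypes, path) {
  check_columns(genotypes, c("chrom", "pos", "ref", "alt", "site_qual", "mq",
                             "strand_bias", "sample_id", "gt", "gq", "dp",
                             "alt_reads"), "`genotypes`")
  g <- arrange(as_tibble(genotypes), .data$chrom, .data$pos, .data$sample_id)
  sites <- distinct(g, .data$chrom, .data$pos, .data$ref, .data$alt,
                    .data$site_qual, .data$mq, .data$strand_bias)
  samples <- sort(unique(g$sample_id))

  fix <- cbind(
    CHROM = as.character(sites$chrom), POS = as.character(sites$pos),
    ID = rep(".", nrow(sites)), REF = sites$ref, ALT = sites$alt,
    QUAL = as.character(sites$site_qual), FILTER = rep(".", nrow(sites)),
    INFO = sprintf("MQ=%g;FS=%g", sites$mq, sites$strand_bias)
  )
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  key <- paste(g$chrom, g$pos, g$ref, g$alt)
  site_key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
  gtm <- matrix("./.:.:.:.", nrow = nrow(sites), ncol = length(samples),
                dimnames = list(NULL, samples))
  gtm[cbind(match(key, site_key), match(g$sample_id, samples))] <-
    sprintf("%s:%s:%s:%s", gt_code[g$gt], g$gq, g$dp,
            paste(g$dp - g$alt_reads, g$alt_reads, sep = ","))
  gtm <- cbind(FORMAT = rep("GT:GQ:DP:AD", nrow(sites)), gtm)

  meta <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled strand bias\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">"
  )
  vcf <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                      meta = meta, fix = fix, gt = gtm)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Read trio genotypes from VCF
#'
#' Inverse of [write_genotype_vcf()]: parses a VCF (plain or gzipped) with
#' FORMAT `GT:GQ:DP:AD` into the long genotype tibble the QC functions
#' consume. Genotypes other than `0/0`, `0/1`/`1/0` and `1/1` map to
#' `missing`.
#'
#' @param path Path to a VCF file.
#' @return A long genotype tibble (see [write_genotype_vcf()]).
#' @export
read_genotype_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info_num <- function(field) {
    v <- stringr::str_match(fix$INFO, paste0("(?:^|;)", field, "=([^;]+)"))[, 2]
    as.numeric(v)
  }
  sites <- tibble(
    chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    site_qual = as.numeric(fix$QUAL),
    mq = info_num("MQ"), strand_bias = info_num("FS")
  )
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  gq <- vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE)
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  alt_reads <- suppressWarnings(
    matrix(as.numeric(vapply(strsplit(as.vector(ad), ","), function(z)
      if (length(z) >= 2) z[2] else NA_character_, character(1))),
      nrow = nrow(gt_raw)))

  classify_gt <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    dplyr::case_match(x, "0/0" ~ "hom_ref", c("0/1", "1/0") ~ "het",
                      "1/1" ~ "hom_alt", .default = "missing")
  }
  samples <- colnames(gt_raw)
  purrr::map(seq_along(samples), function(j) {
    mutate(sites,
           sample_id = samples[j],
           gt = classify_gt(gt_raw[, j]),
           gq = ifelse(is.na(gq[, j]), 0, gq[, j]),
           dp = ifelse(is.na(dp[, j]), 0, dp[, j]),
           alt_reads = ifelse(is.na(alt_reads[, j]), 0, alt_reads[, j]))
  }) |> list_rbind()
}

#' Write and read a 6-column PED pedigree
#'
#' Standard PED columns: family, individual, father, mother, sex, phenotype
#' (`0` = missing parent). [read_pedigree()] additionally returns one trio row
#' per individual with both parents present.
#'
#' @param pedigree Tibble with columns `family_id, sample_id, father_id,
#'   mother_id, sex, phenotype`.
#' @param path File path.
#' @return `write_pedigree()`: `path` invisibly. `read_pedigree()`: the
#'   pedigree tibble.
#' @export
write_pedigree <- function(pedigree, path) {
  check_columns(pedigree, c("family_id", "sample_id", "father_id",
                            "mother_id", "sex", "phenotype"), "`pedigree`")
  readr::write_tsv(pedigree[, c("family_id", "sample_id", "father_id",
                                "mother_id", "sex", "phenotype")],
                   path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  readr::read_tsv(path, col_names = c("family_id", "sample_id", "father_id",
                                      "mother_id", "sex", "phenotype"),
                  col_types = "ccccii")
}

#' Extract trios from a pedigree
#'
#' @param pedigree A pedigree tibble (see [write_pedigree()]).
#' @param family_history Optional named character vector mapping proband ids
#'   to `sporadic`/`familial`; unknown probands get `"unknown"`.
#' @return Tibble with columns `trio_id, proband_id, father_id, mother_id,
#'   family_history`.
#' @export
trios_from_pedigree <- function(pedigree, family_history = NULL) {
  tr <- filter(pedigree, .data$father_id != "0", .data$mother_id != "0")
  if (any(tr$father_id == tr$sample_id | tr$mother_id == tr$sample_id |
            tr$father_id == tr$mother_id)) {
    abort("trio members must be three distinct individuals")
  }
  tibble(
    trio_id = tr$family_id, proband_id = tr$sample_id,
    father_id = tr$father_id, mother_id = tr$mother_id,
    family_history = unname(
      (family_history %||% character(0))[tr$sample_id]) %|na|% "unknown"
  )
}

`%|na|%` <- function(x, y) {
  if (length(x) == 0) return(y)
  ifelse(is.na(x), y, x)
}

#' Write and read an expression dataset
#'
#' The expression matrix travels as a TSV with a `gene` column followed by one
#' column per sample; sample metadata as a TSV with columns `sample_id,
#' region, subregion, age_value, age_unit` (`age_unit` one of `pcw`, `month`,
#' `year`).
#'
#' @param dataset An `expression_dataset` (see [expression_dataset()]).
#' @param expr_path,meta_path Output/input paths.
#' @return `write_expression()`: paths invisibly; `read_expression()`: an
#'   `expression_dataset`.
#' @export
write_expression <- function(dataset, expr_path, meta_path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  expr <- as_tibble(dataset$matrix, rownames = "gene")
  readr::write_tsv(expr, expr_path)
  readr::write_tsv(dataset$sample_meta, meta_path)
  invisible(c(expr_path, meta_path))
}

#' @rdname write_expression
#' @export
read_expression <- function(expr_path, meta_path) {
  expr <- readr::read_tsv(expr_path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()))
  meta <- readr::read_tsv(meta_path, col_types = readr::cols(
    sample_id = readr::col_character(), region = readr::col_character(),
    subregion = readr::col_character(), age_value = readr::col_double(),
    age_unit = readr::col_character()))
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr$gene
  expression_dataset(m, meta)
}

#' Bundle an expression matrix with sample metadata
#'
#' @param matrix Numeric genes x samples matrix with unique rownames (genes)
#'   and colnames (sample ids).
#' @param sample_meta Tibble with columns `sample_id, region, subregion,
#'   age_value, age_unit` covering every column of `matrix`.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(matrix, sample_meta) {
  check_columns(sample_meta, c("sample_id", "region", "subregion",
                               "age_value", "age_unit"), "`sample_meta`")
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix))) {
    abort("expression matrix needs unique gene rownames")
  }
  if (!all(colnames(matrix) %in% sample_meta$sample_id)) {
    abort("every sample column needs a metadata row")
  }
  if (!all(sample_meta$age_unit %in% c("pcw", "month", "year"))) {
    abort("age_unit must be one of 'pcw', 'month', 'year'")
  }
  structure(list(matrix = matrix, sample_meta = as_tibble(sample_meta)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples; %d subregions\n",
              nrow(x$matrix), ncol(x$matrix),
              dplyr::n_distinct(x$sample_meta$subregion)))
  invisible(x)
}

#' Write and read a simulation truth ledger
#'
#' The truth ledger produced by the generators is a plain list of tibbles and
#' vectors; it round-trips through JSON.
#'
#' @param truth A `sim_truth` list.
#' @param path JSON file path.
#' @return `write_sim_truth()`: `path` invisibly; `read_sim_truth()`: the
#'   truth list.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$planted_dnvs <- as_tibble(x$planted_dnvs)
  if (!is.null(x$qc_violations)) x$qc_violations <- as_tibble(x$qc_violations)
  x
}

#' Read gene lists and score tables
#'
#' Gene lists are one-symbol-per-line text files; gene score tables are TSVs
#' with columns `gene, haploinsufficiency, recessive_probability, rvis_01,
#' rvis_1, critical_exon_score`.
#'
#' @param path File path.
#' @return `read_gene_list()`: character vector; `read_gene_scores()`: tibble.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path)
  x[nzchar(trimws(x))]
}

#' @rdname read_gene_list
#' @export
read_gene_scores <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()))
}
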