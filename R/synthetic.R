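# Synthetic-data generators: every input the pipeline consumes, with the
# statistical structure the analysis assumes and a complete truth ledger, so
# all stages are testable without external downloads.

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-data generators. The
#' defaults mirror a 45-trio exome study: 32 sporadic and 13 familial trios,
#' a validated DNV rate of 57/45 per proband, a damaging fraction of 40/47
#' among non-synonymous DNVs, a 19,043-gene universe with a 240-gene control
#' DNV list, and four prenatal frontal/temporal subregion strata (VFC, MFC,
#' OFC, ITC) in which a 20-gene case module is planted, alongside the same
#' subregions at two postnatal stages where nothing is planted.
#'
#' @param n_trios Number of trios.
#' @param n_sporadic Number of sporadic trios (the rest are familial);
#'   defaults to the cohort's 32-in-45 proportion of `n_trios`.
#' @param dnv_rate_lambda Mean planted DNVs per proband (Poisson rate).
#' @param callable_bases Callable bases per haploid exome.
#' @param damaging_fraction Probability a planted missense DNV is damaging.
#' @param frameshift_fraction,synonymous_fraction Class mix of planted DNVs;
#'   the remainder are missense.
#' @param n_genes Gene-universe size.
#' @param n_control_genes Control DNV gene-list size.
#' @param strata Tibble `name, region, subregion, stage, n_samples` defining
#'   the expression strata.
#' @param module_strata Names of the strata in which the case co-expression
#'   module is planted.
#' @param module_genes Number of case genes in the planted module.
#' @param module_loading Latent-factor loading in \[0, 1\].
#' @param noise_sd Expression noise scale for module genes.
#' @param n_expression_background Non-case, non-control genes carried in the
#'   expression matrix (the network statistics only read case and control
#'   genes, so the full universe is not materialised).
#' @param constrained_size,critical_exon_size,prior_study_size Reference-list
#'   sizes.
#' @param n_gwas_loci Number of GWAS locus intervals.
#' @param overlap_constrained,overlap_critical_exon,overlap_prior,overlap_gwas
#'   Planted overlaps between the case genes and each reference list.
#' @param hi_shift Additive haploinsufficiency shift of case genes over the
#'   background.
#' @param rvis_shift_01,rvis_shift_1 Additive RVIS shifts (negative = more
#'   intolerant) of case genes, for the 0.1% and 1% score variants.
#' @param seed Master seed; each generator derives an independent sub-stream
#'   via [substream_seed()].
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_trios = 45,
                       n_sporadic = NULL,
                       dnv_rate_lambda = 57 / 45,
                       callable_bases = 3.0e7,
                       damaging_fraction = 40 / 47,
                       frameshift_fraction = 2 / 57,
                       synonymous_fraction = 10 / 57,
                       n_genes = 19043,
                       n_control_genes = 240,
                       strata = default_strata(),
                       module_strata = NULL,
                       module_genes = 20,
                       module_loading = 0.9,
                       noise_sd = 0.3,
                       n_expression_background = 200,
                       constrained_size = 1000,
                       critical_exon_size = 1744,
                       prior_study_size = 733,
                       n_gwas_loci = 108,
                       overlap_constrained = 8,
                       overlap_critical_exon = 8,
                       overlap_prior = 4,
                       overlap_gwas = 1,
                       hi_shift = 0.15,
                       rvis_shift_01 = -0.75,
                       rvis_shift_1 = -0.6,
                       seed = 1L) {
  check_count(n_trios, "n_trios")
  check_count(n_genes, "n_genes")
  check_count(n_control_genes, "n_control_genes")
  if (dnv_rate_lambda < 0) abort("`dnv_rate_lambda` must be non-negative")
  if (module_loading < 0 || module_loading > 1) {
    abort("`module_loading` must be in [0, 1]")
  }
  if (damaging_fraction < 0 || damaging_fraction > 1) {
    abort("`damaging_fraction` must be in [0, 1]")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  check_columns(strata, c("name", "region", "subregion", "stage", "n_samples"),
                "`strata`")
  if (nrow(strata) == 0) abort("`strata` must be non-empty")
  if (any(strata$n_samples < 4)) abort("every stratum needs >= 4 samples")
  module_strata <- module_strata %||%
    strata$name[strata$stage == "prenatal"]
  if (!all(module_strata %in% strata$name)) {
    abort("`module_strata` must name rows of `strata`")
  }
  n_sporadic <- n_sporadic %||% round(n_trios * 32 / 45)
  if (n_sporadic > n_trios) abort("`n_sporadic` cannot exceed `n_trios`")
  structure(as.list(environment()), class = "sim_config")
}

#' Default expression strata
#'
#' Four frontal/temporal subregions (VFC, MFC, OFC, ITC) at each of the
#' three canonical developmental stages, 30 samples per stratum.
#'
#' @param n_samples Samples per stratum.
#' @return A strata tibble for [sim_config()].
#' @export
default_strata <- function(n_samples = 30) {
  sub <- tibble(
    subregion = c("VFC", "MFC", "OFC", "ITC"),
    region = c("frontal", "frontal", "frontal", "temporal_parietal"))
  tidyr::expand_grid(sub,
                     stage = c("prenatal", "infancy_childhood",
                               "adolescence_adulthood")) |>
    mutate(name = paste(.data$stage, .data$subregion, sep = "-"),
           n_samples = n_samples) |>
    select(dplyr::all_of(c("name", "region", "subregion", "stage",
                           "n_samples")))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d trios (lambda = %.3g), %d genes, %d strata, seed %d\n",
    x$n_trios, x$dnv_rate_lambda, x$n_genes, nrow(x$strata), x$seed))
  invisible(x)
}

# Gene universe symbols.
universe_genes <- function(n_genes) sprintf("G%05d", seq_len(n_genes))

#' Simulate a trio cohort with planted de novo variants
#'
#' Draws each proband's DNV count from Poisson(`dnv_rate_lambda`) and plants
#' the variants as proband-heterozygous, parent-homozygous-reference sites
#' whose genotype quality, depth, allele fractions and site metrics all pass
#' the QC thresholds. When `add_contaminants` is `TRUE` the cohort also
#' carries inherited (Mendelian-consistent) variants and one deliberate
#' violation of every genotype-level and site-level QC rule, so downstream
#' filters can each be exercised and checked against the truth ledger.
#'
#' @param config A [sim_config()].
#' @param add_contaminants Add inherited variants and planted QC violations.
#' @return A list: `genotypes` (long tibble), `trios`, `pedigree`,
#'   `gene_map` (site-to-gene assignment with functional class), and `truth`
#'   (`planted_dnvs`, `qc_violations`, `seed`).
#' @export
simulate_trio_cohort <- function(config = sim_config(),
                                 add_contaminants = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  seed <- substream_seed(config$seed, "trio_cohort")
  with_seed_if(seed, {
    n <- config$n_trios
    trios <- tibble(
      trio_id = sprintf("fam%03d", seq_len(n)),
      proband_id = sprintf("fam%03d_p", seq_len(n)),
      father_id = sprintf("fam%03d_f", seq_len(n)),
      mother_id = sprintf("fam%03d_m", seq_len(n)),
      family_history = c(rep("sporadic", config$n_sporadic),
                         rep("familial", n - config$n_sporadic)))
    samples <- c(rbind(trios$proband_id, trios$father_id, trios$mother_id))

    n_dnv <- rpois(n, config$dnv_rate_lambda)
    n_planted <- sum(n_dnv)
    n_inherited <- if (add_contaminants) 8L else 0L

    bases <- c("A", "C", "G", "T")
    new_sites <- function(k, tag) {
      if (k == 0) return(tibble(
        site_id = character(0), chrom = character(0), pos = numeric(0),
        ref = character(0), alt = character(0)))
      ref <- sample(bases, k, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
      tibble(site_id = sprintf("%s%03d", tag, seq_len(k)),
             chrom = as.character(sample(1:22, k, replace = TRUE)),
             pos = sample.int(2e8, k), ref = ref, alt = unname(alt))
    }

    gene_pool <- sample(universe_genes(config$n_genes))
    gene_cursor <- 0L
    take_genes <- function(k) {
      out <- gene_pool[gene_cursor + seq_len(k)]
      gene_cursor <<- gene_cursor + k
      out
    }

    pass_geno <- function(site_row, sample_id, gt) {
      dp <- sample(30:60, length(sample_id), replace = TRUE)
      alt_reads <- dplyr::case_match(gt,
        "hom_ref" ~ 0,
        "het" ~ round(dp * runif(length(dp), 0.35, 0.6)),
        "hom_alt" ~ dp,
        "missing" ~ 0)
      tibble(chrom = site_row$chrom, pos = site_row$pos, ref = site_row$ref,
             alt = site_row$alt, site_qual = site_row$site_qual,
             mq = site_row$mq, strand_bias = site_row$strand_bias,
             sample_id = sample_id, gt = gt,
             gq = sample(60:99, length(sample_id), replace = TRUE),
             dp = dp, alt_reads = alt_reads)
    }

    site_metrics <- function(sites, qual = NULL, mq = NULL, fs = NULL) {
      mutate(sites,
             site_qual = qual %||% round(runif(nrow(sites), 60, 200), 1),
             mq = mq %||% round(runif(nrow(sites), 40, 60), 1),
             strand_bias = fs %||% round(runif(nrow(sites), 0, 20), 1))
    }

    # --- planted DNVs -----------------------------------------------------
    planted_sites <- site_metrics(new_sites(n_planted, "dnv"))
    carrier <- rep(seq_len(n), n_dnv)
    cls <- sample(c("missense", "frameshift", "synonymous"), n_planted,
                  replace = TRUE,
                  prob = c(1 - config$frameshift_fraction -
                             config$synonymous_fraction,
                           config$frameshift_fraction,
                           config$synonymous_fraction))
    planted <- planted_sites |>
      mutate(trio_id = trios$trio_id[carrier],
             gene = take_genes(n_planted),
             functional_class = cls,
             damaging = dplyr::case_when(
               cls == "missense" ~ runif(n_planted) < config$damaging_fraction,
               cls == "frameshift" ~ NA,
               .default = FALSE))

    geno <- purrr::map(seq_len(nrow(planted)), function(i) {
      row <- planted[i, ]
      tr <- trios[match(row$trio_id, trios$trio_id), ]
      gt <- ifelse(samples == tr$proband_id, "het", "hom_ref")
      pass_geno(row, samples, gt)
    })

    violations <- tibble(site_id = character(0), chrom = character(0),
                         pos = numeric(0), level = character(0),
                         rule = character(0), sample_id = character(0))

    if (add_contaminants) {
      # --- inherited variants (Mendelian-consistent, pass all QC) ---------
      inh_sites <- site_metrics(new_sites(n_inherited, "inh"))
      inh_sites$gene <- take_genes(n_inherited)
      inh_trio <- sample.int(n, n_inherited, replace = TRUE)
      geno <- c(geno, purrr::map(seq_len(n_inherited), function(i) {
        tr <- trios[inh_trio[i], ]
        gt <- ifelse(samples == tr$proband_id | samples == tr$father_id,
                     "het", "hom_ref")
        pass_geno(inh_sites[i, ], samples, gt)
      }))

      # --- genotype-level QC violations, one per rule ---------------------
      gv <- site_metrics(new_sites(5, "genoqc"))
      gv$gene <- take_genes(5)
      gv_rules <- c("low_gq", "low_dp", "ref_alt_fraction",
                    "het_alt_fraction", "hom_alt_fraction")
      gv_target <- sample.int(n, 5, replace = TRUE)
      geno <- c(geno, purrr::map(1:5, function(i) {
        tr <- trios[gv_target[i], ]
        gt <- ifelse(samples == tr$proband_id, "het", "hom_ref")
        bad_sample <- tr$proband_id
        if (gv_rules[i] == "ref_alt_fraction") bad_sample <- tr$father_id
        if (gv_rules[i] == "hom_alt_fraction") {
          gt[samples == tr$proband_id] <- "hom_alt"
        }
        g <- pass_geno(gv[i, ], samples, gt)
        j <- match(bad_sample, g$sample_id)
        switch(gv_rules[i],
          low_gq = { g$gq[j] <- 29 },
          low_dp = { g$dp[j] <- 9; g$alt_reads[j] <- 5 },
          ref_alt_fraction = { g$dp[j] <- 40; g$alt_reads[j] <- 2 },
          het_alt_fraction = { g$dp[j] <- 40; g$alt_reads[j] <- 10 },
          hom_alt_fraction = { g$dp[j] <- 40; g$alt_reads[j] <- 28 })
        g
      }))
      violations <- bind_rows(violations, tibble(
        site_id = gv$site_id, chrom = gv$chrom, pos = gv$pos,
        level = "genotype", rule = gv_rules,
        sample_id = ifelse(gv_rules == "ref_alt_fraction",
                           trios$father_id[gv_target],
                           trios$proband_id[gv_target])))

      # --- site-level QC violations, one per rule -------------------------
      sv_rules <- c("low_site_qual", "low_mq", "strand_bias",
                    "low_call_rate", "hwe")
      sv <- new_sites(5, "siteqc") |>
        site_metrics() |>
        mutate(site_qual = replace(.data$site_qual, 1, 49),
               mq = replace(.data$mq, 2, 15),
               strand_bias = replace(.data$strand_bias, 3, 70),
               gene = take_genes(5))
      sv_target <- sample.int(n, 5, replace = TRUE)
      geno <- c(geno, purrr::map(1:5, function(i) {
        tr <- trios[sv_target[i], ]
        gt <- ifelse(samples == tr$proband_id, "het", "hom_ref")
        if (sv_rules[i] == "low_call_rate") {
          # 45% of samples uncalled in the input: call rate 0.55 < 0.60
          uncalled <- sample(setdiff(samples, c(tr$proband_id, tr$father_id,
                                                tr$mother_id)),
                             ceiling(0.45 * length(samples)))
          gt[samples %in% uncalled] <- "missing"
        }
        if (sv_rules[i] == "hwe") {
          # founders split hom_ref / hom_alt with no heterozygotes
          gt <- ifelse(samples %in% trios$father_id, "hom_alt",
                       ifelse(samples %in% trios$mother_id, "hom_ref", "het"))
        }
        pass_geno(sv[i, ], samples, gt)
      }))
      violations <- bind_rows(violations, tibble(
        site_id = sv$site_id, chrom = sv$chrom, pos = sv$pos,
        level = "site", rule = sv_rules, sample_id = NA_character_))

      gene_map_extra <- bind_rows(
        select(inh_sites, dplyr::all_of(c("chrom", "pos", "gene"))),
        select(gv, dplyr::all_of(c("chrom", "pos", "gene"))),
        select(sv, dplyr::all_of(c("chrom", "pos", "gene")))) |>
        mutate(functional_class = "missense")
    } else {
      gene_map_extra <- tibble(chrom = character(0), pos = numeric(0),
                               gene = character(0),
                               functional_class = character(0))
    }

    genotypes <- list_rbind(geno)
    gene_map <- bind_rows(
      select(planted, dplyr::all_of(c("chrom", "pos", "gene",
                                      "functional_class"))),
      gene_map_extra)

    pedigree <- bind_rows(
      tibble(family_id = trios$trio_id, sample_id = trios$father_id,
             father_id = "0", mother_id = "0", sex = 1L, phenotype = 1L),
      tibble(family_id = trios$trio_id, sample_id = trios$mother_id,
             father_id = "0", mother_id = "0", sex = 2L, phenotype = 1L),
      tibble(family_id = trios$trio_id, sample_id = trios$proband_id,
             father_id = trios$father_id, mother_id = trios$mother_id,
             sex = 1L, phenotype = 2L)) |>
      arrange(.data$family_id)

    truth <- list(
      planted_dnvs = select(planted, dplyr::all_of(
        c("site_id", "trio_id", "chrom", "pos", "ref", "alt", "gene",
          "functional_class", "damaging"))),
      qc_violations = violations,
      seed = seed)

    list(genotypes = genotypes, trios = trios, pedigree = pedigree,
         gene_map = gene_map, truth = truth)
  })
}

#' Simulate predictor profiles for DNV records
#'
#' Gives every DNV the seven categorical predictor calls: profiles flagged
#' damaging receive at least one damaging-class code (in one to three
#' randomly chosen predictors), non-damaging profiles receive only
#' benign-class codes, and frameshift records get all-missing calls, since
#' the missense predictors do not score indels. `max_af` is missing for most
#' records and otherwise below 1%.
#'
#' @param dnvs Tibble with columns `gene` and `functional_class`; if a
#'   logical `damaging` column is present it is honoured, otherwise flags are
#'   drawn Bernoulli(`damaging_fraction`) for missense records.
#' @param damaging_fraction Probability a missense record is damaging.
#' @param seed Optional integer seed.
#' @return The input tibble with the seven predictor columns, `max_af`, and
#'   the truth flag `damaging_truth` appended.
#' @export
simulate_predictor_profiles <- function(dnvs, damaging_fraction = 40 / 47,
                                        seed = NULL) {
  if (nrow(dnvs) == 0) abort("`dnvs` is empty")
  check_columns(dnvs, "functional_class", "`dnvs`")
  with_seed_if(seed, {
    n <- nrow(dnvs)
    flag <- if ("damaging" %in% names(dnvs)) {
      ifelse(is.na(dnvs$damaging), FALSE, dnvs$damaging)
    } else {
      runif(n) < damaging_fraction
    }
    flag[dnvs$functional_class == "frameshift"] <- FALSE

    benign <- list(sift = "T", polyphen2_hdiv = "B", polyphen2_hvar = "B",
                   lrt = c("N", "U"), mutation_taster = "N",
                   mutation_assessor = c("L", "N"), fathmm = "T")
    damaging <- predictor_damaging

    out <- dnvs
    fields <- predictor_columns()
    profiles <- purrr::map(seq_len(n), function(i) {
      if (dnvs$functional_class[i] == "frameshift") {
        return(setNames(rep(".", 7), fields))
      }
      n_tx <- sample(1:4, 7, replace = TRUE)
      prof <- vapply(seq_along(fields), function(j) {
        paste(sample(benign[[fields[j]]], n_tx[j], replace = TRUE),
              collapse = ";")
      }, character(1))
      if (flag[i]) {
        hit_fields <- sample(7, sample(1:3, 1))
        for (j in hit_fields) {
          codes <- strsplit(prof[j], ";")[[1]]
          codes[sample(length(codes), 1)] <-
            sample(damaging[[fields[j]]], 1)
          prof[j] <- paste(codes, collapse = ";")
        }
      }
      setNames(prof, fields)
    })
    for (f in fields) {
      out[[f]] <- vapply(profiles, `[[`, character(1), f)
    }
    out$max_af <- ifelse(runif(n) < 0.8, NA_real_,
                         round(runif(n, 0, 0.0099), 6))
    out$damaging_truth <- flag
    out
  })
}

#' Simulate a BrainSpan-like expression dataset
#'
#' Background genes are independent Gaussian noise in every stratum. The
#' first `module_genes` case genes follow, in the designated module strata, a
#' shared per-sample latent factor with loading `module_loading` plus
#' `noise_sd`-scaled noise, which yields high pairwise Spearman correlation
#' in exactly those strata. Values are generated on a continuous scale with
#' no attempt to mimic RNA-seq count distributions: every downstream
#' statistic is rank-based and only sees the ordering.
#'
#' @param config A [sim_config()].
#' @param case_genes,control_genes Gene symbols to carry in the matrix (the
#'   module is planted in the head of `case_genes`).
#' @param seed Optional integer seed; defaults to a sub-stream of
#'   `config$seed`.
#' @return An [expression_dataset()].
#' @export
simulate_expression <- function(config = sim_config(), case_genes,
                                control_genes, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% substream_seed(config$seed, "expression")
  with_seed_if(seed, {
    strata <- config$strata
    background <- setdiff(universe_genes(config$n_genes),
                          c(case_genes, control_genes))
    background <- background[seq_len(min(config$n_expression_background,
                                         length(background)))]
    genes <- unique(c(case_genes, control_genes, background))
    module <- case_genes[seq_len(min(config$module_genes,
                                     length(case_genes)))]

    blocks <- purrr::map(seq_len(nrow(strata)), function(i) {
      st <- strata[i, ]
      ns <- st$n_samples
      ids <- sprintf("%s_s%02d", st$name, seq_len(ns))
      age <- switch(st$stage,
        prenatal = list(round(runif(ns, 8, 37), 1), "pcw"),
        infancy_childhood = list(round(runif(ns, 4, 132), 1), "month"),
        adolescence_adulthood = list(round(runif(ns, 13, 23), 1), "year"),
        abort(sprintf("unknown stage '%s' in strata", st$stage)))
      m <- matrix(rnorm(length(genes) * ns), nrow = length(genes),
                  dimnames = list(genes, ids))
      if (st$name %in% config$module_strata && length(module) > 0) {
        f <- rnorm(ns)
        m[module, ] <- config$module_loading *
          matrix(f, nrow = length(module), ncol = ns, byrow = TRUE) +
          config$noise_sd * matrix(rnorm(length(module) * ns),
                                   nrow = length(module))
      }
      meta <- tibble(sample_id = ids, region = st$region,
                     subregion = st$subregion, age_value = age[[1]],
                     age_unit = age[[2]])
      list(m = m, meta = meta)
    })
    expression_dataset(
      do.call(cbind, purrr::map(blocks, "m")),
      list_rbind(purrr::map(blocks, "meta")))
  })
}

#' Simulate reference gene lists, scores, loci and coordinates
#'
#' Draws the constrained-gene, brain-critical-exon and prior-study lists from
#' the gene universe with configured planted overlaps with the case genes;
#' picks a disjoint control DNV gene list; builds a gene score table
#' (haploinsufficiency and recessive probability in \[0, 1\], real-valued
#' RVIS at two allele-frequency variants, critical-exon scores for list
#' members) with configured case-versus-background shifts; and lays out GWAS
#' locus intervals with a planted number of case genes inside loci.
#'
#' @param config A [sim_config()].
#' @param case_genes Case gene symbols (must fit in the universe).
#' @param seed Optional integer seed; defaults to a sub-stream of
#'   `config$seed`.
#' @return A list: `constrained`, `critical_exon`, `prior_study`,
#'   `control_genes` (character vectors), `gene_scores` (tibble),
#'   `gene_coords`, `gwas_loci` (tibbles), and `truth` with the planted
#'   overlaps.
#' @export
simulate_reference_lists <- function(config = sim_config(), case_genes,
                                     seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% substream_seed(config$seed, "reference_lists")
  case_genes <- unique(case_genes)
  univ <- universe_genes(config$n_genes)
  if (!all(case_genes %in% univ)) abort("case genes outside the universe")
  with_seed_if(seed, {
    non_case <- setdiff(univ, case_genes)
    draw_list <- function(size, overlap) {
      if (size > length(univ)) abort("requested list larger than the universe")
      overlap <- min(overlap, length(case_genes), size)
      sort(c(sample(case_genes, overlap),
             sample(non_case, size - overlap)))
    }
    constrained <- draw_list(config$constrained_size, config$overlap_constrained)
    critical_exon <- draw_list(config$critical_exon_size,
                               config$overlap_critical_exon)
    prior_study <- draw_list(config$prior_study_size, config$overlap_prior)
    control_genes <- sample(non_case, config$n_control_genes)

    is_case <- univ %in% case_genes
    scores <- tibble(
      gene = univ,
      haploinsufficiency = pmin(1, rbeta(length(univ), 2, 5) +
                                  ifelse(is_case, config$hi_shift, 0)),
      recessive_probability = rbeta(length(univ), 2, 5),
      rvis_01 = rnorm(length(univ)) + ifelse(is_case, config$rvis_shift_01, 0),
      rvis_1 = rnorm(length(univ)) + ifelse(is_case, config$rvis_shift_1, 0),
      critical_exon_score = ifelse(univ %in% critical_exon,
                                   round(runif(length(univ), 0.5, 6), 2),
                                   NA_real_))

    # GWAS loci (~250 kb) and case-gene coordinates; `overlap_gwas` case
    # genes are placed inside loci, the rest far away.
    loci <- tibble(
      label = sprintf("locus%03d", seq_len(config$n_gwas_loci)),
      chrom = as.character(sample(1:22, config$n_gwas_loci, replace = TRUE)),
      start = sample.int(1e8, config$n_gwas_loci) + 1e6) |>
      mutate(end = .data$start + round(runif(config$n_gwas_loci, 1e5, 4e5)))
    n_hit <- min(config$overlap_gwas, length(case_genes),
                 config$n_gwas_loci)
    hit_genes <- sample(case_genes, n_hit)
    hit_loci <- loci[sample.int(nrow(loci), n_hit), ]
    coords <- tibble(
      gene = case_genes,
      chrom = as.character(sample(1:22, length(case_genes), replace = TRUE)),
      start = sample.int(1e8, length(case_genes)) + 2.2e8) |>
      mutate(end = .data$start + sample(2e3:2e5, length(case_genes),
                                        replace = TRUE))
    idx <- match(hit_genes, coords$gene)
    coords$chrom[idx] <- hit_loci$chrom
    coords$start[idx] <- hit_loci$start +
      round((hit_loci$end - hit_loci$start) * 0.25)
    coords$end[idx] <- pmin(hit_loci$end,
                            coords$start[idx] + 2e4)

    list(constrained = constrained, critical_exon = critical_exon,
         prior_study = prior_study, control_genes = control_genes,
         gene_scores = scores, gene_coords = coords, gwas_loci = loci,
         truth = list(
           overlap_constrained = sort(intersect(case_genes, constrained)),
           overlap_critical_exon = sort(intersect(case_genes, critical_exon)),
           overlap_prior = sort(intersect(case_genes, prior_study)),
           gwas_hit_genes = sort(hit_genes),
           seed = seed))
  })
}

#' Simulate a complete study
#'
#' Convenience wrapper running every generator off independent sub-streams of
#' `config$seed`: the trio cohort, predictor profiles for the planted DNVs,
#' the reference lists and scores, and the expression dataset (case genes =
#' genes carrying planted non-synonymous DNVs).
#'
#' @param config A [sim_config()].
#' @param add_contaminants Passed to [simulate_trio_cohort()].
#' @return A list with components `cohort`, `profiles`, `refs`, `expression`
#'   and `case_genes`.
#' @export
simulate_study <- function(config = sim_config(), add_contaminants = TRUE) {
  cohort <- simulate_trio_cohort(config, add_contaminants = add_contaminants)
  planted <- cohort$truth$planted_dnvs
  nonsyn <- filter(planted, .data$functional_class != "synonymous")
  profiles <- if (nrow(nonsyn) > 0) {
    simulate_predictor_profiles(
      nonsyn, config$damaging_fraction,
      seed = substream_seed(config$seed, "profiles"))
  } else NULL
  case_genes <- unique(nonsyn$gene)
  refs <- simulate_reference_lists(config, case_genes)
  expr <- simulate_expression(config, case_genes, refs$control_genes)
  list(cohort = cohort, profiles = profiles, refs = refs, expression = expr,
       case_genes = case_genes)
}
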