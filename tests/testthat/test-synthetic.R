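test_that("generators are bit-reproducible under a fixed master seed", {
  cfg <- sim_config(n_trios = 8, seed = 55)
  a <- simulate_trio_cohort(cfg)
  b <- simulate_trio_cohort(cfg)
  expect_identical(a, b)

  ra <- simulate_reference_lists(cfg, sprintf("G%05d", 1:10))
  rb <- simulate_reference_lists(cfg, sprintf("G%05d", 1:10))
  expect_identical(ra, rb)

  ea <- simulate_expression(cfg, sprintf("G%05d", 1:10), sprintf("G%05d", 21:60))
  eb <- simulate_expression(cfg, sprintf("G%05d", 1:10), sprintf("G%05d", 21:60))
  expect_identical(ea, eb)
})

test_that("sub-streams keep generators independent of one another", {
  cfg <- sim_config(n_trios = 8, seed = 55)
  base <- simulate_trio_cohort(cfg)
  # running an unrelated generator in between must not change the cohort
  invisible(simulate_expression(cfg, sprintf("G%05d", 1:5), sprintf("G%05d", 6:30)))
  expect_identical(simulate_trio_cohort(cfg), base)
  expect_true(substream_seed(1, "a") != substream_seed(1, "b"))
  expect_lt(substream_seed(.Machine$integer.max, "expression"), 2^31)
})

test_that("config validation rejects impossible studies", {
  expect_error(sim_config(n_trios = 0), "positive")
  expect_error(sim_config(dnv_rate_lambda = -1), "non-negative")
  expect_error(sim_config(module_loading = 1.5), "0, 1")
  expect_error(sim_config(strata = default_strata(n_samples = 2)), ">= 4")
  expect_error(sim_config(module_strata = "nope"), "rows of")
  expect_error(sim_config(n_sporadic = 99, n_trios = 10), "exceed")
})

test_that("planted DNV counts follow the configured Poisson rate", {
  # pool per-trio counts across seeds and test the rate and fit
  counts <- unlist(lapply(1:12, function(s) {
    sim <- simulate_trio_cohort(sim_config(n_trios = 32, dnv_rate_lambda = 0.81,
                                           seed = s), add_contaminants = FALSE)
    tab <- table(factor(sim$truth$planted_dnvs$trio_id,
                        levels = sim$trios$trio_id))
    as.integer(tab)
  }))
  expect_equal(length(counts), 12 * 32)
  expect_lt(abs(mean(counts) - 0.81), 3 * sqrt(0.81 / length(counts)))
  expect_gt(poisson_fit(counts)$gof_p, 0.01)
})

test_that("a zero DNV rate plants nothing but keeps background records", {
  sim <- simulate_trio_cohort(sim_config(n_trios = 6, dnv_rate_lambda = 0,
                                         seed = 3))
  expect_equal(nrow(sim$truth$planted_dnvs), 0)
  expect_gt(nrow(sim$genotypes), 0)
  called <- call_dnvs(filter_variants(filter_genotypes(sim$genotypes),
                                      sim$trios), sim$trios)
  expect_equal(nrow(called), 0)
})

test_that("the truth ledger is a complete, recoverable account of planted objects", {
  sim <- simulate_trio_cohort(sim_config(n_trios = 12, seed = 41))
  planted <- sim$truth$planted_dnvs
  expect_false(anyDuplicated(planted$site_id) > 0)
  # every planted DNV is present in the genotype table at its coordinates
  key_geno <- unique(paste(sim$genotypes$chrom, sim$genotypes$pos))
  expect_true(all(paste(planted$chrom, planted$pos) %in% key_geno))
  # and in the gene map with its functional class
  gm <- paste(sim$gene_map$chrom, sim$gene_map$pos, sim$gene_map$gene)
  expect_true(all(paste(planted$chrom, planted$pos, planted$gene) %in% gm))
  # every QC violation names a site present in the data
  expect_true(all(paste(sim$truth$qc_violations$chrom,
                        sim$truth$qc_violations$pos) %in% key_geno))
})

test_that("predictor profiles realise the requested damaging status", {
  dnvs <- tibble::tibble(gene = sprintf("G%05d", 1:60),
                         functional_class = c(rep("missense", 56),
                                              rep("frameshift", 4)))
  all_dmg <- simulate_predictor_profiles(dnvs, damaging_fraction = 1, seed = 5)
  cl <- classify_damaging(all_dmg)
  expect_true(all(cl$damaging[cl$functional_class == "missense"]))
  expect_false(any(cl$damaging[cl$functional_class == "frameshift"]))
  expect_true(all(all_dmg$sift[all_dmg$functional_class == "frameshift"] == "."))

  none <- simulate_predictor_profiles(dnvs, damaging_fraction = 0, seed = 5)
  expect_false(any(classify_damaging(none)$damaging))

  # truth flags agree with the downstream classifier row by row
  mid <- simulate_predictor_profiles(dnvs, damaging_fraction = 0.5, seed = 9)
  expect_equal(classify_damaging(mid)$damaging, mid$damaging_truth)
  # MAF never at or above 1%
  expect_true(all(is.na(mid$max_af) | mid$max_af < 0.01))
})

test_that("the realised damaging count matches the binomial expectation", {
  # fraction 40/47 over 47 missense records, averaged across seeds
  dnvs <- tibble::tibble(gene = sprintf("G%05d", 1:47),
                         functional_class = "missense")
  hits <- vapply(1:30, function(s) {
    prof <- simulate_predictor_profiles(dnvs, damaging_fraction = 40 / 47,
                                        seed = s)
    sum(classify_damaging(prof)$damaging)
  }, numeric(1))
  expectation <- 40
  se <- sqrt(47 * (40 / 47) * (7 / 47) / 30)
  expect_lt(abs(mean(hits) - expectation), 4 * se)
})

test_that("expression strata carry metadata and the module only where planted", {
  cfg <- sim_config(n_trios = 6, module_genes = 6, module_loading = 0.95,
                    noise_sd = 0.1, seed = 61,
                    strata = default_strata(n_samples = 20))
  case <- sprintf("G%05d", 1:10)
  ctrl <- sprintf("G%05d", 51:140)
  ds <- simulate_expression(cfg, case, ctrl)

  # stratum partition matches the configured layout exactly
  got <- dplyr::count(ds$sample_meta, subregion, age_unit)
  expect_equal(sum(got$n), sum(cfg$strata$n_samples))
  expect_setequal(unique(ds$sample_meta$subregion), c("VFC", "MFC", "OFC", "ITC"))

  prenatal <- stratum_spec("p-VFC", "VFC", "prenatal")
  postnatal <- stratum_spec("a-VFC", "VFC", "adolescence_adulthood")
  module <- case[1:6]
  net_pre <- build_network(module, ds, prenatal, cutoff = 0.8)
  net_post <- build_network(module, ds, postnatal, cutoff = 0.8)
  expect_equal(nrow(net_pre), choose(6, 2))   # near-degenerate factor model
  expect_lt(nrow(net_post), 3)                # nothing planted postnatally
})

test_that("a zero loading leaves module genes indistinguishable from noise", {
  cfg <- sim_config(module_loading = 0, seed = 71,
                    strata = default_strata(n_samples = 24))
  case <- sprintf("G%05d", 1:20)
  ds <- simulate_expression(cfg, case, sprintf("G%05d", 101:200))
  net <- build_network(case, ds, stratum_spec("p-VFC", "VFC", "prenatal"),
                       cutoff = 0.8)
  expect_lt(nrow(net), 3)
})

test_that("reference lists hold the planted overlaps and score shifts", {
  cfg <- sim_config(seed = 83)
  case <- sprintf("G%05d", 101:140)  # 40 case genes
  refs <- simulate_reference_lists(cfg, case)

  expect_equal(length(refs$constrained), 1000)
  expect_equal(length(refs$critical_exon), 1744)
  expect_equal(length(refs$prior_study), 733)
  expect_equal(length(refs$control_genes), 240)
  expect_equal(length(intersect(case, refs$constrained)), 8)
  expect_equal(length(intersect(case, refs$critical_exon)), 8)
  expect_equal(length(intersect(case, refs$prior_study)), 4)
  expect_equal(length(intersect(case, refs$control_genes)), 0)

  # ledger matches the realised lists
  expect_equal(refs$truth$overlap_prior,
               sort(intersect(case, refs$prior_study)))

  # GWAS: exactly the planted case gene overlaps a locus
  hits <- gwas_overlap(refs$gene_coords, refs$gwas_loci)
  expect_equal(sort(unique(hits$gene)), refs$truth$gwas_hit_genes)

  sc <- refs$gene_scores
  expect_true(all(sc$haploinsufficiency >= 0 & sc$haploinsufficiency <= 1))
  is_case <- sc$gene %in% case
  expect_gt(mean(sc$haploinsufficiency[is_case]),
            mean(sc$haploinsufficiency[!is_case]))
  expect_lt(mean(sc$rvis_01[is_case]), mean(sc$rvis_01[!is_case]))

  expect_error(simulate_reference_lists(sim_config(n_genes = 500), case),
               "universe")
})

test_that("an unshifted score yields calibrated empirical p-values", {
  # RVIS shift 0: the case mean is exchangeable with random draws
  small <- function(s) sim_config(
    n_genes = 400, rvis_shift_01 = 0, rvis_shift_1 = 0, hi_shift = 0,
    constrained_size = 50, critical_exon_size = 50, prior_study_size = 50,
    n_gwas_loci = 10, n_control_genes = 40, seed = s)
  ps <- vapply(1:60, function(s) {
    refs <- simulate_reference_lists(small(s), sprintf("G%05d", 1:20))
    vals <- setNames(refs$gene_scores$rvis_01, refs$gene_scores$gene)
    empirical_set_test(sprintf("G%05d", 1:20), values = vals,
                       statistic = "mean", direction = "less_equal",
                       t = 200, seed = s)$p
  }, numeric(1))
  # uniform-ish: mean near 1/2, no mass piling at either end
  expect_lt(abs(mean(ps) - 0.5), 0.12)
  expect_gt(min(ps), 1 / 201 - 1e-12)
})
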