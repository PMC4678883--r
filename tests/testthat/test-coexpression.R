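test_that("stratification applies subregion and inclusive age windows", {
  ds <- tiny_expression(n_samples = 5)
  ds$sample_meta$age_value <- c(12, 37.0, 38, 12, 9)
  ds$sample_meta$subregion <- c("VFC", "VFC", "VFC", "DFC", "VFC")
  sp <- stratum_spec("prenatal-VFC", "VFC", "prenatal")
  out <- stratify(ds, sp)
  # 38 pcw is past the window; the DFC sample is the wrong subregion
  expect_setequal(out$sample_meta$sample_id, c("s01", "s02", "s05"))

  # 12 years falls between the postnatal stages: excluded from both
  ds$sample_meta$age_value <- rep(12, 5)
  ds$sample_meta$age_unit <- "year"
  ds$sample_meta$subregion <- "VFC"
  expect_error(stratify(ds, stratum_spec("aa-VFC", "VFC", "adolescence_adulthood")),
               "no samples")
  expect_error(stratify(ds, stratum_spec("ic-VFC", "VFC", "infancy_childhood")),
               "no samples")
  # 11 years is inside infancy/childhood (inclusive bound)
  ds$sample_meta$age_value <- rep(11, 5)
  expect_equal(ncol(stratify(ds, stratum_spec("ic-VFC", "VFC", "infancy_childhood"))$matrix), 5)
})

test_that("Spearman correlation is a rank statistic with defined edge cases", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_r(x, exp(x)), 1)       # any increasing transform
  expect_equal(spearman_r(x, -x), -1)
  expect_warning(r <- spearman_r(x, rep(2, 5)), "constant")
  expect_true(is.na(r))
  expect_error(spearman_r(1:4, 1:5), "equal length")
  expect_error(spearman_r(1:2, 2:1), "at least 3")

  # oracle: direct rank-formula computation on length-5 vectors with ties
  withr::with_seed(3, {
    for (i in 1:10) {
      a <- sample(1:4, 5, replace = TRUE) + runif(5, 0, 0.2)
      b <- rnorm(5)
      ra <- rank(a); rb <- rank(b)
      oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
        sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
      expect_equal(spearman_r(a, b), oracle, tolerance = 1e-12)
    }
  })
})

test_that("network construction keeps |r| >= cutoff pairs with signs", {
  ds <- tiny_expression(planted_pair = TRUE)
  net <- build_network(c("g01", "g02", "g03"), ds, cutoff = 0.8)
  expect_equal(nrow(net), 1)
  expect_equal(net$gene_a, "g01")
  expect_equal(net$gene_b, "g02")
  expect_equal(net$r, 1)
  expect_equal(net$sign, "positive")
  expect_equal(attr(net, "nodes"), c("g01", "g02"))

  # genes missing from the matrix are dropped with a message
  expect_message(build_network(c("g01", "g02", "nope"), ds, cutoff = 0.8),
                 "lacking expression")
  expect_error(suppressMessages(build_network(c("no1", "no2"), ds)), "none")
})

test_that("independent noise genes form almost no edges at cutoff 0.8", {
  ds <- tiny_expression(n_genes = 30, n_samples = 20, seed = 99)
  net <- build_network(rownames(ds$matrix), ds, cutoff = 0.8)
  # permutation tail: P(|spearman r| >= 0.8) at n = 20 is ~1e-4, so the
  # expected count over 435 pairs is well under one
  expect_lt(nrow(net), 3)
})

test_that("networks are invariant to monotone transforms, sample order and gene order", {
  ds <- tiny_expression(n_genes = 8, n_samples = 12, seed = 17, planted_pair = TRUE)
  genes <- rownames(ds$matrix)
  net <- build_network(genes, ds, cutoff = 0.5)

  # strictly monotone per-gene transform
  m2 <- t(apply(ds$matrix, 1, function(r) exp(r / 2) + 1))
  dimnames(m2) <- dimnames(ds$matrix)
  net2 <- build_network(genes, expression_dataset(m2, ds$sample_meta), cutoff = 0.5)
  expect_equal(as.data.frame(net), as.data.frame(net2))

  # sample reordering
  perm <- sample(ncol(ds$matrix))
  net3 <- build_network(genes, expression_dataset(ds$matrix[, perm],
                                                  ds$sample_meta), cutoff = 0.5)
  expect_equal(as.data.frame(net), as.data.frame(net3))

  # gene input order
  net4 <- build_network(rev(genes), ds, cutoff = 0.5)
  expect_equal(as.data.frame(net), as.data.frame(net4))
})

test_that("merging unions edges, keeps the strongest r and matches igraph components", {
  e1 <- build_network(c("g01", "g02"), tiny_expression(planted_pair = TRUE), cutoff = 0.8)
  ds2 <- tiny_expression(seed = 2)
  ds2$matrix["g04", ] <- -3 * ds2$matrix["g03", ]
  e2 <- build_network(c("g03", "g04"), ds2, cutoff = 0.8)

  merged <- merge_networks(list(e1, e2))
  expect_equal(nrow(merged), 2)
  expect_equal(length(attr(merged, "nodes")), 4)
  # idempotence on identical inputs
  same <- merge_networks(list(e1, e1))
  expect_equal(same$r, e1$r)
  expect_equal(nrow(same), nrow(e1))

  # component count agrees with an independent graph library
  comp <- igraph::components(as_igraph(merged))$no
  expect_equal(comp, 2)
})

test_that("hub genes are the nodes at or above the degree threshold", {
  expect_equal(nrow(hub_genes(build_network(
    c("g01", "g03"), tiny_expression(), cutoff = 2))), 0)  # empty network

  # star graph: centre degree 9, leaves degree 1
  star <- tibble::tibble(gene_a = pmin("hub", sprintf("leaf%02d", 1:9)),
                         gene_b = pmax("hub", sprintf("leaf%02d", 1:9)),
                         r = 0.9, sign = "positive", stratum = "x")
  class(star) <- c("coexpression_network", class(star))
  hubs <- hub_genes(star, min_degree = 9)
  expect_equal(hubs$gene, "hub")
  expect_equal(hubs$degree, 9)

  # random graph: degrees agree with brute-force adjacency counting
  withr::with_seed(6, {
    pairs <- t(combn(sprintf("n%02d", 1:8), 2))
    keep <- runif(nrow(pairs)) < 0.4
    g <- tibble::tibble(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
                        r = 0.85, sign = "positive", stratum = "x")
    class(g) <- c("coexpression_network", class(g))
    all_deg <- hub_genes(g, min_degree = 0)
    brute <- table(c(g$gene_a, g$gene_b))
    expect_equal(all_deg$degree[match(names(brute), all_deg$gene)],
                 unname(as.integer(brute)))
  })
})

test_that("connectedness test matches exhaustive enumeration on a tiny control pool", {
  # 8 control genes, case size 3: all 56 subsets enumerable
  ds <- tiny_expression(n_genes = 11, n_samples = 12, seed = 23)
  ds$matrix[2, ] <- ds$matrix[1, ] + rnorm(12, sd = 0.05)  # case pair edge
  case <- c("g01", "g02", "g03")
  ctrl <- sprintf("g%02d", 4:11)
  cutoff <- 0.6

  res <- connectedness_test(case, ctrl, ds, cutoff = cutoff, t = 20000, seed = 77)

  # oracle: brute-force edges over every 3-subset of the controls
  R <- cor(apply(ds$matrix, 1, rank))  # genes in columns
  edges_of <- function(gs) sum(abs(R[gs, gs])[upper.tri(R[gs, gs])] >= cutoff)
  obs <- edges_of(case)
  expect_equal(res$n_edges, obs)
  combos <- combn(ctrl, 3)
  q <- mean(apply(combos, 2, edges_of) >= obs)
  se <- sqrt(q * (1 - q) / 20000)
  expect_lt(abs(res$empirical$p - q), 3 * se + 1 / 20001)
})

test_that("connectedness p is near 1 for unrelated cases and minimal for a planted module", {
  cfg <- sim_config(n_trios = 10, module_genes = 10, seed = 19,
                    strata = default_strata(n_samples = 30))
  case <- sprintf("G%05d", 1:20)
  ctrl <- sprintf("G%05d", 101:300)
  ds <- simulate_expression(cfg, case, ctrl)
  sp <- stratum_spec("prenatal-VFC", "VFC", "prenatal")

  planted <- connectedness_test(case, ctrl, ds, sp, t = 999, seed = 4)
  expect_equal(planted$empirical$p, 1 / 1000)  # controls are pure noise
  expect_gte(planted$n_edges, choose(10, 2) * 0.9)

  # swap roles: an uncorrelated case set against controls is unremarkable
  null_case <- sprintf("G%05d", 201:220)
  flat <- connectedness_test(null_case, sprintf("G%05d", 251:450), ds, sp,
                             t = 499, seed = 4)
  expect_gt(flat$empirical$p, 0.5)
})

test_that("the stratified suite applies the Bonferroni family", {
  cfg <- sim_config(n_trios = 10, module_genes = 8, seed = 29,
                    strata = default_strata(n_samples = 20))
  case <- sprintf("G%05d", 1:12)
  ctrl <- sprintf("G%05d", 101:220)
  ds <- simulate_expression(cfg, case, ctrl)
  strata <- list(stratum_spec("prenatal-VFC", "VFC", "prenatal"),
                 stratum_spec("prenatal-MFC", "MFC", "prenatal"))
  suite <- connectedness_suite(case, ctrl, ds, strata, t = 199, seed = 3,
                               n_tests = 12)
  expect_equal(suite$bonferroni_p, pmin(1, suite$p * 12))
  expect_true(all(suite$bonferroni_p >= suite$p))
})
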