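test_that("GWAS overlap uses closed-interval intersection per chromosome", {
  genes <- tibble::tibble(gene = c("LRP1like", "elsewhere"),
                          chrom = c("12", "3"),
                          start = c(57500000, 57500000),
                          end = c(57520000, 57520000))
  loci <- tibble::tibble(chrom = "12", start = 57428314, end = 57682971,
                         label = "locus020")
  hits <- gwas_overlap(genes, loci)
  expect_equal(hits$gene, "LRP1like")
  expect_equal(hits$label, "locus020")

  # touching endpoints overlap under closed coordinates
  touch <- gwas_overlap(
    tibble::tibble(gene = "g", chrom = "1", start = 100, end = 200),
    tibble::tibble(chrom = "1", start = 200, end = 300, label = "L"))
  expect_equal(nrow(touch), 1)
  expect_error(gwas_overlap(
    tibble::tibble(gene = "g", chrom = "1", start = 5, end = 2), loci),
    "malformed")
})

test_that("GWAS overlap agrees with a quadratic brute-force oracle and is shift-invariant", {
  withr::with_seed(14, {
    genes <- tibble::tibble(
      gene = sprintf("g%02d", 1:25),
      chrom = as.character(sample(1:3, 25, replace = TRUE)),
      start = sample.int(1e5, 25))
    genes$end <- genes$start + sample.int(2e4, 25)
    loci <- tibble::tibble(
      chrom = as.character(sample(1:3, 10, replace = TRUE)),
      start = sample.int(1e5, 10), label = sprintf("L%02d", 1:10))
    loci$end <- loci$start + sample.int(3e4, 10)
  })
  hits <- gwas_overlap(genes, loci)
  brute <- list()
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(loci))) {
    if (genes$chrom[i] == loci$chrom[j] &&
          genes$start[i] <= loci$end[j] && loci$start[j] <= genes$end[i]) {
      brute[[length(brute) + 1]] <- c(genes$gene[i], loci$label[j])
    }
  }
  brute <- do.call(rbind, brute)
  expect_equal(nrow(hits), nrow(brute))
  expect_setequal(paste(hits$gene, hits$label), paste(brute[, 1], brute[, 2]))

  # shifting every coordinate by a constant preserves the hit set
  shifted <- gwas_overlap(
    dplyr::mutate(genes, start = start + 7e4, end = end + 7e4),
    dplyr::mutate(loci, start = start + 7e4, end = end + 7e4))
  expect_setequal(paste(hits$gene, hits$label),
                  paste(shifted$gene, shifted$label))
})

test_that("BED intervals convert to 1-based closed coordinates", {
  bed <- tibble::tibble(chrom = "1", start = 0, end = 10)
  conv <- bed_to_closed(bed)
  expect_equal(conv$start, 1)
  expect_equal(conv$end, 10)
})

test_that("evidence integration counts flags, ranks densely and is idempotent", {
  flags <- list(rvis = c("a", "b", "c"), constrained = c("a", "b"),
                critical_exon = "a", hub = "a", prior = "a", gwas = "a")
  ev <- integrate_evidence(flags)
  expect_equal(ev$evidence_count[ev$gene == "a"], 6)
  expect_equal(ev$rank[ev$gene == "a"], 1)
  expect_equal(ev$rank[ev$gene == "b"], 2)
  expect_equal(ev$rank[ev$gene == "c"], 3)

  # permutation invariance in row order and idempotence through the tibble form
  tbl <- ev[, c("gene", names(flags))]
  again <- integrate_evidence(tbl[sample.int(nrow(tbl)), ])
  expect_equal(as.data.frame(again[, names(ev)]), as.data.frame(ev))

  # counts equal independent row sums
  withr::with_seed(16, {
    rnd <- tibble::tibble(gene = sprintf("g%02d", 1:15),
                          f1 = runif(15) < 0.5, f2 = runif(15) < 0.5,
                          f3 = runif(15) < 0.5)
  })
  out <- integrate_evidence(rnd)
  expect_equal(out$evidence_count,
               rowSums(as.matrix(out[, c("f1", "f2", "f3")])))

  # all-empty flags: single rank
  none <- integrate_evidence(list(a = character(0)), genes = c("x", "y"))
  expect_true(all(none$evidence_count == 0))
  expect_true(all(none$rank == 1))

  expect_error(integrate_evidence(tibble::tibble(gene = c("a", "a"), f = TRUE)),
               "duplicate")
})

test_that("cognition regression matches closed-form OLS and flags degenerate input", {
  counts <- tibble::tibble(subject_id = c("s1", "s2", "s3", "s4"),
                           n_dnvs = c(0, 1, 2, 3))
  # exact linear outcome: slope 2, vanishing p
  meas <- tibble::tibble(subject_id = counts$subject_id,
                         stroop = 2 * counts$n_dnvs + 1)
  fit <- suppressWarnings(cognition_regression(counts, meas))  # exact fit warning
  expect_equal(fit$slope, 2)
  expect_lt(fit$p_value, 1e-10)
  expect_equal(fit$n, 4)

  # closed-form simple-regression oracle on a minimal n = 3 case
  c3 <- counts[1:3, ]
  y <- c(1.2, 0.4, 2.9)
  m3 <- tibble::tibble(subject_id = c3$subject_id, wcst = y)
  fit3 <- cognition_regression(c3, m3)
  x <- c3$n_dnvs
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  resid <- y - (mean(y) - beta * mean(x)) - beta * x
  se <- sqrt(sum(resid^2) / 1 / sum((x - mean(x))^2))
  expect_equal(fit3$slope, beta, tolerance = 1e-12)
  expect_equal(fit3$slope_se, se, tolerance = 1e-12)
  expect_equal(fit3$p_value, 2 * pt(abs(beta / se), df = 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # missing outcomes are dropped per outcome
  m4 <- tibble::tibble(subject_id = counts$subject_id,
                       a = c(1, NA, 3, 4), b = c(5, 6, 7, 8))
  fit4 <- suppressWarnings(cognition_regression(counts, m4))
  expect_equal(fit4$n, c(3, 4))

  expect_error(cognition_regression(counts[1:2, ], meas[1:2, ]), "fewer than 3")
  expect_error(cognition_regression(dplyr::mutate(counts, n_dnvs = 2), meas),
               "zero variance")
})

test_that("slope p-values are calibrated under the null", {
  withr::with_seed(77, {
    ps <- replicate(1000, {
      counts <- tibble::tibble(subject_id = as.character(1:20),
                               n_dnvs = rpois(20, 1.2))
      if (var(counts$n_dnvs) == 0) return(NA_real_)
      meas <- tibble::tibble(subject_id = counts$subject_id, y = rnorm(20))
      cognition_regression(counts, meas)$p_value
    })
  })
  rej <- mean(ps < 0.05, na.rm = TRUE)
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})
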