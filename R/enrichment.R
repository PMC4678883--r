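# Gene-set statistics: the random-sampling empirical significance engine,
# exact hypergeometric tails, and their applications.

#' Empirical gene-set test by random sampling
#'
#' Computes a statistic (mean, sum or count) of per-gene values over the case
#' set, then draws `t` random gene sets of the same size from the universe,
#' each sampled without replacement (draws are independent of one another and
#' may repeat sets), and counts the draws `s` whose statistic is `>=` the
#' observed value (direction `greater_equal`) or `<=` it (`less_equal`). The
#' empirical p-value is the add-one estimator `(s + 1) / (t + 1)`, bounded
#' below by `1/(t + 1)`.
#'
#' @param case_genes Character vector of case gene symbols.
#' @param universe_genes Genes to sample from (the null universe). Defaults
#'   to all genes of `values`.
#' @param values Named numeric vector of per-gene scores covering the case
#'   genes and the universe.
#' @param statistic `"mean"`, `"sum"` or `"count"` (count of genes with
#'   non-zero value).
#' @param direction `"greater_equal"` (large statistic = extreme) or
#'   `"less_equal"`.
#' @param t Number of random sets; default 1e5.
#' @param seed Optional integer seed for reproducible draws.
#' @return An object of class `dnv_empirical_test`: fields `observed, t, s,
#'   p, direction, statistic, m`, plus the vector of null draws in
#'   `null_draws`.
#' @export
#' @examples
#' vals <- setNames(c(5, 4, 1, 1, 1, 1), paste0("g", 1:6))
#' empirical_set_test(c("g1", "g2"), values = vals, t = 999, seed = 1)
empirical_set_test <- function(case_genes,
                               universe_genes = names(values),
                               values,
                               statistic = c("mean", "sum", "count"),
                               direction = c("greater_equal", "less_equal"),
                               t = 1e5, seed = NULL) {
  statistic <- match.arg(statistic)
  direction <- match.arg(direction)
  if (is.null(names(values))) abort("`values` must be a named vector")
  if (t < 1) abort("`t` must be at least 1")
  case_genes <- unique(case_genes)
  if (length(case_genes) == 0) abort("empty case set")
  unscored <- setdiff(case_genes, names(values))
  if (length(unscored) > 0L) {
    abort(sprintf("case gene(s) without scores: %s",
                  paste(unscored, collapse = ", ")))
  }
  universe_genes <- unique(universe_genes)
  if (!all(universe_genes %in% names(values))) {
    abort("every universe gene needs a score")
  }
  m <- length(case_genes)
  if (length(universe_genes) < m) {
    abort("universe smaller than the case set")
  }

  stat_fun <- switch(statistic,
                     mean = mean, sum = sum, count = function(v) sum(v != 0))
  observed <- stat_fun(values[case_genes])
  pool <- unname(values[universe_genes])
  n_pool <- length(pool)

  null_draws <- with_seed_if(seed, vapply(
    seq_len(t),
    function(i) stat_fun(pool[sample.int(n_pool, m)]),
    numeric(1)))

  s <- if (direction == "greater_equal") sum(null_draws >= observed)
       else sum(null_draws <= observed)

  structure(
    list(observed = observed, t = as.integer(t), s = s, p = (s + 1) / (t + 1),
         direction = direction, statistic = statistic, m = m,
         null_draws = null_draws),
    class = "dnv_empirical_test")
}

#' @export
print.dnv_empirical_test <- function(x, ...) {
  cat(sprintf(
    "Empirical gene-set test (%s, %s)\n  observed = %.4g over %d genes\n  s = %d of t = %d draws; p = (s+1)/(t+1) = %.4g\n",
    x$statistic, x$direction, x$observed, x$m, x$s, x$t, x$p))
  invisible(x)
}

#' @rdname empirical_set_test
#' @param x A `dnv_empirical_test`.
#' @param ... Unused.
#' @export
tidy.dnv_empirical_test <- function(x, ...) {
  tibble(observed = x$observed, statistic = x$statistic,
         direction = x$direction, m = x$m, s = x$s, t = x$t, p = x$p)
}

#' @rdname empirical_set_test
#' @export
glance.dnv_empirical_test <- function(x, ...) tidy(x)

#' Gene-score empirical test suite
#'
#' Runs the empirical sampling engine over the four gene-level pathogenicity
#' scores: haploinsufficiency and recessive probability (tested for a case
#' mean larger than random sets), and RVIS at its 0.1% and 1% allele-frequency
#' variants (tested for a case mean smaller than random sets, since negative
#' RVIS means intolerant). Genes missing a score are dropped from that score's
#' test with a message. The null universe is all scored genes (whole-genome
#' sampling, case genes included).
#'
#' @param case_genes Case gene symbols.
#' @param gene_scores Tibble with columns `gene, haploinsufficiency,
#'   recessive_probability, rvis_01, rvis_1`.
#' @param t,seed Passed to [empirical_set_test()]; each score gets an
#'   independent sub-stream of `seed`.
#' @return A tibble with one row per score (`score, observed, m_used, s, t,
#'   p, direction`).
#' @export
score_enrichment_suite <- function(case_genes, gene_scores, t = 1e5,
                                   seed = NULL) {
  check_columns(gene_scores, c("gene", "haploinsufficiency",
                               "recessive_probability", "rvis_01", "rvis_1"),
                "`gene_scores`")
  specs <- tibble(
    score = c("haploinsufficiency", "recessive_probability",
              "rvis_01", "rvis_1"),
    direction = c("greater_equal", "greater_equal",
                  "less_equal", "less_equal"))
  purrr::pmap(specs, function(score, direction) {
    vals <- setNames(gene_scores[[score]], gene_scores$gene)
    vals <- vals[!is.na(vals)]
    used <- intersect(case_genes, names(vals))
    dropped <- length(setdiff(case_genes, used))
    if (dropped > 0) {
      inform(sprintf("%s: dropped %d case gene(s) without a score",
                     score, dropped))
    }
    if (length(used) == 0) abort(sprintf("no case genes scored for %s", score))
    res <- empirical_set_test(
      used, values = vals, statistic = "mean", direction = direction, t = t,
      seed = if (is.null(seed)) NULL else substream_seed(seed, score))
    tibble(score = score, observed = res$observed, m_used = res$m,
           s = res$s, t = res$t, p = res$p, direction = direction)
  }) |> list_rbind()
}

#' Exact hypergeometric upper tail
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` of which `K` are in the reference list.
#'
#' @param k Observed overlap.
#' @param K Reference-list size.
#' @param n Case-set size.
#' @param N Background-universe size.
#' @return The exact upper-tail probability.
#' @export
#' @examples
#' hypergeom_tail(4, 733, 40, 19043)
hypergeom_tail <- function(k, K, n, N) {
  ok <- k >= 0 && k <= n && n <= N && K <= N && K >= 0
  if (!ok) abort("inconsistent counts: need 0 <= k <= n <= N and 0 <= K <= N")
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-list enrichment by hypergeometric test
#'
#' Counts the overlap between a case gene set and a reference list and
#' evaluates its upper-tail hypergeometric probability against a background
#' universe of `background_n` genes.
#'
#' @param case_genes Case gene symbols.
#' @param reference_list Reference gene symbols.
#' @param background_n Background-universe size (>= reference-list size).
#' @return A one-row tibble `k, n, K, N, p` with the overlapping symbols in
#'   the list-column `overlap`.
#' @export
list_enrichment <- function(case_genes, reference_list, background_n) {
  case_genes <- unique(case_genes)
  reference_list <- unique(reference_list)
  if (length(reference_list) == 0) abort("empty reference list")
  if (background_n < length(reference_list)) {
    abort("`background_n` smaller than the reference list")
  }
  hits <- sort(intersect(case_genes, reference_list))
  tibble(
    k = length(hits), n = length(case_genes), K = length(reference_list),
    N = background_n,
    p = hypergeom_tail(length(hits), length(reference_list),
                       length(case_genes), background_n),
    overlap = list(hits))
}

#' GO-term enrichment with Bonferroni correction
#'
#' One hypergeometric upper-tail test per term against the background, with
#' `bonferroni_p = min(1, p * number of terms tested)`. Terms with zero case
#' overlap are still reported (p = 1).
#'
#' @param case_genes Case gene symbols.
#' @param term_to_genes Named list mapping term id to its gene symbols.
#' @param background_n Background-universe size.
#' @param alpha Significance level applied to `bonferroni_p` for the
#'   `significant` flag.
#' @return A tibble with one row per term, ordered by p.
#' @export
go_enrichment <- function(case_genes, term_to_genes, background_n,
                          alpha = 0.05) {
  if (length(term_to_genes) == 0) abort("no terms supplied")
  if (is.null(names(term_to_genes))) abort("`term_to_genes` must be named")
  n_terms <- length(term_to_genes)
  purrr::imap(term_to_genes, function(genes, term) {
    if (length(unique(genes)) > background_n) {
      abort(sprintf("term %s larger than the background universe", term))
    }
    res <- list_enrichment(case_genes, genes, background_n)
    mutate(res, term = term, .before = 1)
  }) |>
    list_rbind() |>
    mutate(bonferroni_p = bonferroni(.data$p, n_terms),
           significant = .data$bonferroni_p < alpha) |>
    arrange(.data$p, .data$term)
}

#' Bonferroni correction
#'
#' @param p Nominal p-value(s).
#' @param n_tests Family size.
#' @return `min(1, p * n_tests)`, vectorised over `p`.
#' @export
#' @examples
#' bonferroni(4.0e-3, 12) # 0.048
bonferroni <- function(p, n_tests) {
  if (n_tests < 1) abort("`n_tests` must be at least 1")
  pmin(1, p * n_tests)
}

#' Plot an empirical test's null distribution
#'
#' Histogram of the statistic over the random draws with the observed value
#' marked, the usual display for resampling-based connectedness tests.
#'
#' @param object A `dnv_empirical_test`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dnv_empirical_test <- function(object, bins = 40, ...) {
  df <- tibble(draw = object$null_draws)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$draw)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("%s of %d sampled genes", object$statistic, object$m),
      y = "random sets",
      title = sprintf("Observed %.3g; empirical p = %.3g",
                      object$observed, object$p)) +
    ggplot2::theme_minimal()
}
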