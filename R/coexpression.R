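# Spearman co-expression networks of gene sets within brain region x
# developmental-stage strata, and the connectedness permutation test.

# Canonical age: days post conception. Birth is taken at 40 gestational
# weeks; months/years are post-natal.
age_to_dpc <- function(value, unit) {
  dplyr::case_match(unit,
                    "pcw" ~ value * 7,
                    "month" ~ 280 + value * 30.4375,
                    "year" ~ 280 + value * 365.25,
                    .default = NA_real_)
}

# The three canonical developmental stage windows (inclusive bounds).
stage_windows <- list(
  prenatal = c(age_to_dpc(8, "pcw"), age_to_dpc(37, "pcw")),
  infancy_childhood = c(age_to_dpc(4, "month"), age_to_dpc(11, "year")),
  adolescence_adulthood = c(age_to_dpc(13, "year"), age_to_dpc(23, "year"))
)

#' Define a region-by-stage stratum
#'
#' A stratum is a set of brain subregions crossed with a developmental age
#' window: either one of the canonical stages (`prenatal` = 8-37 post
#' conception weeks, `infancy_childhood` = 4 months-11 years,
#' `adolescence_adulthood` = 13-23 years) or a custom window given in days
#' post conception. Bounds are inclusive.
#'
#' @param name Stratum label.
#' @param subregions Character vector of subregion codes (e.g. `"VFC"`).
#' @param stage One of the canonical stage names, or `NULL` with an explicit
#'   `age_window`.
#' @param age_window Numeric length-2 window in days post conception, used
#'   when `stage` is `NULL`.
#' @return A `stratum_spec` list.
#' @export
#' @examples
#' stratum_spec("prenatal-VFC", "VFC", "prenatal")
stratum_spec <- function(name, subregions, stage = NULL, age_window = NULL) {
  if (!is.null(stage)) {
    stage <- match.arg(stage, names(stage_windows))
    age_window <- stage_windows[[stage]]
  }
  if (is.null(age_window) || length(age_window) != 2 ||
        age_window[1] > age_window[2]) {
    abort("supply a canonical `stage` or a non-empty `age_window`")
  }
  structure(list(name = name, subregions = unique(subregions),
                 stage = stage %||% "custom",
                 age_window = as.numeric(age_window)),
            class = "stratum_spec")
}

#' Subset an expression dataset to a stratum
#'
#' Keeps the samples whose subregion is in the stratum and whose age (after
#' conversion of `pcw`/`month`/`year` to days post conception) lies inside
#' the stratum's window, bounds included.
#'
#' @param dataset An [expression_dataset()].
#' @param spec A [stratum_spec()].
#' @return The subset as an `expression_dataset`.
#' @export
stratify <- function(dataset, spec) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(spec, "stratum_spec"))
  meta <- dataset$sample_meta |>
    mutate(age_dpc = age_to_dpc(.data$age_value, .data$age_unit)) |>
    filter(.data$subregion %in% spec$subregions,
           .data$age_dpc >= spec$age_window[1],
           .data$age_dpc <= spec$age_window[2])
  keep <- intersect(colnames(dataset$matrix), meta$sample_id)
  if (length(keep) == 0) {
    abort(sprintf("stratum '%s' contains no samples", spec$name))
  }
  expression_dataset(dataset$matrix[, keep, drop = FALSE],
                     select(meta, -"age_dpc"))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data (ties receive their mean rank).
#' Undefined for a constant vector, in which case `NA` is returned with a
#' warning; network construction drops such genes.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return The correlation in \[-1, 1\], or `NA` if undefined.
#' @export
spearman_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warn("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(rank(x), rank(y))
}

# Rank-correlation matrix for a genes x samples matrix; genes in columns of
# the result. Constant genes are removed beforehand.
rank_cor_matrix <- function(mat) {
  keep <- apply(mat, 1, function(r) length(unique(r)) > 1)
  mat <- mat[keep, , drop = FALSE]
  ranks <- apply(mat, 1, rank)   # samples x genes
  list(R = cor(ranks), dropped_constant = sum(!keep))
}

# Edge tibble from a correlation matrix restricted to `genes`.
edges_from_cor <- function(R, genes, cutoff) {
  sub <- R[genes, genes, drop = FALSE]
  idx <- which(upper.tri(sub) & abs(sub) >= cutoff, arr.ind = TRUE)
  g_a <- pmin(genes[idx[, 1]], genes[idx[, 2]])
  g_b <- pmax(genes[idx[, 1]], genes[idx[, 2]])
  r <- sub[idx]
  tibble(gene_a = g_a, gene_b = g_b, r = r,
         sign = if_else(r >= 0, "positive", "negative")) |>
    arrange(.data$gene_a, .data$gene_b)
}

#' Build a Spearman co-expression network for a gene set
#'
#' Computes the Spearman correlation for every unordered pair of the listed
#' genes over the samples of one stratum and keeps the pairs with `|r| >=
#' cutoff` as signed edges. Genes absent from the expression data, and genes
#' with constant expression in the stratum (undefined Spearman), are dropped
#' with a message. Being rank-based, the network is invariant to any strictly
#' monotone per-gene transform of the expression values.
#'
#' @param genes Gene symbols to correlate.
#' @param dataset An [expression_dataset()].
#' @param spec Optional [stratum_spec()]; when supplied the dataset is first
#'   restricted with [stratify()].
#' @param cutoff Absolute-correlation edge threshold (inclusive); default 0.8.
#' @return A `coexpression_network`: an edge tibble (`gene_a, gene_b, r,
#'   sign, stratum`) with attributes `nodes` (genes with at least one edge),
#'   `genes_used`, `cutoff` and `stratum`.
#' @export
build_network <- function(genes, dataset, spec = NULL, cutoff = 0.8) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!is.null(spec)) dataset <- stratify(dataset, spec)
  genes <- unique(genes)
  present <- intersect(genes, rownames(dataset$matrix))
  if (length(present) < length(genes)) {
    inform(sprintf("dropped %d gene(s) lacking expression data",
                   length(genes) - length(present)))
  }
  if (length(present) == 0) abort("none of the genes has expression data")
  rc <- rank_cor_matrix(dataset$matrix[present, , drop = FALSE])
  if (rc$dropped_constant > 0) {
    inform(sprintf("dropped %d gene(s) with constant expression in stratum",
                   rc$dropped_constant))
  }
  usable <- sort(rownames(rc$R))
  edges <- if (length(usable) >= 2) edges_from_cor(rc$R, usable, cutoff) else {
    tibble(gene_a = character(0), gene_b = character(0),
           r = numeric(0), sign = character(0))
  }
  stratum_name <- if (!is.null(spec)) spec$name else NA_character_
  edges$stratum <- rep(stratum_name, nrow(edges))
  structure(edges,
            class = c("coexpression_network", class(edges)),
            nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
            genes_used = usable, cutoff = cutoff, stratum = stratum_name)
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> stratum %s: %d nodes, %d edges (|r| >= %g)\n",
              attr(x, "stratum") %||% "?", length(attr(x, "nodes")),
              nrow(x), attr(x, "cutoff") %||% NA))
  NextMethod()
}

#' Connectedness test of a gene set against control-gene networks
#'
#' Counts the co-expression edges among the case genes in one stratum, then
#' compares that count to `t` networks built identically from random
#' same-size subsets of the control genes (sampled without replacement within
#' each draw). The empirical p-value is `(s + 1)/(t + 1)` where `s` draws
#' reach at least the observed edge count. The full rank-correlation matrix
#' over case and control genes is computed once, so each draw only indexes
#' it.
#'
#' @param case_genes,control_genes Gene symbol vectors; the controls must be
#'   at least as numerous as the cases present in the data.
#' @param dataset An [expression_dataset()].
#' @param spec Optional [stratum_spec()] restricting the samples.
#' @param cutoff Edge threshold on `|r|`; default 0.8.
#' @param t Number of random control sets; default 1e5.
#' @param seed Optional integer seed.
#' @return A `dnv_connectedness` object: `n_nodes`, `n_edges`, the embedded
#'   `empirical` test, the case `network`, and the stratum name.
#' @export
connectedness_test <- function(case_genes, control_genes, dataset,
                               spec = NULL, cutoff = 0.8, t = 1e5,
                               seed = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (t < 1) abort("`t` must be at least 1")
  if (!is.null(spec)) dataset <- stratify(dataset, spec)
  case_genes <- unique(case_genes)
  control_genes <- setdiff(unique(control_genes), case_genes)
  case_in <- intersect(case_genes, rownames(dataset$matrix))
  ctrl_in <- intersect(control_genes, rownames(dataset$matrix))
  if (length(case_in) < 2) abort("fewer than two case genes with expression")
  if (length(ctrl_in) < length(case_in)) {
    abort("control universe smaller than the case set")
  }

  rc <- rank_cor_matrix(dataset$matrix[c(case_in, ctrl_in), , drop = FALSE])
  R <- abs(rc$R)
  diag(R) <- 0
  case_use <- intersect(case_in, rownames(R))
  ctrl_use <- intersect(ctrl_in, rownames(R))
  m <- length(case_use)
  if (length(ctrl_use) < m) abort("control universe smaller than the case set")

  count_edges <- function(idx) sum(R[idx, idx] >= cutoff) / 2
  ci <- match(case_use, rownames(R))
  pi_ <- match(ctrl_use, rownames(R))
  observed <- count_edges(ci)
  null_draws <- with_seed_if(seed, vapply(
    seq_len(t),
    function(i) count_edges(pi_[sample.int(length(pi_), m)]),
    numeric(1)))
  s <- sum(null_draws >= observed)

  emp <- structure(
    list(observed = observed, t = as.integer(t), s = s,
         p = (s + 1) / (t + 1), direction = "greater_equal",
         statistic = "count", m = m, null_draws = null_draws),
    class = "dnv_empirical_test")
  net <- build_network(case_use, dataset, spec = NULL, cutoff = cutoff)
  if (!is.null(spec)) attr(net, "stratum") <- spec$name

  structure(
    list(n_nodes = length(attr(net, "nodes")), n_edges = nrow(net),
         empirical = emp, network = net,
         stratum = if (!is.null(spec)) spec$name else NA_character_,
         cutoff = cutoff),
    class = "dnv_connectedness")
}

#' @export
print.dnv_connectedness <- function(x, ...) {
  cat(sprintf(
    "Connectedness test, stratum %s\n  %d nodes, %d edges; empirical p = %.4g (t = %d)\n",
    x$stratum, x$n_nodes, x$n_edges, x$empirical$p, x$empirical$t))
  invisible(x)
}

#' @rdname connectedness_test
#' @param x A `dnv_connectedness`.
#' @param ... Unused.
#' @export
tidy.dnv_connectedness <- function(x, ...) {
  tibble(stratum = x$stratum, n_nodes = x$n_nodes, n_edges = x$n_edges,
         s = x$empirical$s, t = x$empirical$t, p = x$empirical$p)
}

#' Run the connectedness test over several strata
#'
#' One [connectedness_test()] per stratum with per-stratum seed sub-streams,
#' plus a Bonferroni-corrected p over the family of strata tested (family
#' size defaults to the number of strata in this run).
#'
#' @inheritParams connectedness_test
#' @param strata A list of [stratum_spec()] objects.
#' @param n_tests Bonferroni family size; defaults to `length(strata)`.
#' @return A tibble with one row per stratum (`stratum, n_nodes, n_edges, s,
#'   t, p, bonferroni_p`), with the fitted objects in the list-column `fit`.
#' @export
connectedness_suite <- function(case_genes, control_genes, dataset, strata,
                                cutoff = 0.8, t = 1e5, seed = NULL,
                                n_tests = length(strata)) {
  if (length(strata) == 0) abort("no strata supplied")
  fits <- purrr::map(strata, function(sp) {
    connectedness_test(
      case_genes, control_genes, dataset, spec = sp, cutoff = cutoff, t = t,
      seed = if (is.null(seed)) NULL else substream_seed(seed, sp$name))
  })
  purrr::map(fits, tidy) |>
    list_rbind() |>
    mutate(bonferroni_p = bonferroni(.data$p, n_tests), fit = fits)
}

#' Merge co-expression networks
#'
#' Union of nodes and edges over networks; an edge present in several
#' networks keeps the coefficient of maximal absolute value and records all
#' of its source strata (semicolon-joined). A warning is issued when the
#' inputs used different cutoffs.
#'
#' @param networks A list of `coexpression_network` objects.
#' @return A merged `coexpression_network` with a `strata` column.
#' @export
merge_networks <- function(networks) {
  stopifnot(length(networks) >= 1,
            all(vapply(networks, inherits, logical(1), "coexpression_network")))
  cutoffs <- unique(vapply(networks, function(n) attr(n, "cutoff"), numeric(1)))
  if (length(cutoffs) > 1) {
    warn("merging networks built with different cutoffs")
  }
  all_edges <- purrr::map(networks, function(n) {
    as_tibble(n)[, c("gene_a", "gene_b", "r", "sign", "stratum")]
  }) |> list_rbind()
  merged <- all_edges |>
    group_by(.data$gene_a, .data$gene_b) |>
    summarise(
      strata = paste(unique(.data$stratum), collapse = ";"),
      r = .data$r[which.max(abs(.data$r))],
      .groups = "drop") |>
    mutate(sign = if_else(.data$r >= 0, "positive", "negative"),
           stratum = "merged") |>
    select(dplyr::all_of(c("gene_a", "gene_b", "r", "sign", "stratum",
                           "strata"))) |>
    arrange(.data$gene_a, .data$gene_b)
  structure(merged,
            class = c("coexpression_network", class(merged)),
            nodes = sort(unique(c(merged$gene_a, merged$gene_b))),
            genes_used = sort(unique(unlist(
              purrr::map(networks, attr, "genes_used")))),
            cutoff = cutoffs[1], stratum = "merged")
}

#' Hub genes of a network
#'
#' @param network A `coexpression_network`.
#' @param min_degree Minimum degree (connections) for hub status; default 9.
#' @return Tibble `gene, degree`, sorted by degree descending then name.
#' @export
hub_genes <- function(network, min_degree = 9) {
  degs <- degree_table(network)
  filter(degs, .data$degree >= min_degree)
}

# Degree of every node from the edge list.
degree_table <- function(network) {
  tibble(gene = c(network$gene_a, network$gene_b)) |>
    count(.data$gene, name = "degree") |>
    arrange(desc(.data$degree), .data$gene)
}

#' Convert a co-expression network to igraph / GraphML
#'
#' @param network A `coexpression_network`.
#' @param path Output path for [write_network_graphml()].
#' @return `as_igraph()`: an igraph graph with edge attributes `r` and
#'   `sign`; `write_network_graphml()`: `path` invisibly.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "coexpression_network"))
  igraph::graph_from_data_frame(
    as_tibble(network)[, c("gene_a", "gene_b", "r", "sign")],
    directed = FALSE)
}

#' @rdname as_igraph
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Plot a co-expression network
#'
#' Force-directed layout with red positive and green negative edges, the
#' conventional display for signed co-expression networks.
#'
#' @param object A `coexpression_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coexpression_network <- function(object, seed = 1, ...) {
  if (nrow(object) == 0) abort("cannot plot an empty network")
  g <- as_igraph(object)
  xy <- with_seed_if(seed, igraph::layout_with_fr(g))
  nodes <- tibble(gene = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  edges <- as_tibble(object) |>
    left_join(rename(nodes, xa = "x", ya = "y"),
              by = c(gene_a = "gene")) |>
    left_join(rename(nodes, xb = "x", yb = "y"),
              by = c(gene_b = "gene"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, colour = .data$sign),
      linewidth = 0.4) +
    ggplot2::scale_colour_manual(
      values = c(positive = "firebrick", negative = "forestgreen")) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 2) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$gene),
                       vjust = -0.8, size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "co-expression")
}
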