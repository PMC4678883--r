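# Damaging-prediction aggregation, allele-frequency filtering and
# cohort-level DNV summaries (NS:S ratio, per-trio Poisson model).

# Legend vocabularies for the seven in-silico predictors (dbNSFP-style codes).
predictor_vocab <- list(
  sift              = c("T", "D"),
  polyphen2_hdiv    = c("B", "P", "D"),
  polyphen2_hvar    = c("B", "P", "D"),
  lrt               = c("D", "N", "U"),
  mutation_taster   = c("D", "N"),
  mutation_assessor = c("H", "M", "L", "N"),
  fathmm            = c("D", "T")
)

# Codes that count as damaging/deleterious/disease-causing per predictor.
predictor_damaging <- list(
  sift              = "D",
  polyphen2_hdiv    = c("D", "P"),
  polyphen2_hvar    = c("D", "P"),
  lrt               = "D",
  mutation_taster   = "D",
  mutation_assessor = c("H", "M"),
  fathmm            = "D"
)

#' Names of the seven predictor columns
#'
#' Column names, in conventional order, of the seven categorical pathogenicity
#' predictors consumed by [classify_damaging()].
#'
#' @return A character vector of length 7.
#' @export
predictor_columns <- function() names(predictor_vocab)

# Split a semicolon-delimited per-transcript code string into codes,
# dropping missing markers ("." / "" / NA).
split_codes <- function(x) {
  if (is.na(x) || x == "." || x == "") return(character(0))
  codes <- strsplit(x, ";", fixed = TRUE)[[1]]
  codes <- trimws(codes)
  codes[codes != "" & codes != "."]
}

#' Classify variants as damaging by the seven-predictor aggregation rule
#'
#' A variant is called damaging when at least one of the seven predictors
#' assigns a damaging, deleterious or disease-causing category to at least one
#' transcript: SIFT `D`; PolyPhen-2 (HDIV or HVAR) `D` or `P`; LRT `D`;
#' MutationTaster `D`; MutationAssessor `H` or `M`; FATHMM `D`. Missing calls
#' (`"."`, `""`, `NA`) contribute nothing, so an all-missing profile (e.g. a
#' frameshift indel, which these missense predictors do not score) is not
#' damaging.
#'
#' @param profiles A data frame with the columns named by
#'   [predictor_columns()], each a character vector of semicolon-delimited
#'   per-transcript codes.
#' @return The input as a tibble with a logical `damaging` column appended.
#' @export
#' @examples
#' dnvs <- read_dnv_annotations(dnvnet_example("dnv_predictor_profiles.tsv"))
#' sum(classify_damaging(dnvs)$damaging)
classify_damaging <- function(profiles) {
  check_columns(profiles, predictor_columns(), "`profiles`")
  profiles <- as_tibble(profiles)
  hit <- rep(FALSE, nrow(profiles))
  for (field in predictor_columns()) {
    vocab <- predictor_vocab[[field]]
    bad <- predictor_damaging[[field]]
    col_codes <- lapply(as.character(profiles[[field]]), split_codes)
    unknown <- setdiff(unique(unlist(col_codes)), vocab)
    if (length(unknown) > 0L) {
      abort(sprintf("unknown code(s) %s in predictor field `%s`",
                    paste(sQuote(unknown), collapse = ", "), field))
    }
    hit <- hit | vapply(col_codes, function(z) any(z %in% bad), logical(1))
  }
  mutate(profiles, damaging = hit)
}

#' Filter variants on maximal reference-panel allele frequency
#'
#' Retains records whose maximal alternative allele frequency (across
#' reference panels such as 1000 Genomes, ESP6500 and dbSNP) is missing or
#' strictly below `threshold`. Missingness means the allele was never observed
#' in the panels, the strongest evidence of rarity, so such records pass.
#'
#' @param records A data frame with a `max_af` column (numeric in \[0, 1\],
#'   `NA` for missing).
#' @param threshold Exclusive upper bound on `max_af`; default 0.01 (1%).
#' @return The retained rows as a tibble.
#' @export
maf_filter <- function(records, threshold = 0.01) {
  check_columns(records, "max_af", "`records`")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    abort("`threshold` must be a single non-negative number")
  }
  filter(as_tibble(records), is.na(.data$max_af) | .data$max_af < threshold)
}

#' Non-synonymous to synonymous ratio
#'
#' @param n_nonsyn,n_syn Non-negative counts of non-synonymous and synonymous
#'   variants.
#' @return `n_nonsyn / n_syn`.
#' @export
#' @examples
#' ns_s_ratio(47, 10) # 4.7
ns_s_ratio <- function(n_nonsyn, n_syn) {
  stopifnot(is.numeric(n_nonsyn), is.numeric(n_syn),
            n_nonsyn >= 0, n_syn >= 0)
  if (n_syn == 0) abort("NS:S ratio undefined: zero synonymous variants")
  n_nonsyn / n_syn
}

#' Fit a Poisson model to per-trio DNV counts
#'
#' Estimates the per-proband DNV rate as the sample mean, attaches a normal
#' approximation 95% confidence interval (`lambda_hat +/- 1.96
#' sqrt(lambda_hat/n)`), and tests goodness of fit by a binned likelihood-ratio
#' statistic: observed frequencies of the count categories (default 0, 1, 2
#' and 3-or-more; categories with zero expected mass are pooled)
#' against Poisson(`lambda_hat`) expectations, referred to a chi-square
#' distribution with (categories - 2) degrees of freedom (one df for the
#' estimated mean).
#'
#' @param per_trio_counts Non-negative integer vector, one DNV count per trio.
#' @param breaks Upper bin edges for the count categories; the default
#'   `c(0, 1, 2)` yields categories 0, 1, 2 and >= 3.
#' @return An object of class `dnv_poisson_fit` with fields `lambda_hat`,
#'   `ci_low`, `ci_high`, `gof_stat`, `gof_df`, `gof_p`, `n_trios`, `n_dnvs`.
#' @export
#' @examples
#' fit <- poisson_fit(c(rep(0, 13), rep(1, 13), rep(2, 5), 3))
#' round(fit$lambda_hat, 2)
poisson_fit <- function(per_trio_counts, breaks = c(0, 1, 2)) {
  x <- per_trio_counts
  if (length(x) < 2L) abort("need counts for at least two trios")
  if (any(is.na(x)) || any(x < 0) || any(x != trunc(x))) {
    abort("`per_trio_counts` must be non-negative integers")
  }
  n <- length(x)
  lambda_hat <- mean(x)
  se <- sqrt(lambda_hat / n)
  ci <- lambda_hat + c(-1, 1) * qnorm(0.975) * se

  if (lambda_hat == 0) {
    warn("all counts are zero; goodness of fit degenerate, p = 1")
    gof <- list(stat = 0, df = NA_real_, p = 1)
  } else {
    breaks <- sort(unique(as.integer(breaks)))
    obs <- c(vapply(breaks, function(b) sum(x == b), numeric(1)),
             sum(x > breaks[length(breaks)]))
    pr <- c(dpois(breaks, lambda_hat),
            ppois(breaks[length(breaks)], lambda_hat, lower.tail = FALSE))
    # pool zero-expectation categories into the nearest retained neighbour
    keep <- pr > 0
    obs <- vapply(split(obs, cumsum(keep)), sum, numeric(1))
    pr <- vapply(split(pr, cumsum(keep)), sum, numeric(1))
    expct <- n * pr
    stat <- 2 * sum(ifelse(obs > 0, obs * log(obs / expct), 0))
    df <- length(obs) - 2
    p <- if (df < 1) 1 else pchisq(stat, df = df, lower.tail = FALSE)
    gof <- list(stat = stat, df = as.numeric(df), p = p)
  }

  structure(
    list(lambda_hat = lambda_hat, ci_low = ci[1], ci_high = ci[2],
         gof_stat = gof$stat, gof_df = gof$df, gof_p = gof$p,
         n_trios = n, n_dnvs = sum(x)),
    class = "dnv_poisson_fit"
  )
}

#' @export
print.dnv_poisson_fit <- function(x, ...) {
  cat(sprintf(
    "Poisson fit to per-trio DNV counts\n  %d DNVs in %d trios\n  mean %.3f (95%% CI [%.2f, %.2f])\n  GOF LRT p = %.3g\n",
    x$n_dnvs, x$n_trios, x$lambda_hat, x$ci_low, x$ci_high, x$gof_p))
  invisible(x)
}

#' @rdname poisson_fit
#' @param x A `dnv_poisson_fit` object.
#' @param ... Unused.
#' @export
tidy.dnv_poisson_fit <- function(x, ...) {
  tibble(term = "lambda", estimate = x$lambda_hat,
         conf.low = x$ci_low, conf.high = x$ci_high)
}

#' @rdname poisson_fit
#' @export
glance.dnv_poisson_fit <- function(x, ...) {
  tibble(lambda = x$lambda_hat, ci_low = x$ci_low, ci_high = x$ci_high,
         gof_stat = x$gof_stat, gof_df = x$gof_df, gof_p = x$gof_p,
         n_trios = x$n_trios, n_dnvs = x$n_dnvs)
}
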