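# Internal helpers shared across modules.

#' Derive an independent sub-stream seed from a master seed
#'
#' A single integer seed fans out to per-generator sub-seeds keyed by a label,
#' so adding one generator to a simulation does not perturb the draws of the
#' others. The derivation is a small deterministic string hash folded into the
#' master seed, kept strictly below `2^31 - 1`.
#'
#' @param seed Master integer seed.
#' @param label Character label naming the sub-stream.
#' @return A single integer seed.
#' @export
#' @examples
#' substream_seed(1L, "cohort")
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 7919) %% 2147483647)
}

# Run code under a fixed seed without disturbing the caller's RNG state.
# seed = NULL leaves the RNG alone (caller-controlled randomness).
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Assert that `df` has the named columns; error names the caller's table.
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Scalar positive-count check used by the generators.
check_count <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x == trunc(x) && (x > 0 || (allow_zero && x == 0))
  if (!ok) abort(sprintf("`%s` must be a %s integer", name,
                         if (allow_zero) "non-negative" else "positive"))
  invisible(as.integer(x))
}
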