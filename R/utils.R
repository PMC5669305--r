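# Internal helpers: classed error conditions and fast grouped operations.

cc_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "coalcough_error")))
}

abort_invalid_config <- function(msg) cc_abort(msg, "coalcough_invalid_config")
abort_degenerate <- function(msg) cc_abort(msg, "coalcough_degenerate_design")
abort_inference <- function(msg) cc_abort(msg, "coalcough_inference_error")
abort_missing_data <- function(msg) cc_abort(msg, "coalcough_missing_data")
abort_rank <- function(msg) cc_abort(msg, "coalcough_rank_error")
abort_usage <- function(msg) cc_abort(msg, "coalcough_usage_error")
abort_schema <- function(msg) cc_abort(msg, "coalcough_schema_error")
abort_integrity <- function(msg) cc_abort(msg, "coalcough_integrity_error")
abort_convergence <- function(msg) cc_abort(msg, "coalcough_convergence_error")
abort_inestimable <- function(msg) cc_abort(msg, "coalcough_inestimable_error")

# Group means by integer group index, expanded back to observation length.
# `g` must be a factor (or integer codes 1..K); columns of `x` numeric.
group_mean_expand <- function(x, g) {
  g <- as.integer(g)
  n_per <- tabulate(g)
  if (is.matrix(x)) {
    m <- rowsum(x, g, reorder = TRUE) / n_per
    m[g, , drop = FALSE]
  } else {
    m <- rowsum(x, g, reorder = TRUE)[, 1] / n_per
    m[g]
  }
}

# Demean columns within groups; groups of size 1 become zero rows.
demean_by_group <- function(x, g) {
  x - group_mean_expand(x, g)
}

# Deterministic child seed derivation (keeps results reproducible per stage
# while all randomness flows from one user-visible seed). Child seeds are
# drawn through the generator itself rather than by seed arithmetic:
# arithmetically related seeds can yield measurably correlated
# Mersenne-Twister streams. The global RNG state is restored on exit.
child_seed <- function(seed, offset) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  sample.int(2147483646L, offset)[offset]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
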