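# Internal helpers shared across modules.

# Uppercase + trim a vector of gene symbols.
norm_symbol <- function(x) toupper(trimws(as.character(x)))

# Stop with a classed error so callers/tests can distinguish domain errors
# (bad values) from usage errors (bad invocation).
domain_error <- function(msg, ...) {
  abort(msg, class = "tfconcord_domain_error", ...)
}

usage_error <- function(msg, ...) {
  abort(msg, class = "tfconcord_usage_error", ...)
}

# Run `code` under a fixed RNG seed when `seed` is non-NULL, leaving the
# caller's RNG state untouched; otherwise draw from the current stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Pearson correlation of the rows of `m` (genes x conditions) against the
# rows of `cent`; returns a matrix nrow(m) x nrow(cent).
row_cor <- function(m, cent) {
  stats::cor(t(m), t(cent))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
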