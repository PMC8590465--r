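# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed when `seed` is non-NULL, leaving the
# caller's RNG state untouched; otherwise use the ambient RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Derive a reproducible child seed from a parent seed and a stream index,
# kept inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1000003 + 7919 * stream) %% .Machine$integer.max)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
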