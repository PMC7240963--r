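# Internal helpers shared across modules.

# Deterministic 31-bit substream seed for pair (i, j) under a master seed.
# Keeps per-pair permutation streams independent of iteration order so that
# correlate_all()/correlate_between() are reproducible cell by cell.
pair_seed <- function(seed, i, j) {
  s <- (as.numeric(seed) %% 65011) * 33013 + i * 10007 + j * 271
  as.integer(s %% 2147483629) + 1L
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

stop_config <- function(field, msg) {
  abort(sprintf("invalid configuration: field `%s` %s", field, msg),
        class = "traitnet_config_error")
}

# Uniform draw from an inclusive integer range; safe when the range is a
# single value (where sample(x, ...) would resample from 1:x).
sample_int_range <- function(range, n) {
  vals <- range[1]:range[2]
  if (length(vals) == 1L) rep(vals, n) else sample(vals, n, replace = TRUE)
}

# Canonical unordered pair key: endpoints sorted alphabetically.
sort_pair <- function(a, b) {
  swap <- a > b
  tibble(first = ifelse(swap, b, a), second = ifelse(swap, a, b))
}
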