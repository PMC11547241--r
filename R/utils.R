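# Internal helpers shared across modules.

# Deterministic 31-bit hash of a string, for per-chamber seed derivation.
.hash_string <- function(x) {
  h <- 0
  for (ch in utf8ToInt(as.character(x))) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Combine a user seed with a chamber identifier into a reproducible
# 31-bit sub-seed, so that element i of a series does not depend on how
# many chambers were generated before it.
.chamber_seed <- function(seed, chamber_id) {
  as.integer((as.numeric(seed) * 48271 + .hash_string(chamber_id)) %% 2147483647)
}

# Round half away from zero to `digits` decimals (the convention used for
# printed percentages, e.g. 16.666... -> 16.67).
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  trunc(abs(x) * m + 0.5) / m * sign(x)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
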