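# Internal helpers shared across modules.

# FNV-1a 32-bit hash, done in doubles with 16-bit limbs so the modular
# multiplication never exceeds 2^53. Used to fingerprint feature registries;
# a short stable identifier, not a cryptographic hash.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  p <- 16777619
  two32 <- 4294967296
  for (b in bytes) {
    h <- bitwXor32(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((hi * p) %% 65536) * 65536 + lo * p
    h <- h %% two32
  }
  hi <- (h - h %% 65536) / 65536
  sprintf("%04x%04x", as.integer(hi), as.integer(h %% 65536))
}

# 32-bit xor on doubles (bitwXor works on 32-bit signed ints; route through
# the two 16-bit halves to stay in range).
bitwXor32 <- function(a, b) {
  a_lo <- a %% 65536; a_hi <- (a - a_lo) / 65536
  b_lo <- b %% 65536; b_hi <- (b - b_lo) / 65536
  bitwXor(as.integer(a_hi), as.integer(b_hi)) * 65536 +
    bitwXor(as.integer(a_lo), as.integer(b_lo))
}

# Format doubles so that read-back reproduces them exactly (%.17g round-trips
# IEEE doubles).
fmt_num <- function(x) sprintf("%.17g", x)

tool_version <- function() {
  as.character(utils::packageVersion("icnoise"))
}

# Seeded evaluation without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
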