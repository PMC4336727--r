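run_seeded <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# derive a per-item substream seed below 2^31
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 100003 + as.double(i)) %% 2147483647)
}

# FNV-1a 32-bit over a character scalar, as 8 hex digits; used to stamp
# output files with an auditable configuration fingerprint.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    # h * 16777619 mod 2^32 without integer overflow: 16-bit split
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 2^32
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
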