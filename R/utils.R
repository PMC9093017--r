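## Internal helpers: deterministic sub-seed derivation and a small FNV-1a
## hash for run manifests.

## Deterministic sub-seed from (seed, stream index), kept within 32-bit range.
## Streams for distinct indices are distinct for any base seed.
deriveSeed <- function(seed, stream) {
  s <- (as.double(seed) %% 1000003) * 2147 + as.double(stream) * 7919 + 17
  as.integer(s %% 2147483647)
}

## FNV-1a over the UTF-8 bytes of a string; returned as 8 hex digits.
## Arithmetic is done in doubles on 16-bit halves to stay exact.
fnv1a <- function(txt) {
  bytes <- as.integer(utf8ToInt(txt))
  hash <- 2166136261
  for (b in bytes) {
    hash <- bitwXor32(hash, b)
    hash <- mul32(hash, 16777619)
  }
  lo <- hash %% 65536
  sprintf("%04x%04x", as.integer((hash - lo) / 65536), as.integer(lo))
}

mul32 <- function(a, b) {
  ## (a * b) mod 2^32 without loss: split a into 16-bit halves
  lo <- a %% 65536
  hi <- (a - lo) / 65536
  ((lo * b) %% 4294967296 + ((hi * b) %% 65536) * 65536) %% 4294967296
}

bitwXor32 <- function(a, b) {
  ## xor for doubles in [0, 2^32)
  r <- 0
  p <- 1
  for (i in 1:32) {
    ab <- a %% 2; bb <- b %% 2
    if (ab != bb) r <- r + p
    a <- (a - ab) / 2; b <- (b - bb) / 2
    p <- p * 2
    if (a == 0 && b == 0) break
  }
  r
}

## stable serialization of a flat config list for hashing
serializeConfig <- function(cfg) {
  keys <- sort(names(cfg))
  paste(vapply(keys, function(k)
    paste0(k, "=", paste(format(cfg[[k]], digits = 15), collapse = ",")),
    character(1)), collapse = ";")
}

configHash <- function(cfg) fnv1a(serializeConfig(cfg))
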