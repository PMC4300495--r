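# Internal helpers shared across modules.

# Empirical p-value with the add-one convention: never 0, always in (0, 1].
empiricalP <- function(nExceed, nPerm) (1 + nExceed) / (1 + nPerm)

# Deterministic fan-out of a global seed into per-stage / per-replicate
# seeds. Multiplicative congruential step keeps values in 32-bit range and
# well separated for small indices.
deriveSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

.assertCount <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != as.integer(x))
    stop(sprintf("'%s' must be a single non-negative integer", name),
         call. = FALSE)
  as.integer(x)
}

.assertProb <- function(x, name) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  x
}

# Format values identically across runs for report serialization.
.fmtNum <- function(x) {
  if (!is.numeric(x)) return(as.character(x))
  ifelse(is.na(x), "NA",
         ifelse(x == floor(x) & abs(x) < 1e15,
                sprintf("%.0f", x), sprintf("%.10g", x)))
}

# Stable non-cryptographic polynomial string hash (mod 2^31 - 1) for config
# provenance; avoids external digest dependencies.
.hashString <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
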