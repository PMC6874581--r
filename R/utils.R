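# Internal helpers shared across modules.

# Deterministic 32-bit djb2-style hash of a character scalar, returned as
# 8 hex digits. Used for filtration/gating identification numbers; stable
# across platforms because arithmetic stays below 2^53.
hash_id <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

# Canonical string form of a numeric vector for hashing. 12 significant
# digits: stable under serialization round-trips (YAML/CSV write at >= 15
# digits, so only sub-ulp noise is discarded) while still distinguishing
# any meaningful parameter change.
num_signature <- function(x) paste(formatC(x, digits = 12, format = "g"), collapse = ",")

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

stop_cyto <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Weighted quantile of `v` with non-negative weights, lower tie-break:
# smallest v whose cumulative weight fraction reaches p.
weighted_quantile_lower <- function(v, w, p) {
  stopifnot(length(v) == length(w), all(w >= 0), p >= 0, p <= 1)
  o <- order(v)
  v <- v[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  v[which(cw >= p - 1e-12)[1L]]
}
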