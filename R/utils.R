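# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min)
    stop_invalid(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

check_proportion <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
    stop_invalid(sprintf("`%s` must be a single number in [0, 1]", name))
  as.numeric(x)
}

check_pvalues <- function(p, name = "p") {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p > 1))
    stop_invalid(sprintf("`%s` must be probabilities in (0, 1]", name))
  as.numeric(p)
}

#' @importFrom withr with_seed
seeded <- function(seed, code) {
  if (length(seed) != 1L || !is.finite(seed))
    stop_invalid("`seed` must be a single finite number")
  withr::with_seed(as.integer(seed), code)
}

# "chr6" / "Chr6" / "6" -> "6"; MT left as-is.
normalize_chrom <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))

# FNV-1a over a character scalar; used to stamp outputs with a config hash.
# State kept as a double in [0, 2^32); xor and modular multiply done in
# 16-bit halves to stay inside exact double/integer arithmetic.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# Contiguous, near-equal partition of n items into k groups; returns group ids.
contiguous_blocks <- function(n, k) {
  bounds <- round(seq(0, n, length.out = k + 1L))
  rep.int(seq_len(k), diff(bounds))
}

pkg_version <- function() as.character(utils::packageVersion("scherit"))

# Keep p-values inside (0, 1] against floating-point underflow.
floor_p <- function(p) pmin(pmax(p, 1e-300), 1)
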