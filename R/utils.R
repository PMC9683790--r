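# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Sample column indices of a regular time grid covering [w[1], w[2]) seconds
# relative to t = 0 at index `zero_index`.
window_index <- function(time, w) {
  which(time >= w[1] - 1e-9 & time < w[2] - 1e-9)
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

# Linear interpolation of a neurons x samples matrix at fractional sample
# positions `pos` (1-based, same length as output columns).
interp_rows <- function(F, pos) {
  n <- ncol(F)
  pos <- pmin(pmax(pos, 1), n)
  i0 <- pmin(floor(pos), n - 1L)
  fr <- pos - i0
  F[, i0, drop = FALSE] * rep(1 - fr, each = nrow(F)) +
    F[, i0 + 1L, drop = FALSE] * rep(fr, each = nrow(F))
}

# FNV-1a hash of a character scalar, as 8 hex digits; used to fingerprint
# pipeline configurations without external dependencies.  State kept as two
# 16-bit words so the 32-bit modular product stays exact in doubles.
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  hi <- 33052; lo <- 40389   # 0x811C9DC5
  for (b in bytes) {
    lo <- bitwXor(lo, b)
    tot <- (lo * 403 + ((lo * 256 + hi * 403) %% 65536) * 65536) %% 4294967296
    hi <- tot %/% 65536
    lo <- tot %% 65536
  }
  sprintf("%04x%04x", hi, lo)
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}
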