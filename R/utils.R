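# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; screening reports in this package
#' follow the convention used in docking tables (-10.01/29 prints as -0.345),
#' i.e. ties move away from zero.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return numeric vector rounded to `digits`
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# FNV-1a 32-bit hash of a character string, returned as a non-negative double
# (< 2^32). Implemented with 16-bit split multiplication so the product never
# leaves double precision.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- bitw_xor32(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((lo * prime) %% 2^32 + ((hi * prime) %% 65536) * 65536) %% 2^32
  }
  h
}

# xor of two non-negative doubles < 2^32, result double
bitw_xor32 <- function(a, b) {
  a_lo <- a %% 2^16; a_hi <- (a - a_lo) / 2^16
  b_lo <- b %% 2^16; b_hi <- (b - b_lo) / 2^16
  lo <- bitwXor(as.integer(a_lo), as.integer(b_lo))
  hi <- bitwXor(as.integer(a_hi), as.integer(b_hi))
  hi * 2^16 + lo
}

# Combine a character key into a bit position in [0, nbits)
hash_to_bit <- function(key, nbits) {
  as.integer(fnv1a(key) %% nbits)
}

cvs_log <- function(..., verbose = getOption("consensusVS.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
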