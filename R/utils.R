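#' @keywords internal
"_PACKAGE"

# -- small shared numerics ----------------------------------------------------

#' Numerically stable softmax over the rows of a matrix
#'
#' The transformation turning decoder score vectors into token posteriors:
#' each row `x_i` maps to `exp(x_i) / sum(exp(x_i))`.
#'
#' @param x numeric matrix; each row is a score vector.
#' @return matrix of the same shape whose rows are probability vectors.
#' @export
row_softmax <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Derive a reproducible child seed from a parent seed and integer indices
#'
#' A small multiplicative hash keeps independent substreams (per generation,
#' per individual, per evaluation cycle) reproducible from one run seed while
#' staying inside the 32-bit integer range `set.seed()` accepts.
#'
#' @param seed integer parent seed.
#' @param ... further non-negative integer indices.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(seed, ...)
  h <- 0
  m <- 2147483629  # largest prime < 2^31 - 1
  for (v in idx) {
    h <- (h * 69069 + (as.numeric(v) %% m) + 1) %% m
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

# Polynomial rolling checksum of a character scalar (mod 2^31 - 1), as a hex
# string.  Used only as an integrity check on saved run state, not security.
text_checksum <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  m <- 2147483647
  h <- 17
  for (b in bytes) h <- (h * 257 + b + 1) %% m
  sprintf("%08x", as.integer(h))
}
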