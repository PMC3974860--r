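#' Derive a reproducible sub-stream seed
#'
#' All stochastic operations in the package take a single user-facing seed and
#' derive one sub-seed per named stream from it, so that adding or reordering
#' operations does not perturb the random numbers used by the others. The
#' derivation is a small multiplicative hash of the stream label folded into
#' the top-level seed, reduced modulo 2^31 - 1 so the result is always a valid
#' R integer seed.
#'
#' @param seed integer top-level seed.
#' @param stream character label of the consuming operation.
#' @return integer seed for `set.seed()`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(stream)) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h)
}

#' Lower median (lower of the two middle values for even n)
#'
#' @param x numeric vector.
#' @return the lower median of `x`.
#' @keywords internal
median_lower <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}

# stop() with sprintf-style formatting
pg_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

pg_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Random DNA sequence
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Hamming distance between two equal-length strings (no gaps).
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}
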