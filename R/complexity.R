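#' Lempel-Ziv (LZ76) complexity of a binary sequence
#'
#' Number of distinct patterns in the exhaustive-history parsing of the
#' sequence (Kaspar-Schuster formulation of Lempel & Ziv's 1976
#' complexity): the sequence is scanned left to right and a new phrase is
#' opened whenever the current suffix cannot be copied from the history.
#' More diverse, less predictable sequences contain more phrases.
#'
#' @param bits vector of 0/1 (integer, numeric, or logical).
#' @return integer phrase count `c(n)`.
#' @export
lz76_complexity <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) == 0) stop("sequence must be nonempty")
  if (anyNA(bits) || !all(bits %in% c(0L, 1L)))
    stop("sequence must contain only 0 and 1")
  .lz76_count(bits)
}

#' Normalized Lempel-Ziv complexity (compressibility)
#'
#' The LZ76 phrase count divided by the sequence length, `c(n) / n`
#' (default), the entropy-rate proxy used for binarized meta-state
#' sequences. The asymptotically scaled variant
#' `c(n) log2(n) / n` is available behind `scaled = TRUE`.
#'
#' @param bits binary vector.
#' @param scaled use the `c(n) log2(n) / n` normalization instead.
#' @return scalar complexity.
#' @export
normalized_lz <- function(bits, scaled = FALSE) {
  n <- length(bits)
  c_n <- lz76_complexity(bits)
  if (scaled) c_n * log2(n) / n else c_n / n
}
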