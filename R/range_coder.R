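#' Adaptive order-0 range coding of a symbol stream
#'
#' Encodes integer symbols `0..alphabet_size-1` with the package's 32-bit
#' carry-propagating range coder driven by a single adaptive frequency table
#' (counts start at 1, grow by `increment`, halve past `rescale_limit`).
#' Integer-only arithmetic makes the byte stream bit-exact across platforms;
#' the decoder needs the symbol count and identical model parameters.
#'
#' @param symbols Integer vector of symbols (0-based).
#' @param alphabet_size Number of symbols in the alphabet.
#' @param increment,rescale_limit Adaptive model parameters.
#' @return Raw vector of compressed bytes.
#' @seealso [rc_decode()], [rc_encode_trace()]
#' @export
rc_encode <- function(symbols, alphabet_size, increment = 32L,
                      rescale_limit = 8192L) {
  cpp_encode_adaptive0(as.integer(symbols), as.integer(alphabet_size),
                       as.integer(increment), as.integer(rescale_limit))
}

#' @rdname rc_encode
#' @param bytes Raw vector produced by [rc_encode()].
#' @param n Number of symbols to decode.
#' @export
rc_decode <- function(bytes, n, alphabet_size, increment = 32L,
                      rescale_limit = 8192L) {
  cpp_decode_adaptive0(bytes, as.integer(n), as.integer(alphabet_size),
                       as.integer(increment), as.integer(rescale_limit))
}

#' Range coding under an explicit per-step model trace
#'
#' Encodes/decodes symbols where the frequency counts used at every step are
#' supplied as a matrix (row i = counts in force when symbol i is coded),
#' with no adaptation inside the coder. This isolates the coder itself, so
#' its output can be compared against the ideal code length
#' \eqn{\sum_i -\log_2 p_i(s_i)}.
#'
#' @param symbols Integer vector of 0-based symbols.
#' @param counts Integer matrix, `length(symbols)` rows; all entries positive
#'   for coded symbols, row totals below 2^16.
#' @return `rc_encode_trace`: raw vector; `rc_decode_trace`: integer symbols.
#' @export
rc_encode_trace <- function(symbols, counts) {
  cpp_encode_trace(as.integer(symbols), as.matrix(counts))
}

#' @rdname rc_encode_trace
#' @param bytes Raw vector from [rc_encode_trace()].
#' @export
rc_decode_trace <- function(bytes, counts) {
  cpp_decode_trace(bytes, as.matrix(counts))
}

#' Ideal code length of a symbol/model trace
#'
#' @param symbols 0-based symbols.
#' @param counts Per-step count matrix as in [rc_encode_trace()].
#' @return Ideal total code length in bits, \eqn{\sum_i -\log_2 p_i(s_i)}.
#' @export
ideal_code_length <- function(symbols, counts) {
  counts <- as.matrix(counts)
  p <- counts[cbind(seq_along(symbols), as.integer(symbols) + 1L)] /
    rowSums(counts)
  sum(-log2(p))
}
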