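#' Compression rate
#'
#' \deqn{CR = \frac{L_{after}}{L_{begin}} \times 100\%}
#'
#' @param L_after Compressed size in bytes.
#' @param L_begin Original size in bytes (must be positive).
#' @return CR as a percentage.
#' @export
compression_ratio <- function(L_after, L_begin) {
  if (any(L_begin <= 0)) stop("L_begin must be positive")
  L_after / L_begin * 100
}

#' Bits per quality value
#'
#' One uncompressed ASCII quality character costs 8 bits, so
#' `BPQ = 8 * CR / 100`; an uncompressed stream scores 8 BPQ.
#'
#' @param CR Compression rate in percent.
#' @return Bits per quality value.
#' @export
bits_per_quality <- function(CR) {
  if (any(CR < 0)) stop("CR must be non-negative")
  8 * CR / 100
}

#' Compression report for a FASTQ / container pair
#'
#' Sizes attributable to quality compression are the lengths, row-bin and
#' quality streams plus the fixed header; the embedded base stream (when
#' present) is reported separately so quality-only figures remain comparable
#' across `embed_bases` settings.
#'
#' @param fastq FASTQ path or `fastq` object.
#' @param container `.aco` path or raw container bytes.
#' @param run_id Label used in printed / tabulated output.
#' @return An `aco_report`: list with `L_begin`, `L_after`, `CR`, `BPQ`,
#'   `base_stream_bytes` and `total_bytes`.
#' @export
aco_stats <- function(fastq, container, run_id = "run") {
  fq <- if (inherits(fastq, "fastq")) fastq else read_fastq(fastq)
  bytes <- if (is.raw(container)) container else {
    readBin(container, "raw", file.size(container))
  }
  hdr <- parse_container(bytes)
  base_bytes <- sum(vapply(hdr$blocks, function(b) b$stream_bytes[["bases"]],
                           numeric(1))) +
    (if (hdr$bases_embedded) 1L + length(hdr$base_alpha) else 0L)
  L_begin <- sum(nchar(fq$qual))
  L_after <- length(bytes) - base_bytes
  CR <- compression_ratio(L_after, L_begin)
  structure(list(run_id = run_id, L_begin = L_begin, L_after = L_after,
                 CR = CR, BPQ = bits_per_quality(CR),
                 base_stream_bytes = base_bytes,
                 total_bytes = length(bytes)),
            class = "aco_report")
}

#' @export
print.aco_report <- function(x, ...) {
  cat(sprintf("%s: %d -> %d quality bytes  CR = %.2f%%  BPQ = %.2f",
              x$run_id, x$L_begin, x$L_after, x$CR, x$BPQ))
  if (x$base_stream_bytes > 0) {
    cat(sprintf("  (+%d base-stream bytes)", x$base_stream_bytes))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.aco_report <- function(x, ...) {
  data.frame(run_id = x$run_id, L_begin = x$L_begin, L_after = x$L_after,
             CR_percent = x$CR, BPQ = x$BPQ,
             stringsAsFactors = FALSE)
}
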