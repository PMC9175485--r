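#' Mean quality of a read
#'
#' The per-read (row) mean is the cheap stand-in for the full row
#' distribution: reads with the same mean are treated as draws from
#' approximately the same quality profile, so the quantized mean becomes a
#' per-read context dimension transmitted to the decoder as side information.
#'
#' @param quals Integer vector of Phred scores for one read.
#' @return The arithmetic mean (unrounded); 0 for an empty read.
#' @export
compute_row_mean <- function(quals) {
  if (length(quals) == 0L) return(0)
  mean(quals)
}

#' Quantize a row mean into its context bin
#'
#' Piecewise rule mapping a raw mean quality to the bin value used as context:
#' means below 30 collapse to 30, then 2-Phred-wide bins up to 38
#' (`30 <= q < 32 -> 32`, `32 <= q < 34 -> 34`, `34 <= q < 36 -> 36`,
#' `36 <= q < 38 -> 38`), and means of 38 and above are kept as-is (rounded to
#' the nearest integer so the side stream stays integral). Low means are rare
#' and merged aggressively; the dense high-quality range keeps full
#' resolution. The bin boundaries are the shipped production solution of the
#' dynamic-programming quantizer in [optimal_partition()].
#'
#' @param q Numeric vector of raw row means (must be >= 0).
#' @return Integer vector of bin values.
#' @examples
#' quantize_row_mean(c(29, 31, 33, 37, 40.2))  # 30 32 34 38 40
#' @export
quantize_row_mean <- function(q) {
  stopifnot(all(q >= 0))
  out <- as.integer(round(q))
  out[q < 38] <- 38L
  out[q < 36] <- 36L
  out[q < 34] <- 34L
  out[q < 32] <- 32L
  out[q < 30] <- 30L
  out
}

# number of distinct row bins for a quality alphabet 0..max_q, and the
# 0-based index of a bin value. Bins are {30,32,34,36,38} plus one bin per
# integer above 38 up to max_q (at least the five merged bins).
n_row_bins <- function(max_q) 5L + max(0L, as.integer(max_q) - 38L)

row_bin_index <- function(bin, max_q) {
  idx <- ifelse(bin <= 38L, (bin - 30L) %/% 2L, 5L + (bin - 39L))
  idx <- pmin(pmax(as.integer(idx), 0L), n_row_bins(max_q) - 1L)
  idx
}

#' Build the compound context key for one scan position
#'
#' Reference implementation of the conditioning state used for every quality
#' symbol: the previous quality symbol along the scan path at full
#' resolution, the second-previous symbol coarsened to `q2_levels` levels
#' (`value %/% 5`), the quantized row-mean bin of the current read, and the
#' second-order base pair (current base, previous base within the same read,
#' with a start-of-read sentinel `^`). Everything entering the key is known
#' to the decoder before the symbol is decoded: earlier path symbols, plus
#' the side streams (lengths, row bins, bases).
#'
#' The compiled codec computes identical keys; this function exists for
#' inspection and for decodability checks.
#'
#' @param path_pos 1-based position along the scan path.
#' @param matrix A `quality_matrix` (see [build_matrix()]).
#' @param bases Character vector of per-read base strings (or NULL).
#' @param row_bins Integer vector of per-read bin values (or NULL).
#' @param decisions List of switches: `serpentine`, `use_q2`, `use_rowmean`,
#'   `use_base`, `q2_levels` (default 9).
#' @return List with components `q_prev1`, `q_prev2_coarse`, `row_bin`,
#'   `base_pair` (character, e.g. `"A^"`), and the integer `key`.
#' @export
make_context <- function(path_pos, matrix, bases = NULL, row_bins = NULL,
                         decisions = list()) {
  d <- modifyList(list(serpentine = TRUE, use_q2 = TRUE, use_rowmean = TRUE,
                       use_base = TRUE, q2_levels = 9L, max_q = 41L), decisions)
  path <- if (d$serpentine) serpentine_path(matrix$lengths) else raster_path(matrix$lengths)
  n <- nrow(path$cells)
  if (path_pos < 1L || path_pos > n) stop("path position out of range")
  cell_q <- function(i) {
    rc <- path$cells[i, ]
    matrix$rows[[rc[1] + 1L]][rc[2] + 1L]
  }
  q_prev1 <- if (path_pos > 1L) cell_q(path_pos - 1L) else 0L
  q_prev2 <- if (path_pos > 2L) cell_q(path_pos - 2L) else 0L
  q2 <- if (d$use_q2) min(q_prev2 %/% 5L, d$q2_levels - 1L) else 0L
  rc <- path$cells[path_pos, ]
  r <- rc[1] + 1L; cc <- rc[2] + 1L
  rb <- if (d$use_rowmean) row_bins[r] else 0L
  alphabet <- c("A", "C", "G", "T", "N", "^")
  if (d$use_base) {
    read_bases <- strsplit(toupper(bases[r]), "")[[1]]
    read_bases[!read_bases %in% alphabet[1:5]] <- "N"
    cur <- read_bases[cc]
    prev <- if (cc > 1L) read_bases[cc - 1L] else "^"
  } else {
    cur <- "A"; prev <- "A"
  }
  dim_q2 <- if (d$use_q2) d$q2_levels else 1L
  dim_rb <- if (d$use_rowmean) n_row_bins(d$max_q) else 1L
  rb_idx <- if (d$use_rowmean) row_bin_index(rb, d$max_q) else 0L
  dim_bp <- if (d$use_base) 36L else 1L
  bp <- if (d$use_base) {
    (match(cur, alphabet) - 1L) * 6L + (match(prev, alphabet) - 1L)
  } else 0L
  key <- ((q_prev1 * dim_q2 + q2) * dim_rb + rb_idx) * dim_bp + bp
  list(q_prev1 = q_prev1, q_prev2_coarse = q2, row_bin = rb,
       base_pair = paste0(cur, prev), key = key)
}

#' Adaptive per-context symbol model
#'
#' Frequency-count model used by the range coder: each context starts with
#' one count per symbol (uniform), observing a symbol adds `increment` to its
#' count, and when a context's total exceeds `rescale_limit` all its counts
#' are halved with floor 1. Halving implements exponential forgetting, which
#' is what makes the coder sensitive to scan order: recently coded symbols
#' dominate the estimate.
#'
#' This R implementation mirrors the compiled table used by the codec and is
#' intended for inspection and testing at small scale.
#'
#' @param alphabet_size Number of symbols.
#' @param increment Count added per observation (default 32).
#' @param rescale_limit Total count that triggers halving (default 8192).
#' @return An `adaptive_model` object.
#' @export
adaptive_model <- function(alphabet_size, increment = 32L, rescale_limit = 8192L) {
  stopifnot(alphabet_size >= 1L, increment >= 1L, rescale_limit < 65536L,
            rescale_limit >= alphabet_size)
  e <- new.env(parent = emptyenv())
  e$table <- list()
  e$alphabet_size <- as.integer(alphabet_size)
  e$increment <- as.integer(increment)
  e$rescale_limit <- as.integer(rescale_limit)
  class(e) <- "adaptive_model"
  e
}

counts_for <- function(model, key) {
  k <- as.character(key)
  cnt <- model$table[[k]]
  if (is.null(cnt)) rep.int(1L, model$alphabet_size) else cnt
}

#' Predicted symbol distribution for a context
#'
#' @param object An `adaptive_model`.
#' @param key Context key (any scalar usable as a name).
#' @param ... Unused.
#' @return Numeric probability vector over the alphabet (strictly positive,
#'   sums to 1); uniform for a context never seen.
#' @export
predict.adaptive_model <- function(object, key, ...) {
  cnt <- counts_for(object, key)
  cnt / sum(cnt)
}

#' Record an observed symbol in a context
#'
#' @param object An `adaptive_model`.
#' @param key Context key.
#' @param symbol 0-based symbol.
#' @param ... Unused.
#' @return The model, invisibly (updated in place).
#' @export
update.adaptive_model <- function(object, key, symbol, ...) {
  stopifnot(symbol >= 0L, symbol < object$alphabet_size)
  cnt <- counts_for(object, key)
  cnt[symbol + 1L] <- cnt[symbol + 1L] + object$increment
  if (sum(cnt) > object$rescale_limit) cnt <- pmax((cnt + 1L) %/% 2L, 1L)
  object$table[[as.character(key)]] <- cnt
  invisible(object)
}

#' @export
print.adaptive_model <- function(x, ...) {
  cat(sprintf("adaptive_model: alphabet %d, increment %d, rescale %d, %d active contexts\n",
              x$alphabet_size, x$increment, x$rescale_limit, length(x$table)))
  invisible(x)
}

#' Conditional entropy H(X | M) from a joint count table
#'
#' \deqn{H(X|M) = \sum_m p(m) \sum_x p(x|m) \log_2 \frac{1}{p(x|m)}}
#' with the usual convention that empty cells contribute nothing.
#'
#' @param joint_counts Numeric matrix, rows = conditioning states m,
#'   columns = symbols x; entries are non-negative counts.
#' @return Conditional entropy in bits per symbol.
#' @export
conditional_entropy <- function(joint_counts) {
  joint_counts <- as.matrix(joint_counts)
  if (any(joint_counts < 0)) stop("negative count")
  tot <- sum(joint_counts)
  if (tot == 0) stop("all-zero count table")
  row_tot <- rowSums(joint_counts)
  h <- 0
  for (i in seq_len(nrow(joint_counts))) {
    if (row_tot[i] == 0) next
    p <- joint_counts[i, ] / row_tot[i]
    p <- p[p > 0]
    h <- h + (row_tot[i] / tot) * sum(-p * log2(p))
  }
  unname(h)
}
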