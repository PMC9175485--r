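#' Serpentine (snake) scan path over the quality matrix
#'
#' The codec traverses the read-by-cycle matrix column by column: column 0
#' top to bottom, column 1 bottom to top, alternating, so that consecutive
#' coded symbols are vertical neighbours from the same sequencing cycle.
#' This keeps the adaptive coder on a locally stationary signal instead of
#' jumping from the (low-quality) tail of one read to the (high-quality) head
#' of the next, as the raster order does.
#'
#' For ragged inputs a column visits, in the current direction, exactly the
#' rows whose read is long enough to possess that column; the direction still
#' alternates with the column index, so the decoder can rebuild the path from
#' the transmitted length vector alone.
#'
#' @param row_lengths Integer vector of read lengths (one per read).
#' @return A `scan_path` object: list with `cells`, an n x 2 integer matrix
#'   of 0-based (row, column) pairs in coding order, and `shape`, the length
#'   vector it was built for.
#' @examples
#' serpentine_path(c(3, 3))$cells
#' @seealso [raster_path()], [invert_path()]
#' @export
serpentine_path <- function(row_lengths) {
  new_scan_path(cpp_scan_cells(as.integer(row_lengths), TRUE), row_lengths)
}

#' Raster (row-major) scan path
#'
#' The traditional traversal: each read left to right, read after read.
#' Kept as the baseline the serpentine order is compared against.
#'
#' @inheritParams serpentine_path
#' @return A `scan_path` object.
#' @export
raster_path <- function(row_lengths) {
  new_scan_path(cpp_scan_cells(as.integer(row_lengths), FALSE), row_lengths)
}

new_scan_path <- function(cells, row_lengths) {
  colnames(cells) <- c("row", "col")
  structure(list(cells = cells, shape = as.integer(row_lengths)),
            class = "scan_path")
}

#' @export
print.scan_path <- function(x, ...) {
  cat(sprintf("scan_path: %d cells over %d reads\n", nrow(x$cells),
              length(x$shape)))
  invisible(x)
}

#' Invert a scan path
#'
#' Returns the position of every matrix cell along the path, i.e. the inverse
#' of the bijection cells -> 1..n. Cell (r, c) of the ragged matrix is
#' addressed by its row-major linear index.
#'
#' @param path A `scan_path`.
#' @return Integer vector `pos` of length `sum(shape)` with
#'   `pos[linear_index(r, c)] = i` when `path$cells[i, ] == c(r, c)`;
#'   indices are 1-based, cells 0-based.
#' @export
invert_path <- function(path) {
  stopifnot(inherits(path, "scan_path"))
  n <- sum(path$shape)
  if (nrow(path$cells) != n) stop("path does not cover the matrix")
  lin <- cell_linear_index(path$shape, path$cells[, 1L], path$cells[, 2L])
  if (anyDuplicated(lin)) stop("duplicate cell in scan path")
  if (length(lin) && (min(lin) < 1L || max(lin) > n)) stop("cell outside matrix")
  pos <- integer(n)
  pos[lin] <- seq_len(nrow(path$cells))
  pos
}

# 1-based row-major linear index of 0-based cells (r, c) in a ragged matrix
cell_linear_index <- function(row_lengths, r, c) {
  offsets <- c(0L, cumsum(as.integer(row_lengths)))
  offsets[r + 1L] + c + 1L
}
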