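#' Read a 4-line FASTQ file
#'
#' Parses a canonical 4-line-per-record FASTQ file (identifier, bases, `+`
#' separator, quality string) into a `fastq` object holding the three record
#' streams. Gzipped input is decompressed transparently. Multi-line (wrapped)
#' FASTQ is rejected rather than normalized so that [write_fastq()] can
#' guarantee a byte-identical round trip.
#'
#' @param path Path to a FASTQ (optionally `.gz`) file, or a character vector
#'   of raw FASTQ lines.
#' @param offset Phred ASCII offset (default 33).
#' @return An object of class `fastq`: a list with character vectors `id`,
#'   `bases` and `qual` (one element per record, quality still ASCII-encoded),
#'   plus the `offset`. Quality integers are recovered with [build_matrix()].
#' @examples
#' fq <- read_fastq(c("@r1", "ACGT", "+", "IIII"))
#' build_matrix(fq)$rows[[1]]  # 40 40 40 40
#' @export
read_fastq <- function(path, offset = 33L) {
  lines <- if (is.character(path) && length(path) != 1L) {
    path
  } else if (is.character(path) && length(path) == 1L && !file.exists(path) &&
             grepl("\n", path)) {
    strsplit(path, "\n", fixed = TRUE)[[1]]
  } else {
    con <- gzfile(path, "rb")
    on.exit(close(con))
    readLines(con, warn = FALSE)
  }
  if (length(lines) == 0L) {
    return(new_fastq(character(), character(), character(), offset))
  }
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("malformed FASTQ: %d lines is not a multiple of 4 (record %d truncated)",
                 length(lines), length(lines) %/% 4L + 1L))
  }
  n <- length(lines) %/% 4L
  id <- lines[seq(1L, by = 4L, length.out = n)]
  bases <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]

  bad <- which(!startsWith(id, "@"))
  if (length(bad)) stop(sprintf("malformed FASTQ: record %d does not start with '@'", bad[1]))
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) stop(sprintf("malformed FASTQ: record %d is missing the '+' line", bad[1]))
  bad <- which(nchar(bases) != nchar(qual))
  if (length(bad)) {
    stop(sprintf("record %d: base/quality length mismatch (%d vs %d)",
                 bad[1], nchar(bases[bad[1]]), nchar(qual[bad[1]])))
  }
  qcodes <- utf8ToInt(paste(qual, collapse = ""))
  if (length(qcodes) && (min(qcodes) < 33L || max(qcodes) > 126L)) {
    off <- which(qcodes < 33L | qcodes > 126L)[1]
    lens <- cumsum(nchar(qual))
    rec <- findInterval(off - 1L, lens) + 1L
    stop(sprintf("record %d: quality character outside printable ASCII 33-126", rec))
  }
  bad <- which(grepl("[^ACGTNacgtn]", bases))
  if (length(bad)) {
    # IUPAC ambiguity codes are tolerated (folded to N for context purposes)
    bad2 <- which(grepl("[^A-Za-z]", bases))
    if (length(bad2)) stop(sprintf("record %d: non-alphabetic base character", bad2[1]))
  }
  new_fastq(id, bases, qual, offset)
}

new_fastq <- function(id, bases, qual, offset = 33L) {
  structure(list(id = id, bases = bases, qual = qual,
                 offset = as.integer(offset)),
            class = "fastq")
}

#' @export
print.fastq <- function(x, ...) {
  cat(sprintf("fastq: %d records, read lengths %s, Phred+%d\n",
              length(x$id),
              if (length(x$id)) paste(range(nchar(x$qual)), collapse = "-") else "-",
              x$offset))
  invisible(x)
}

#' @export
length.fastq <- function(x) length(x$id)

#' Write a fastq object back to disk
#'
#' Inverse of [read_fastq()] for canonical 4-line FASTQ: the emitted bytes are
#' identical to the parsed input.
#'
#' @param fq A `fastq` object.
#' @param path Output path ( `"-"` for stdout) .
#' @return Invisibly, the number of bytes written.
#' @export
write_fastq <- function(fq, path) {
  stopifnot(inherits(fq, "fastq"))
  n <- length(fq$id)
  if (n == 0L) {
    con <- file(path, "wb")
    close(con)
    return(invisible(0L))
  }
  lines <- character(4L * n)
  lines[seq(1L, by = 4L, length.out = n)] <- fq$id
  lines[seq(2L, by = 4L, length.out = n)] <- fq$bases
  lines[seq(3L, by = 4L, length.out = n)] <- "+"
  lines[seq(4L, by = 4L, length.out = n)] <- fq$qual
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(sum(nchar(lines, type = "bytes")) + length(lines))
}

#' Assemble the quality matrix of a FASTQ file
#'
#' Converts the ASCII quality stream into the ragged read-by-cycle matrix of
#' Phred integers that the codec traverses: row r is read r (file order),
#' column c is sequencing cycle c.
#'
#' @param fq A `fastq` object (or character vector of quality strings).
#' @param offset Phred ASCII offset; defaults to the object's.
#' @return An object of class `quality_matrix`: list with `rows` (list of
#'   integer vectors), `lengths`, `n_reads` and `max_len`.
#' @export
build_matrix <- function(fq, offset = NULL) {
  qual <- if (inherits(fq, "fastq")) fq$qual else as.character(fq)
  if (is.null(offset)) offset <- if (inherits(fq, "fastq")) fq$offset else 33L
  lengths <- nchar(qual)
  flat <- phred_from_ascii(qual, offset)
  rows <- if (length(qual)) {
    split(flat, rep.int(seq_along(qual), lengths))
  } else {
    list()
  }
  names(rows) <- NULL
  structure(list(rows = rows, lengths = as.integer(lengths),
                 n_reads = length(qual),
                 max_len = if (length(qual)) max(lengths) else 0L,
                 offset = as.integer(offset)),
            class = "quality_matrix")
}

#' @export
print.quality_matrix <- function(x, ...) {
  cat(sprintf("quality_matrix: %d reads, max length %d\n", x$n_reads, x$max_len))
  invisible(x)
}

# flat vector of Phred integers for a vector of quality strings
phred_from_ascii <- function(qual, offset = 33L) {
  if (!length(qual) || sum(nchar(qual)) == 0L) return(integer())
  utf8ToInt(paste(qual, collapse = "")) - as.integer(offset)
}

phred_to_ascii <- function(phred, lengths, offset = 33L) {
  stopifnot(all(phred >= 0L), all(phred + offset <= 126L))
  if (!length(phred)) return(rep("", length(lengths)))
  s <- intToUtf8(phred + as.integer(offset))
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  substring(s, starts, ends)
}

# fold base characters to the 5-letter context alphabet codes A,C,G,T,N -> 0..4
base_context_codes <- function(bases) {
  if (!length(bases) || sum(nchar(bases)) == 0L) return(integer())
  chars <- utf8ToInt(paste(toupper(bases), collapse = ""))
  code <- rep.int(4L, length(chars))                     # default N
  code[chars == utf8ToInt("A")] <- 0L
  code[chars == utf8ToInt("C")] <- 1L
  code[chars == utf8ToInt("G")] <- 2L
  code[chars == utf8ToInt("T")] <- 3L
  code
}
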