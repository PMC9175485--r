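ACO_MAGIC <- charToRaw("ACOQ")
ACO_VERSION <- 1L

FLAG_ROWMEAN <- 1L
FLAG_BASES_EMBEDDED <- 2L
FLAG_SERPENTINE <- 4L
FLAG_Q2 <- 8L
FLAG_BASE_CTX <- 16L

#' Compress FASTQ quality scores into a container
#'
#' Encodes the quality stream of a FASTQ file into the `.aco` container:
#' reads are processed in blocks, and per block the read lengths, the
#' quantized row means and (optionally) the bases are coded as side streams,
#' followed by the quality bitstream coded along the serpentine scan under
#' the compound context model. Decoding with [aco_decompress()] reproduces
#' the quality stream byte-identically. Read identifiers are not stored.
#'
#' With `use_rowmean = "auto"` the first block is encoded once with and once
#' without the row-mean context; whichever total (quality bitstream plus
#' row-bin side stream) is smaller decides the file-wide setting, recorded in
#' the header.
#'
#' @param x Path to a FASTQ file (optionally gzipped) or a `fastq` object.
#' @param file Optional output path; when given the container is written
#'   there.
#' @param block_size Reads per block (each block is coded independently).
#' @param serpentine Use the serpentine scan (`FALSE` = raster baseline).
#' @param use_rowmean `"auto"`, `TRUE` or `FALSE`: row-mean context dimension.
#' @param use_base Condition on the second-order base context.
#' @param use_q2 Condition on the coarsened second-previous quality symbol.
#' @param embed_bases Store the base stream in the container (order-2 coded)
#'   so decompression is self-contained; with `FALSE` the same bases must be
#'   supplied to [aco_decompress()].
#' @param increment,rescale_limit,q2_levels Adaptive model hyperparameters,
#'   recorded in the header so decode is parameter-exact.
#' @return Raw vector of container bytes (invisibly when `file` is given).
#' @examples
#' fq <- read_fastq(c("@r", "ACGT", "+", "IIII"))
#' con <- aco_compress(fq)
#' identical(aco_decompress(con)$qual, fq$qual)
#' @export
aco_compress <- function(x, file = NULL, block_size = 100000L,
                         serpentine = TRUE, use_rowmean = "auto",
                         use_base = TRUE, use_q2 = TRUE, embed_bases = TRUE,
                         increment = 32L, rescale_limit = 8192L,
                         q2_levels = 9L) {
  fq <- if (inherits(x, "fastq")) x else read_fastq(x)
  block_size <- as.integer(block_size)
  stopifnot(block_size >= 1L)

  n <- length(fq$id)
  lengths <- nchar(fq$qual)
  if (any(lengths >= 65536L)) stop("read length >= 65536 not supported")
  quals <- phred_from_ascii(fq$qual, fq$offset)
  if (length(quals) && min(quals) < 0L) stop("quality below Phred offset: mixed offsets?")
  alphabet <- max(1L, if (length(quals)) max(quals) + 1L else 1L)
  if (alphabet > 94L) stop("quality above printable Phred+33 range")
  nrb <- n_row_bins(alphabet - 1L)

  base_codes <- if (use_base || embed_bases) base_context_codes(fq$bases) else integer()
  if ((use_base || embed_bases) && length(base_codes) != sum(lengths)) {
    stop("bases and qualities disagree in length")
  }
  # original base bytes, for the verbatim side stream
  base_alpha <- if (embed_bases && n > 0L && sum(nchar(fq$bases)) > 0L) {
    sort(unique(strsplit(paste(fq$bases, collapse = ""), "")[[1]]))
  } else {
    character()
  }
  base_byte_codes <- if (embed_bases && length(base_alpha)) {
    match(strsplit(paste(fq$bases, collapse = ""), "")[[1]], base_alpha) - 1L
  } else {
    integer()
  }

  offsets <- c(0L, cumsum(lengths))
  blocks <- if (n > 0L) split(seq_len(n), (seq_len(n) - 1L) %/% block_size) else list()

  block_cells <- function(idx) {
    seq(offsets[idx[1]] + 1L,
        length.out = offsets[idx[length(idx)] + 1L] - offsets[idx[1]])
  }

  encode_quality_block <- function(idx, rowmean_on) {
    qs <- quals[block_cells(idx)]
    bl <- lengths[idx]
    bc <- if (use_base) base_codes[block_cells(idx)] else integer()
    if (rowmean_on) {
      means <- block_row_means(qs, bl)
      bins <- quantize_row_mean(means)
      rb_idx <- row_bin_index(bins, alphabet - 1L)
    } else {
      rb_idx <- integer()
    }
    qbytes <- cpp_encode_qualities(qs, bl, bc, rb_idx, serpentine, alphabet,
                                   as.integer(q2_levels), nrb, use_q2,
                                   rowmean_on, use_base,
                                   as.integer(increment), as.integer(rescale_limit))
    rb_bytes <- if (rowmean_on) {
      rc_encode(rb_idx, nrb, increment, rescale_limit)
    } else {
      raw()
    }
    list(quality = qbytes, rowbins = rb_bytes)
  }

  if (identical(use_rowmean, "auto")) {
    use_rowmean <- if (length(blocks)) {
      on <- encode_quality_block(blocks[[1]], TRUE)
      off <- encode_quality_block(blocks[[1]], FALSE)
      length(on$quality) + length(on$rowbins) < length(off$quality)
    } else {
      FALSE
    }
  }
  use_rowmean <- isTRUE(use_rowmean)

  flags <- 0L
  if (use_rowmean) flags <- flags + FLAG_ROWMEAN
  if (embed_bases) flags <- flags + FLAG_BASES_EMBEDDED
  if (serpentine) flags <- flags + FLAG_SERPENTINE
  if (use_q2) flags <- flags + FLAG_Q2
  if (use_base) flags <- flags + FLAG_BASE_CTX

  chunks <- list(
    ACO_MAGIC, as.raw(ACO_VERSION), as.raw(fq$offset), as.raw(flags),
    as.raw(alphabet), as.raw(q2_levels),
    pack_u16(increment), pack_u16(rescale_limit),
    pack_u32(block_size), pack_u32(n), pack_u32(length(blocks))
  )
  if (embed_bases) {
    ab <- if (length(base_alpha)) charToRaw(paste(base_alpha, collapse = "")) else raw()
    chunks <- c(chunks, list(as.raw(length(ab)), ab))
  }

  for (idx in blocks) {
    bl <- lengths[idx]
    chunks <- c(chunks, list(pack_u32(length(idx))))
    chunks <- c(chunks, encode_lengths_stream(bl, increment, rescale_limit))
    enc <- encode_quality_block(idx, use_rowmean)
    if (use_rowmean) {
      chunks <- c(chunks, list(pack_u32(length(enc$rowbins)), enc$rowbins))
    }
    if (embed_bases) {
      bb <- if (length(base_alpha)) {
        cpp_encode_bases(base_byte_codes[block_cells(idx)],
                         bl, length(base_alpha),
                         as.integer(increment), as.integer(rescale_limit))
      } else {
        raw()
      }
      chunks <- c(chunks, list(pack_u32(length(bb)), bb))
    }
    chunks <- c(chunks, list(pack_u32(length(enc$quality)), enc$quality))
  }
  chunks <- c(chunks, list(cpp_fnv1a64(quals)))
  out <- do.call(c, chunks)
  if (!is.null(file)) {
    writeBin(out, file)
    return(invisible(out))
  }
  out
}

# per-read means of a concatenated quality block
block_row_means <- function(quals, lengths) {
  if (!length(lengths)) return(numeric())
  means <- numeric(length(lengths))
  nz <- lengths > 0L
  if (any(nz)) {
    grp <- rep.int(seq_along(lengths), lengths)
    means[nz] <- (rowsum(as.numeric(quals), grp)[, 1]) / lengths[nz]
  }
  means
}

encode_lengths_stream <- function(lengths, increment, rescale_limit) {
  if (length(unique(lengths)) <= 1L) {
    return(list(as.raw(1L), pack_u32(if (length(lengths)) lengths[1] else 0L)))
  }
  zz <- zigzag(diff(c(0L, lengths)))
  lo <- rc_encode(zz %% 256L, 256L, increment, rescale_limit)
  hi <- rc_encode(zz %/% 256L, 256L, increment, rescale_limit)
  list(as.raw(0L), pack_u32(length(lo)), lo, pack_u32(length(hi)), hi)
}

#' Decompress an `.aco` container
#'
#' Exact inverse of [aco_compress()] on the quality stream. The header is
#' read first (scan order, context schema and model hyperparameters), then
#' per block the side streams are decoded ahead of the quality bitstream so
#' every context key is available when its symbol is decoded. A 64-bit
#' checksum of the decoded Phred values is verified against the one recorded
#' at compression time.
#'
#' @param x Path to an `.aco` file or a raw vector of container bytes.
#' @param bases External bases (character vector of per-read base strings, a
#'   `fastq` object, or a FASTQ path); required iff the container was written
#'   with `embed_bases = FALSE` and a base-dependent context.
#' @return List with `qual` (ASCII quality strings, Phred+33 by default),
#'   `bases` (character vector if embedded, otherwise `NULL`), `lengths`,
#'   and `offset`.
#' @export
aco_decompress <- function(x, bases = NULL) {
  bytes <- if (is.raw(x)) x else readBin(x, "raw", file.size(x))
  hdr <- parse_container(bytes)

  ext_bases <- NULL
  if (!is.null(bases)) {
    ext_bases <- if (inherits(bases, "fastq")) bases$bases
                 else if (is.character(bases) && length(bases) == 1L &&
                          file.exists(bases)) read_fastq(bases)$bases
                 else as.character(bases)
  }
  if (hdr$use_base && !hdr$bases_embedded && is.null(ext_bases)) {
    stop("container was written without embedded bases: supply them via `bases`")
  }

  nrb <- n_row_bins(hdr$alphabet - 1L)
  all_quals <- integer(0)
  all_lengths <- integer(0)
  base_chunks <- character(0)
  read0 <- 0L

  for (b in seq_len(hdr$n_blocks)) {
    blk <- hdr$blocks[[b]]
    bl <- blk$lengths
    n_cells <- sum(bl)
    rb_idx <- if (hdr$use_rowmean) {
      rc_decode(blk$rowbins, length(bl), nrb, hdr$increment, hdr$rescale)
    } else {
      integer()
    }
    if (hdr$bases_embedded && length(hdr$base_alpha)) {
      codes <- cpp_decode_bases(blk$bases, bl, length(hdr$base_alpha),
                                hdr$increment, hdr$rescale)
      chars <- paste(hdr$base_alpha[codes + 1L], collapse = "")
      ends <- cumsum(bl)
      block_bases <- substring(chars, ends - bl + 1L, ends)
    } else if (!is.null(ext_bases)) {
      block_bases <- ext_bases[(read0 + 1L):(read0 + length(bl))]
      if (any(nchar(block_bases) != bl)) {
        stop("external bases do not match the recorded read lengths")
      }
    } else {
      block_bases <- NULL
    }
    bc <- if (hdr$use_base) base_context_codes(block_bases) else integer()
    qs <- cpp_decode_qualities(blk$quality, bl, bc, rb_idx, hdr$serpentine,
                               hdr$alphabet, hdr$q2_levels, nrb, hdr$use_q2,
                               hdr$use_rowmean, hdr$use_base,
                               hdr$increment, hdr$rescale)
    all_quals <- c(all_quals, qs)
    all_lengths <- c(all_lengths, bl)
    if (!is.null(block_bases) && hdr$bases_embedded) {
      base_chunks <- c(base_chunks, block_bases)
    }
    read0 <- read0 + length(bl)
  }

  if (!identical(as.integer(cpp_fnv1a64(all_quals)), as.integer(hdr$checksum))) {
    stop("checksum mismatch: container corrupted or wrong external bases")
  }
  list(qual = phred_to_ascii(all_quals, all_lengths, hdr$offset),
       bases = if (hdr$bases_embedded) base_chunks else NULL,
       lengths = all_lengths, offset = hdr$offset)
}

# Header + stream layout of a container, without decoding payload streams.
parse_container <- function(bytes) {
  if (length(bytes) < 31L || !identical(bytes[1:4], ACO_MAGIC)) {
    stop("not an ACO container (bad magic)")
  }
  if (as.integer(bytes[5]) != ACO_VERSION) {
    stop(sprintf("unsupported container version %d", as.integer(bytes[5])))
  }
  offset <- as.integer(bytes[6])
  flags <- as.integer(bytes[7])
  alphabet <- as.integer(bytes[8])
  q2_levels <- as.integer(bytes[9])
  increment <- unpack_u16(bytes, 10L)
  rescale <- unpack_u16(bytes, 12L)
  block_size <- unpack_u32(bytes, 14L)
  n_reads <- unpack_u32(bytes, 18L)
  n_blocks <- unpack_u32(bytes, 22L)
  pos <- 26L
  bases_embedded <- bitwAnd(flags, FLAG_BASES_EMBEDDED) > 0L
  base_alpha <- character()
  if (bases_embedded) {
    na <- as.integer(bytes[pos]); pos <- pos + 1L
    if (na > 0L) {
      base_alpha <- strsplit(rawToChar(bytes[pos:(pos + na - 1L)]), "")[[1]]
      pos <- pos + na
    }
  }
  use_rowmean <- bitwAnd(flags, FLAG_ROWMEAN) > 0L
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    nb <- unpack_u32(bytes, pos); pos <- pos + 4L
    const <- as.integer(bytes[pos]); pos <- pos + 1L
    if (const == 1L) {
      len <- unpack_u32(bytes, pos); pos <- pos + 4L
      lengths <- rep.int(len, nb)
      len_bytes <- 5L
    } else {
      nlo <- unpack_u32(bytes, pos); pos <- pos + 4L
      lo <- bytes[seq(pos, length.out = nlo)]; pos <- pos + nlo
      nhi <- unpack_u32(bytes, pos); pos <- pos + 4L
      hi <- bytes[seq(pos, length.out = nhi)]; pos <- pos + nhi
      zz <- rc_decode(lo, nb, 256L, increment, rescale) +
        256L * rc_decode(hi, nb, 256L, increment, rescale)
      lengths <- cumsum(unzigzag(zz))
      len_bytes <- 9L + nlo + nhi
    }
    rowbins <- raw()
    rb_bytes <- 0L
    if (use_rowmean) {
      nrbb <- unpack_u32(bytes, pos); pos <- pos + 4L
      rowbins <- bytes[seq(pos, length.out = nrbb)]; pos <- pos + nrbb
      rb_bytes <- 4L + nrbb
    }
    bstream <- raw()
    b_bytes <- 0L
    if (bases_embedded) {
      nbb <- unpack_u32(bytes, pos); pos <- pos + 4L
      bstream <- bytes[seq(pos, length.out = nbb)]; pos <- pos + nbb
      b_bytes <- 4L + nbb
    }
    nq <- unpack_u32(bytes, pos); pos <- pos + 4L
    quality <- bytes[seq(pos, length.out = nq)]; pos <- pos + nq
    blocks[[b]] <- list(lengths = lengths, rowbins = rowbins, bases = bstream,
                        quality = quality,
                        stream_bytes = c(lengths = len_bytes,
                                         rowbins = rb_bytes,
                                         bases = b_bytes,
                                         quality = 4L + nq))
  }
  if (pos + 7L > length(bytes)) stop("container truncated before checksum")
  checksum <- bytes[pos:(pos + 7L)]
  list(offset = offset, flags = flags, alphabet = alphabet,
       q2_levels = q2_levels, increment = increment, rescale = rescale,
       block_size = block_size, n_reads = n_reads, n_blocks = n_blocks,
       base_alpha = base_alpha,
       use_rowmean = use_rowmean, bases_embedded = bases_embedded,
       serpentine = bitwAnd(flags, FLAG_SERPENTINE) > 0L,
       use_q2 = bitwAnd(flags, FLAG_Q2) > 0L,
       use_base = bitwAnd(flags, FLAG_BASE_CTX) > 0L,
       blocks = blocks, checksum = checksum, total_bytes = length(bytes))
}

#' Verify a container against its source FASTQ
#'
#' Decompresses the container and checks that the quality stream (and the
#' base stream, when embedded) matches the FASTQ file exactly.
#'
#' @param fastq FASTQ path or `fastq` object.
#' @param container `.aco` path or raw vector.
#' @return `TRUE` invisibly; error on any mismatch.
#' @export
aco_verify <- function(fastq, container) {
  fq <- if (inherits(fastq, "fastq")) fastq else read_fastq(fastq)
  dec <- aco_decompress(container, bases = fq$bases)
  if (!identical(dec$qual, unname(fq$qual))) {
    stop("quality stream mismatch after decompression")
  }
  if (!is.null(dec$bases) && !identical(dec$bases, unname(fq$bases))) {
    stop("base stream mismatch after decompression")
  }
  invisible(TRUE)
}
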