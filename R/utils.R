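# Little-endian integer packing for the container format.

pack_u32 <- function(x) {
  stopifnot(x >= 0, x < 2^32)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

unpack_u32 <- function(bytes, at) {
  b <- as.integer(bytes[at:(at + 3L)])
  b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
}

pack_u16 <- function(x) {
  stopifnot(x >= 0, x < 2^16)
  as.raw(c(x %% 256, x %/% 256))
}

unpack_u16 <- function(bytes, at) {
  as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
}

# zigzag map: signed integer -> non-negative, order-preserving around 0
zigzag <- function(x) ifelse(x >= 0, 2L * x, -2L * x - 1L)
unzigzag <- function(z) ifelse(z %% 2L == 0L, z %/% 2L, -(z + 1L) %/% 2L)
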