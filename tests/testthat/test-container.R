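test_that("an empty file yields a header-only container that decodes empty", {
  fq <- acoq:::new_fastq(character(), character(), character())
  con <- aco_compress(fq)
  dec <- aco_decompress(con)
  expect_length(dec$qual, 0)
  expect_lt(length(con), 60)
})

test_that("a single constant-quality read beats its raw size", {
  fq <- read_fastq(c("@r", strrep("A", 200), "+", strrep("I", 200)))
  con <- aco_compress(fq, embed_bases = FALSE)
  expect_lt(length(con), 200)
  expect_identical(aco_decompress(con, bases = fq$bases)$qual, fq$qual)
})

test_that("round trips are exact over random ragged fixtures", {
  for (seed in c(1, 5, 9, 23, 77)) {
    fq <- random_fastq(seed, max_q = if (seed == 9) 93 else 41)
    con <- aco_compress(fq)
    dec <- aco_decompress(con)
    expect_identical(dec$qual, unname(fq$qual))
    expect_identical(dec$bases, unname(fq$bases))
    expect_identical(dec$lengths, unname(nchar(fq$qual)))
    expect_true(aco_verify(fq, con))
  }
  # length-1 reads and alphabet extremes
  fq <- acoq:::new_fastq(c("@a", "@b", "@c"), c("A", "N", "g"),
                         c("!", "~", "5"))
  expect_identical(aco_decompress(aco_compress(fq))$qual, fq$qual)
})

test_that("multi-block processing round-trips and matches the shape", {
  fq <- random_fastq(31, n_reads = 157, max_len = 30)
  con <- aco_compress(fq, block_size = 25L)
  hdr <- acoq:::parse_container(con)
  expect_equal(hdr$n_blocks, ceiling(157 / 25))
  expect_identical(aco_decompress(con)$qual, unname(fq$qual))
})

test_that("every context configuration round-trips", {
  fq <- random_fastq(12, n_reads = 60, max_len = 25)
  for (serp in c(TRUE, FALSE)) {
    for (rm in c(TRUE, FALSE)) {
      for (ub in c(TRUE, FALSE)) {
        con <- aco_compress(fq, serpentine = serp, use_rowmean = rm,
                            use_base = ub, use_q2 = ub)
        expect_identical(aco_decompress(con)$qual, unname(fq$qual))
      }
    }
  }
})

test_that("payload corruption is caught by the checksum", {
  fq <- random_fastq(3, n_reads = 50)
  con <- aco_compress(fq)
  bad <- con
  i <- length(bad) - 20L  # inside the last quality stream
  bad[i] <- xor(bad[i], as.raw(0x10))
  expect_error(aco_decompress(bad), "checksum|exhausted")
})

test_that("external-bases mode needs the right bases", {
  fq <- random_fastq(8, n_reads = 40)
  con <- aco_compress(fq, embed_bases = FALSE)
  dec <- aco_decompress(con, bases = fq$bases)
  expect_identical(dec$qual, unname(fq$qual))
  expect_null(dec$bases)
  expect_error(aco_decompress(con), "supply them")
  wrong <- vapply(nchar(fq$bases), function(l) strrep("A", l), "")
  expect_error(aco_decompress(con, bases = wrong), "checksum")
})

test_that("version and magic are enforced", {
  fq <- random_fastq(2, n_reads = 5)
  con <- aco_compress(fq)
  bad <- con; bad[1] <- as.raw(0x58)
  expect_error(aco_decompress(bad), "magic")
  bad2 <- con; bad2[5] <- as.raw(99)
  expect_error(aco_decompress(bad2), "version")
})

test_that("the auto row-mean probe records a single file-wide flag", {
  fq <- generate_fastq(synth_config(n_reads = 3000, read_len = 40, seed = 2))
  con_auto <- aco_compress(fq, embed_bases = FALSE, use_rowmean = "auto")
  hdr <- acoq:::parse_container(con_auto)
  con_fixed <- aco_compress(fq, embed_bases = FALSE,
                            use_rowmean = hdr$use_rowmean)
  expect_identical(con_auto, con_fixed)
})
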