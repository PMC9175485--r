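test_that("generation is reproducible and leaves the RNG alone", {
  cfg <- synth_config(n_reads = 50, read_len = 30, seed = 6)
  f1 <- tmp_fastq(generate_fastq(cfg))
  set.seed(1234)
  before <- .Random.seed
  f2 <- tmp_fastq(generate_fastq(cfg))
  expect_identical(.Random.seed, before)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  f3 <- tmp_fastq(generate_fastq(synth_config(n_reads = 50, read_len = 30,
                                              seed = 7)))
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
})

test_that("degenerate configurations behave", {
  expect_length(generate_fastq(synth_config(n_reads = 0)), 0)
  fq <- generate_fastq(synth_config(n_reads = 3, read_len = c(5, 2, 9),
                                    seed = 2))
  expect_equal(nchar(fq$qual), c(5L, 2L, 9L))
  expect_equal(nchar(fq$bases), c(5L, 2L, 9L))
})

test_that("generated records are valid FASTQ within the quality ceiling", {
  fq <- generate_fastq(synth_config(n_reads = 200, read_len = 50, seed = 3))
  m <- build_matrix(fq)
  q <- unlist(m$rows)
  expect_gte(min(q), 0)
  expect_lte(max(q), 41)
  expect_true(all(grepl("^[ACGT]+$", fq$bases)))
  # parse back through the standard reader
  expect_identical(read_fastq(tmp_fastq(fq))$qual, unname(fq$qual))
})

test_that("the default regime shows the decaying mean and strong correlation", {
  fq <- generate_fastq(synth_config())  # 20k x 100, seed 1
  m <- build_matrix(fq)
  qm <- matrix(unlist(m$rows), nrow = m$n_reads, byrow = TRUE)
  cyc_mean <- colMeans(qm)
  slope <- unname(coef(lm(cyc_mean ~ seq_along(cyc_mean)))[2])
  expect_lt(slope, 0)
  # variance grows along the read
  v <- apply(qm, 2, var)
  expect_gt(mean(v[81:100]), mean(v[1:20]))
  ac <- mean(apply(qm[1:4000, ], 1, function(x) cor(x[-1], x[-length(x)])))
  expect_gte(ac, 0.7)
  expect_lte(ac, 0.9)
})

test_that("an i.i.d. source makes scan order irrelevant", {
  fq <- generate_fastq(synth_config(n_reads = 5000, read_len = 60,
                                    preset = "iid", seed = 3))
  a <- length(aco_compress(fq, embed_bases = FALSE, serpentine = TRUE))
  b <- length(aco_compress(fq, embed_bases = FALSE, serpentine = FALSE))
  expect_lt(abs(a - b) / b, 0.01)
})

test_that("presets switch their target structure off and on", {
  cfg <- synth_config(preset = "iid")
  expect_equal(cfg$ar1_rho, 0)
  expect_equal(cfg$dip_prob, 0)
  expect_equal(cfg$read_level_sd, 0)
  cfgd <- synth_config(preset = "dips-only")
  expect_equal(cfgd$dip_prob, 1)
  expect_equal(cfgd$mean_slope, 0)
  # dips-only: flat cycle means, dips present at base changes
  fq <- generate_fastq(synth_config(n_reads = 2000, read_len = 40, seed = 5,
                                    preset = "dips-only"))
  m <- build_matrix(fq)
  qm <- matrix(unlist(m$rows), nrow = m$n_reads, byrow = TRUE)
  expect_lt(abs(unname(coef(lm(colMeans(qm) ~ seq_len(ncol(qm))))[2])), 0.02)
  expect_gt(length(unique(as.vector(qm))), 1)  # dips create a second level
})
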