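test_that("row means are plain arithmetic means, empty reads giving 0", {
  expect_equal(compute_row_mean(c(30, 32, 34)), 32)
  expect_equal(compute_row_mean(40), 40)
  expect_equal(compute_row_mean(c(0, 0, 0, 0)), 0)
  expect_equal(compute_row_mean(integer()), 0)
})

test_that("row-mean quantization follows the piecewise bin rule exactly", {
  expect_equal(quantize_row_mean(29), 30L)
  expect_equal(quantize_row_mean(31), 32L)
  expect_equal(quantize_row_mean(33), 34L)
  expect_equal(quantize_row_mean(37), 38L)
  expect_equal(quantize_row_mean(40.2), 40L)
  # full integer range against an independent statement of the rule
  q <- 0:41
  want <- ifelse(q < 30, 30L,
          ifelse(q < 32, 32L,
          ifelse(q < 34, 34L,
          ifelse(q < 36, 36L,
          ifelse(q < 38, 38L, as.integer(round(q)))))))
  expect_equal(quantize_row_mean(q), want)
  # boundary behaviour on reals
  expect_equal(quantize_row_mean(c(29.99, 30, 31.99, 32, 35.99, 36, 37.99, 38)),
               c(30L, 32L, 32L, 34L, 36L, 38L, 38L, 38L))
})

test_that("context keys use sentinels at block and read starts", {
  fq <- read_fastq(c("@a", "ACG", "+", "III", "@b", "TGC", "+", "III"))
  m <- build_matrix(fq)
  bins <- quantize_row_mean(vapply(m$rows, compute_row_mean, numeric(1)))
  ctx1 <- make_context(1, m, fq$bases, bins)
  expect_equal(ctx1$q_prev1, 0L)
  expect_equal(ctx1$q_prev2_coarse, 0L)
  expect_equal(ctx1$base_pair, "A^")  # first base, start-of-read sentinel
  # third cell of the 2x3 serpentine with all quals 40: two symbols back seen
  ctx3 <- make_context(3, m, fq$bases, bins)
  expect_equal(ctx3$q_prev1, 40L)
  expect_equal(ctx3$q_prev2_coarse, 8L)  # 40 %/% 5
})

test_that("every context key is decodable from earlier symbols and side streams", {
  fq <- random_fastq(21, n_reads = 40, max_len = 12)
  m <- build_matrix(fq)
  means <- vapply(m$rows, compute_row_mean, numeric(1))
  bins <- quantize_row_mean(means)
  max_q <- max(unlist(m$rows))
  rb_idx <- acoq:::row_bin_index(bins, max_q)
  trace <- acoq:::cpp_context_trace(
    unlist(m$rows), m$lengths, acoq:::base_context_codes(fq$bases), rb_idx,
    TRUE, max_q + 1L, 9L, acoq:::n_row_bins(max_q), TRUE, TRUE, TRUE)
  decisions <- list(max_q = max_q)
  alpha6 <- c("A", "C", "G", "T", "N", "^")
  for (pos in seq_len(nrow(trace))) {
    ref <- make_context(pos, m, fq$bases, bins, decisions)
    expect_equal(trace[pos, 3], ref$q_prev1)
    expect_equal(trace[pos, 4], ref$q_prev2_coarse)
    expect_equal(trace[pos, 5], acoq:::row_bin_index(ref$row_bin, max_q))
    bp_ref <- (match(substr(ref$base_pair, 1, 1), alpha6) - 1L) * 6L +
      (match(substr(ref$base_pair, 2, 2), alpha6) - 1L)
    expect_equal(trace[pos, 6], bp_ref)
  }
})

test_that("adaptive model predicts by count shares and rescales at the limit", {
  m <- adaptive_model(64L, increment = 32L, rescale_limit = 8192L)
  expect_equal(predict(m, "k"), rep(1 / 64, 64))
  update(m, "k", 40L)
  p <- predict(m, "k")
  expect_equal(p[41], 33 / 96)  # (1+32) / (64+32)
  expect_equal(sum(p), 1)
  expect_true(all(p > 0))
  # totals never exceed the rescale limit
  m2 <- adaptive_model(8L, increment = 100L, rescale_limit = 500L)
  for (i in 1:50) update(m2, "x", i %% 8L)
  expect_lte(sum(acoq:::counts_for(m2, "x")), 500)
  expect_true(all(acoq:::counts_for(m2, "x") >= 1))
})

test_that("adaptive predictions converge to a skewed source distribution", {
  set.seed(14)
  p_true <- c(0.55, 0.2, 0.1, 0.08, 0.04, 0.02, 0.008, 0.002)
  m <- adaptive_model(8L)
  draws <- sample(0:7, 10000, TRUE, p_true)
  for (s in draws) update(m, "ctx", s)
  tv <- 0.5 * sum(abs(predict(m, "ctx") - p_true))
  expect_lt(tv, 0.05)
})

test_that("adaptive order-0 coding rate approaches the source entropy", {
  set.seed(9)
  p <- c(.45, .25, .12, .08, .05, .03, .015, .005)
  x <- sample(0:7, 1e5, TRUE, p)
  H <- -sum(p * log2(p))
  rate <- 8 * length(rc_encode(x, 8L)) / length(x)
  expect_lt(rate - H, 0.05)
})

test_that("conditional entropy follows the defining formula", {
  # independence: H(X|M) = H(X)
  px <- c(0.3, 0.7)
  joint <- outer(c(0.4, 0.6), px) * 1000
  expect_equal(conditional_entropy(joint), -sum(px * log2(px)))
  # determinism: H(X|M) = 0
  expect_equal(conditional_entropy(diag(c(5, 3, 9))), 0)
  # hand-evaluated 2x2 table [[2,1],[1,2]]
  h_row <- -(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3)
  expect_equal(conditional_entropy(matrix(c(2, 1, 1, 2), 2, byrow = TRUE)),
               h_row)
  expect_error(conditional_entropy(matrix(0, 2, 2)), "all-zero")
})

test_that("conditioning on the base pair lowers entropy when dips exist", {
  fq <- generate_fastq(synth_config(n_reads = 4000, read_len = 60, seed = 8,
                                    preset = "dips-only"))
  m <- build_matrix(fq)
  quals <- unlist(m$rows)
  bc <- acoq:::base_context_codes(fq$bases)
  prev <- acoq:::base_context_codes(fq$bases)  # shifted within read below
  idx <- rep(seq_along(m$lengths), m$lengths)
  cyc <- sequence(m$lengths)
  prev_b <- ifelse(cyc == 1, 5L, c(5L, bc[-length(bc)]))
  t1 <- table(bc, quals)
  t2 <- table(paste(bc, prev_b), quals)
  expect_lte(conditional_entropy(unclass(t2)), conditional_entropy(unclass(t1)))
})

test_that("the row-mean context pays for its side stream on spread-out reads", {
  fq <- generate_fastq(synth_config(n_reads = 8000, read_len = 80, seed = 5))
  on_ <- length(aco_compress(fq, embed_bases = FALSE, use_rowmean = TRUE,
                             use_base = FALSE, use_q2 = FALSE))
  off <- length(aco_compress(fq, embed_bases = FALSE, use_rowmean = FALSE,
                             use_base = FALSE, use_q2 = FALSE))
  expect_lt(on_, off)
})
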