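test_that("distortion measures satisfy their closed forms", {
  p <- c(0.2, 0.8)
  for (m in c("kl", "l1", "l2")) expect_equal(distortion(p, p, m), 0)
  expect_equal(distortion(c(1, 0), c(0.5, 0.5), "kl"), 1)
  expect_equal(distortion(c(0.2, 0.8), c(0.5, 0.5), "l1"), 0.6)
  expect_equal(distortion(c(0, 1), c(1, 0), "l2"), sqrt(2))
  expect_error(distortion(c(1, 0), c(1, 0, 0)), "length")
})

test_that("degenerate partitions behave as forced", {
  set.seed(5)
  cs <- random_condition_set(6)
  # K = N: identity partition, zero objective
  pid <- optimal_partition(cs, 6)
  expect_equal(pid$L, 0, tolerance = 1e-12)
  expect_equal(lengths(pid$bins), rep(1L, 6))
  # K = 1: single bin, representative is the prior mixture
  p1 <- optimal_partition(cs, 1)
  expect_equal(length(p1$bins), 1L)
  mix <- colSums(cs$conditionals * cs$priors)
  expect_equal(unname(p1$representatives[1, ]), unname(mix))
  expect_error(optimal_partition(cs, 7), "between 1 and N")
})

test_that("dynamic programming equals exhaustive search on random instances", {
  set.seed(5)
  for (i in 1:12) {
    N <- sample(2:10, 1)
    cs <- random_condition_set(N)
    for (K in 1:min(4, N)) {
      for (msr in c("kl", "l1")) {
        got <- optimal_partition(cs, K, msr)
        expect_equal(got$L, brute_force_partition_L(cs, K, msr),
                     tolerance = 1e-9)
        # reported bins actually achieve the reported objective
        expect_equal(partition_objective(cs, got$bins, msr), got$L,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("the objective is non-increasing in the number of bins", {
  set.seed(8)
  cs <- random_condition_set(9)
  L <- vapply(1:9, function(K) optimal_partition(cs, K)$L, numeric(1))
  expect_true(all(diff(L) <= 1e-12))
})

test_that("quantization cannot reduce conditional entropy", {
  set.seed(13)
  cs <- random_condition_set(8)
  # identity partition: no loss
  gap <- entropy_gap(cs, optimal_partition(cs, 8))
  expect_equal(gap[["H_XQ"]], gap[["H_XM"]], tolerance = 1e-12)
  # K = 1: H(X|Q) is the entropy of the mixture
  g1 <- entropy_gap(cs, optimal_partition(cs, 1))
  mix <- colSums(cs$conditionals * cs$priors)
  expect_equal(g1[["H_XQ"]], -sum(mix[mix > 0] * log2(mix[mix > 0])))
  # data-processing direction over random instances and K
  for (i in 1:10) {
    cs <- random_condition_set(sample(3:9, 1))
    K <- sample(seq_along(cs$priors), 1)
    g <- entropy_gap(cs, optimal_partition(cs, K))
    expect_gte(g[["H_XQ"]], g[["H_XM"]] - 1e-12)
  }
})

test_that("empirical row-mean conditionals quantize to monotone boundaries", {
  fq <- generate_fastq(synth_config(n_reads = 6000, read_len = 60, seed = 4))
  m <- build_matrix(fq)
  means <- round(vapply(m$rows, compute_row_mean, numeric(1)))
  quals <- unlist(m$rows)
  counts <- table(rep(means, m$lengths), quals)
  cs <- acoq:::condition_set_from_counts(unclass(counts))
  part <- optimal_partition(cs, 5)
  # contiguous bins over ordered means: boundaries strictly increase
  expect_true(all(diff(part$boundaries) > 0))
  expect_equal(sort(unlist(part$bins)), seq_along(cs$priors))
})
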