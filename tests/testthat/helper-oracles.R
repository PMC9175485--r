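# Independent reference implementations used as oracles. These deliberately
# use different algorithms from the package internals.

# serpentine order built column-wise with explicit direction bookkeeping
r_serpentine_cells <- function(row_lengths) {
  cells <- matrix(integer(), 0, 2)
  if (!length(row_lengths) || max(row_lengths) == 0) return(cells)
  for (col in 0:(max(row_lengths) - 1)) {
    rows <- which(row_lengths > col) - 1L
    if (!length(rows)) next
    if (col %% 2 == 1) rows <- rev(rows)
    cells <- rbind(cells, cbind(rows, col))
  }
  unname(cells)
}

r_raster_cells <- function(row_lengths) {
  out <- do.call(rbind, lapply(seq_along(row_lengths), function(r) {
    if (row_lengths[r] == 0) return(NULL)
    cbind(r - 1L, 0:(row_lengths[r] - 1L))
  }))
  if (is.null(out)) matrix(integer(), 0, 2) else unname(out)
}

# random FASTQ fixture with ragged lengths, N bases, lowercase, and quality
# values spanning the alphabet extremes
random_fastq <- function(seed, n_reads = NULL, max_len = 40, max_q = 41,
                         min_len = 1) {
  set.seed(seed)
  if (is.null(n_reads)) n_reads <- sample(1:30, 1)
  lens <- sample(min_len:max_len, n_reads, replace = TRUE)
  letters6 <- c("A", "C", "G", "T", "N", "a")
  bases <- vapply(lens, function(l) {
    paste(sample(letters6, l, TRUE, prob = c(.23, .23, .23, .23, .05, .03)),
          collapse = "")
  }, "")
  qual <- vapply(lens, function(l) {
    q <- sample(0:max_q, l, TRUE)
    if (l >= 2) q[1:2] <- c(0L, max_q)  # force alphabet extremes
    intToUtf8(q + 33L)
  }, "")
  acoq:::new_fastq(sprintf("@rand_%d", seq_len(n_reads)), bases, qual)
}

# direct evaluation of the partition objective L for given contiguous bins
partition_objective <- function(cs, bins, measure = "kl") {
  sum(vapply(bins, function(ix) {
    w <- cs$priors[ix]
    Q <- colSums(cs$conditionals[ix, , drop = FALSE] * w) / sum(w)
    sum(vapply(ix, function(t) {
      cs$priors[t] * distortion(cs$conditionals[t, ], Q, measure)
    }, numeric(1)))
  }, numeric(1)))
}

# exhaustive minimum over all contiguous K-partitions of 1..N
brute_force_partition_L <- function(cs, K, measure = "kl") {
  N <- length(cs$priors)
  if (K == 1) return(partition_objective(cs, list(1:N), measure))
  best <- Inf
  for (cut_set in utils::combn(N - 1, K - 1, simplify = FALSE)) {
    starts <- c(1, cut_set + 1)
    ends <- c(cut_set, N)
    bins <- Map(function(s, e) s:e, starts, ends)
    best <- min(best, partition_objective(cs, bins, measure))
  }
  best
}

random_condition_set <- function(N, A = 4) {
  p <- runif(N); p <- p / sum(p)
  cond <- matrix(rgamma(N * A, 0.7), N, A)
  cond <- cond / rowSums(cond)
  condition_set(p, cond)
}

tmp_fastq <- function(fq) {
  path <- tempfile(fileext = ".fastq")
  write_fastq(fq, path)
  path
}
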