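#' Distortion between two distributions
#'
#' Distortion measures available to the context quantizer. `"kl"` is the
#' Kullback-Leibler divergence in bits (with `0 log 0 = 0` and the second
#' argument floored at machine epsilon), matching the code-length
#' interpretation of merging conditioning states; `"l1"` and `"l2"` are the
#' corresponding vector norms of `p - q`.
#'
#' @param p,q Numeric probability vectors of equal length.
#' @param measure One of `"kl"`, `"l1"`, `"l2"`.
#' @return Non-negative scalar distortion.
#' @examples
#' distortion(c(1, 0), c(0.5, 0.5), "kl")  # 1 bit
#' @export
distortion <- function(p, q, measure = c("kl", "l1", "l2")) {
  measure <- match.arg(measure)
  if (length(p) != length(q)) stop("distributions have different lengths")
  switch(measure,
    kl = {
      qf <- pmax(q, .Machine$double.eps)
      nz <- p > 0
      sum(p[nz] * log2(p[nz] / qf[nz]))
    },
    l1 = sum(abs(p - q)),
    l2 = sqrt(sum((p - q)^2))
  )
}

#' Construct a condition set
#'
#' An ordered set of conditioning states m_i, each with a prior p(m_i) and a
#' conditional symbol distribution p(x | m_i). This is the input to the
#' context quantizer: in the production codec the conditions are integer row
#' means and the conditionals are empirical quality distributions.
#'
#' @param priors Numeric vector of state probabilities (sums to 1).
#' @param conditionals Numeric matrix, one row per state, rows sum to 1.
#' @param labels Optional state labels (e.g. the row-mean values).
#' @return A `condition_set` object.
#' @export
condition_set <- function(priors, conditionals, labels = NULL) {
  conditionals <- as.matrix(conditionals)
  if (length(priors) != nrow(conditionals)) {
    stop("one prior per conditional distribution required")
  }
  if (any(priors < 0) || abs(sum(priors) - 1) > 1e-8) {
    stop("priors must be a probability vector")
  }
  rs <- rowSums(conditionals)
  if (any(conditionals < 0) || any(abs(rs - 1) > 1e-8)) {
    stop("each conditional distribution must sum to 1")
  }
  structure(list(priors = as.numeric(priors), conditionals = conditionals,
                 labels = labels %||% seq_along(priors)),
            class = "condition_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# empirical condition set from a (condition, symbol) count matrix
condition_set_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0L) stop("all-zero count table")
  priors <- rowSums(counts) / sum(counts)
  conditionals <- counts / rowSums(counts)
  labs <- rownames(counts) %||% which(keep)
  condition_set(priors, conditionals, labels = labs)
}

#' Optimal contiguous partition of a condition set
#'
#' Groups the N ordered conditioning states into K contiguous bins minimizing
#' the prior-weighted distortion
#' \deqn{L = \sum_i d(p(x|m_i), Q(p(x|m_i)))\, p(m_i)}
#' where the quantized distribution Q of a bin is the prior-weighted mixture
#' of its members' conditionals. Solved exactly by dynamic programming over
#' bin boundaries in O(N^2 K) (after an O(N^2) cost table); ties are broken
#' toward the earliest boundary. Conditions are scalar-ordered (row means),
#' so only contiguous bins are considered.
#'
#' @param cs A `condition_set`.
#' @param K Number of bins, `1 <= K <= N`.
#' @param measure Distortion measure, see [distortion()].
#' @return A `condition_partition`: list with `bins` (list of index vectors),
#'   `boundaries` (last member index of each bin), `representatives` (K x
#'   alphabet matrix of quantized distributions), and the objective `L`.
#' @export
optimal_partition <- function(cs, K, measure = c("kl", "l1", "l2")) {
  measure <- match.arg(measure)
  stopifnot(inherits(cs, "condition_set"))
  N <- length(cs$priors)
  K <- as.integer(K)
  if (K < 1L || K > N) stop(sprintf("K must be between 1 and N = %d", N))

  # cost[i, j]: weighted distortion of merging conditions i..j into one bin
  cost <- matrix(0, N, N)
  reps <- vector("list", N)  # representatives for segments starting at i
  for (i in seq_len(N)) {
    for (j in i:N) {
      w <- cs$priors[i:j]
      Q <- colSums(cs$conditionals[i:j, , drop = FALSE] * w)
      sw <- sum(Q)
      Q <- if (sw > 0) Q / sw else rep(1 / ncol(cs$conditionals), ncol(cs$conditionals))
      cost[i, j] <- sum(vapply(i:j, function(t) {
        cs$priors[t] * distortion(cs$conditionals[t, ], Q, measure)
      }, numeric(1)))
    }
  }

  # dp[k, j]: best objective for conditions 1..j in k bins
  dp <- matrix(Inf, K, N)
  back <- matrix(NA_integer_, K, N)
  dp[1L, ] <- cost[1L, ]
  if (K > 1L) {
    for (k in 2L:K) {
      for (j in k:N) {
        best <- Inf; arg <- NA_integer_
        for (i in k:j) {  # bin k = i..j
          v <- dp[k - 1L, i - 1L] + cost[i, j]
          if (v < best - 1e-15) { best <- v; arg <- i }
        }
        dp[k, j] <- best
        back[k, j] <- arg
      }
    }
  }

  bins <- vector("list", K)
  j <- N
  for (k in K:1L) {
    i <- if (k == 1L) 1L else back[k, j]
    bins[[k]] <- i:j
    j <- i - 1L
  }
  representatives <- t(vapply(bins, function(ix) {
    w <- cs$priors[ix]
    Q <- colSums(cs$conditionals[ix, , drop = FALSE] * w)
    sw <- sum(Q)
    if (sw > 0) Q / sw else rep(1 / ncol(cs$conditionals), ncol(cs$conditionals))
  }, numeric(ncol(cs$conditionals))))

  structure(list(bins = bins,
                 boundaries = vapply(bins, max, integer(1)),
                 representatives = representatives,
                 L = dp[K, N], K = K, measure = measure,
                 labels = cs$labels),
            class = "condition_partition")
}

#' @export
print.condition_partition <- function(x, ...) {
  cat(sprintf("condition_partition: K = %d bins, L = %.6g (%s)\n",
              x$K, x$L, x$measure))
  for (k in seq_along(x$bins)) {
    cat(sprintf("  bin %d: conditions %s\n", k,
                paste(x$labels[x$bins[[k]]], collapse = ", ")))
  }
  invisible(x)
}

#' Conditional entropies before and after context quantization
#'
#' Computes H(X | M) over the original conditioning states and H(X | Q) over
#' the partitioned (quantized) states. Merging states can only lose
#' information, so `H(X|Q) >= H(X|M)`; the gap is the coding cost of the
#' quantization, to be weighed against the smaller model.
#'
#' @param cs A `condition_set`.
#' @param partition A `condition_partition` over `cs`.
#' @return Named numeric vector `c(H_XM = ..., H_XQ = ...)` in bits.
#' @export
entropy_gap <- function(cs, partition) {
  stopifnot(inherits(cs, "condition_set"), inherits(partition, "condition_partition"))
  joint_m <- cs$conditionals * cs$priors
  H_XM <- conditional_entropy(joint_m)
  joint_q <- t(vapply(partition$bins, function(ix) {
    colSums(joint_m[ix, , drop = FALSE])
  }, numeric(ncol(cs$conditionals))))
  H_XQ <- conditional_entropy(joint_q)
  c(H_XM = H_XM, H_XQ = H_XQ)
}
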