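#' Configuration for the synthetic FASTQ generator
#'
#' The generator emulates the statistical structure of Illumina-style
#' quality tracks that the compound context model exploits, with each
#' feature switchable independently:
#' \itemize{
#'   \item per-cycle mean decreasing and variance increasing with cycle
#'     number (`mean_slope`, `noise_sd_slope`) — what the serpentine scan
#'     rides on;
#'   \item a 2D-correlated noise texture: AR(1) along the read (`ar1_rho`)
#'     and AR(1) across neighbouring reads in file order (`cross_read_rho`),
#'     a separable Gauss-Markov field — within-read correlation is what the
#'     previous-quality context captures, across-read correlation is what
#'     the serpentine scan rides on (neighbouring records come from
#'     neighbouring clusters, so their quality curves nearly coincide);
#'   \item a per-read quality-level offset (`read_level_sd`), smooth across
#'     neighbouring reads in file order (`read_level_rho`) the way
#'     neighbouring flowcell clusters are — what the row-mean context and the
#'     vertical (serpentine) scan capture;
#'   \item quality dips at base changes (`base_change_dip`, `dip_prob`) —
#'     what the second-order base context captures.
#' }
#' Quality values are rounded and clipped to `[0, q_max]` (41 by default,
#' the usual Illumina ceiling).
#'
#' @param n_reads Number of reads.
#' @param read_len Read length: scalar, or vector of per-read lengths.
#' @param seed RNG seed; generation is deterministic given the config.
#' @param mean_start Mean Phred at cycle 0.
#' @param mean_slope Phred change per cycle (negative: quality decays).
#' @param noise_sd_start Marginal standard deviation of the noise field at
#'   cycle 0.
#' @param noise_sd_slope Increase of the marginal noise sd per cycle.
#' @param ar1_rho Lag-1 correlation of the noise along the read (cycles).
#' @param cross_read_rho Lag-1 correlation of the noise across reads at the
#'   same cycle (0 = independent reads).
#' @param read_level_sd Standard deviation of the per-read mean offset.
#' @param read_level_rho AR(1) coefficient of the per-read offset across
#'   file order (adjacent records come from nearby clusters, so their
#'   quality levels are similar; 0 = independent reads).
#' @param base_change_dip Phred drop applied at a dipped base change.
#' @param dip_prob Probability that a base change triggers a dip.
#' @param q_max Quality ceiling.
#' @param preset `"paper-like"` (all structure on, the defaults),
#'   `"iid"` (memoryless: no trend, no correlation, no dips, no read
#'   offsets) or `"dips-only"` (base-change dips as the only structure).
#' @return A `synth_config` object (a list of the above).
#' @export
synth_config <- function(n_reads = 20000L, read_len = 100L, seed = 1L,
                         mean_start = 38, mean_slope = -0.05,
                         noise_sd_start = 2.0, noise_sd_slope = 0.02,
                         ar1_rho = 0.8, cross_read_rho = 0.9,
                         read_level_sd = 2.5, read_level_rho = 0.9,
                         base_change_dip = 4, dip_prob = 0.05,
                         q_max = 41L,
                         preset = c("paper-like", "iid", "dips-only")) {
  preset <- match.arg(preset)
  cfg <- list(n_reads = as.integer(n_reads), read_len = read_len,
              seed = as.integer(seed), mean_start = mean_start,
              mean_slope = mean_slope, noise_sd_start = noise_sd_start,
              noise_sd_slope = noise_sd_slope, ar1_rho = ar1_rho,
              cross_read_rho = cross_read_rho,
              read_level_sd = read_level_sd, read_level_rho = read_level_rho,
              base_change_dip = base_change_dip, dip_prob = dip_prob,
              q_max = as.integer(q_max), preset = preset)
  if (preset == "iid") {
    cfg$mean_slope <- 0
    cfg$noise_sd_slope <- 0
    cfg$ar1_rho <- 0
    cfg$cross_read_rho <- 0
    cfg$read_level_sd <- 0
    cfg$read_level_rho <- 0
    cfg$dip_prob <- 0
  } else if (preset == "dips-only") {
    cfg$mean_slope <- 0
    cfg$noise_sd_slope <- 0
    cfg$ar1_rho <- 0
    cfg$cross_read_rho <- 0
    cfg$read_level_sd <- 0
    cfg$read_level_rho <- 0
    cfg$dip_prob <- 1
  }
  stopifnot(all(vapply(cfg[sapply(cfg, is.numeric)],
                       function(v) all(is.finite(v)), logical(1))),
            cfg$n_reads >= 0L, all(cfg$read_len >= 0),
            cfg$dip_prob >= 0, cfg$dip_prob <= 1, cfg$q_max >= 1L)
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("synth_config (%s): %d reads x %s cycles, seed %d\n",
              x$preset, x$n_reads, paste(range(x$read_len), collapse = "-"),
              x$seed))
  invisible(x)
}

#' Generate a synthetic FASTQ file
#'
#' Draws reads under the model described in [synth_config()]: quality at
#' read r, cycle c is
#' `clip(round(mean_start + mean_slope * c + u_r + e_rc - dip_rc))` with
#' `u_r` the per-read offset, `e_rc` an AR(1) noise process along the read
#' whose innovation sd grows with c, and `dip_rc` the base-change dip.
#' Bases are i.i.d. uniform over ACGT. The caller's RNG state is left
#' untouched.
#'
#' @param config A `synth_config`.
#' @param file Optional path: write the FASTQ there as well.
#' @return A `fastq` object.
#' @examples
#' fq <- generate_fastq(synth_config(n_reads = 5, read_len = 20, seed = 42))
#' @export
generate_fastq <- function(config = synth_config(), file = NULL) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)

  n <- config$n_reads
  lens <- rep_len(as.integer(config$read_len), max(n, 0L))
  if (n == 0L) {
    fq <- new_fastq(character(), character(), character())
    if (!is.null(file)) write_fastq(fq, file)
    return(fq)
  }
  L <- max(lens, 1L)

  base_idx <- matrix(sample.int(4L, n * L, replace = TRUE), n, L)
  # per-read level: stationary AR(1) across file order
  u <- numeric(n)
  if (config$read_level_sd > 0) {
    rr <- config$read_level_rho
    u[1L] <- rnorm(1L, 0, config$read_level_sd)
    if (n > 1L) {
      innov <- rnorm(n - 1L, 0, config$read_level_sd * sqrt(1 - rr^2))
      for (r in 2:n) u[r] <- rr * u[r - 1L] + innov[r - 1L]
    }
  }
  # separable 2D Gauss-Markov noise field: AR(1) along cycles with marginal
  # sd sd_c, then AR(1) smoothing across reads (variance-preserving)
  e <- matrix(0, n, L)
  sd_c <- pmax(config$noise_sd_start + config$noise_sd_slope * (0:(L - 1L)), 0)
  rho <- config$ar1_rho
  e[, 1L] <- rnorm(n, 0, sd_c[1L])
  if (L > 1L) {
    for (cc in 2:L) {
      scale <- rho * sd_c[cc] / max(sd_c[cc - 1L], 1e-12)
      innov_sd <- sd_c[cc] * sqrt(max(1 - rho^2, 0))
      e[, cc] <- scale * e[, cc - 1L] + rnorm(n, 0, innov_sd)
    }
  }
  rv <- config$cross_read_rho
  if (rv != 0 && n > 1L) {
    w <- sqrt(max(1 - rv^2, 0))
    for (r in 2:n) e[r, ] <- rv * e[r - 1L, ] + w * e[r, ]
  }
  dip <- matrix(0, n, L)
  if (L > 1L && config$base_change_dip != 0 && config$dip_prob > 0) {
    change <- base_idx[, -1L, drop = FALSE] != base_idx[, -L, drop = FALSE]
    draw <- matrix(runif(n * (L - 1L)) < config$dip_prob, n, L - 1L)
    dip[, -1L] <- (change & draw) * config$base_change_dip
  }
  mu <- matrix(config$mean_start + config$mean_slope * (0:(L - 1L)),
               n, L, byrow = TRUE)
  q <- round(mu + u + e - dip)
  q <- pmin(pmax(q, 0L), config$q_max)

  letters4 <- c("A", "C", "G", "T")
  base_rows <- apply(base_idx, 1L, function(i) paste(letters4[i], collapse = ""))
  qual_rows <- apply(q, 1L, function(v) intToUtf8(v + 33L))
  bases <- substr(base_rows, 1L, lens)
  qual <- substr(qual_rows, 1L, lens)
  fq <- new_fastq(sprintf("@synth_%d", seq_len(n)), bases, qual)
  if (!is.null(file)) write_fastq(fq, file)
  fq
}
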