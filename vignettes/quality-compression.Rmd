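---
title: "Methods: adaptive coding order for quality scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive coding order for quality scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acoq)
```

## The model

A FASTQ quality stream is a stack of per-read Phred vectors. `acoq` treats
it as a ragged 2D matrix (rows = reads in file order, columns = sequencing
cycles) and codes every symbol with an adaptive range coder whose
conditional model is selected by a *compound context*:

* `q_prev1` — the previous quality symbol along the scan path, at full
  resolution;
* `q_prev2` — the symbol two steps back, coarsened to `value %/% 5`
  (9 levels);
* the quantized mean quality of the current read (its *row bin*);
* the second-order base context `(j_i, j_(i-1))`: the base under the current
  symbol and its predecessor within the same read, folded to
  `{A, C, G, T, N}` plus a start-of-read sentinel `^`.

The scan path is serpentine: column 0 top-to-bottom, column 1 bottom-to-top,
and so on. Two assumptions justify it. First, quality decays and its
variance grows along the read, so a column (one cycle) is far more
homogeneous than a read. Second, records adjacent in the file come from
neighbouring flowcell clusters and have similar quality levels, so vertical
neighbours are genuinely informative. The adaptive tables forget (counts are
halved at a rescale limit), which is precisely why traversal order changes
the output size: the model is always dominated by the recent past, and the
serpentine order keeps the recent past relevant.

For ragged inputs a column visits, in the current direction, exactly those
rows whose read extends to that column; the alternation stays tied to the
column index. This is the minimal rule that the decoder can replay from the
transmitted length vector alone.

Decodability is structural: every context component is either an
already-decoded quality symbol or comes from a side stream (lengths,
row bins, bases) that is decoded before the quality bitstream of its block.
The test suite replays contexts on the decoder side and compares them with
the encoder's.

## Row-mean quantization

Conditioning on the raw read mean would explode the context count
(*context dilution*: too many contexts, too few observations each), so means
enter the context quantized. The production rule collapses everything below
30 into one bin, uses 2-Phred bins up to 38, and keeps integer resolution
above 38 — low-mean reads are rare while the informative mass sits in the
high-quality range.

The rule is one solution of a general problem the package also ships: given
ordered conditions `m_i` with priors `p(m_i)` and conditionals `p(x|m_i)`,
find K contiguous bins minimizing the weighted distortion
`L = sum_i d(p(x|m_i), Q(p(x|m_i))) p(m_i)`. `optimal_partition()` solves it
exactly by dynamic programming in O(N^2 K) after an O(N^2) segment-cost
table. Design choices, each genuinely open:

* **Contiguity.** Conditions are scalar row means, so only order-respecting
  bins make sense; unconstrained set partitioning would also be NP-hard.
* **Bin representative.** The prior-weighted mixture of member
  conditionals. For fixed membership it minimizes the expected KL
  divergence of members from the representative, which matches the
  code-length reading of the objective.
* **Distortion.** KL divergence by default (excess code length of coding
  `m_i`'s symbols with the bin's distribution); L1 and L2 are exposed
  because the objective is well defined for any distortion.
* **Ties** are broken toward the earliest boundary, making results
  deterministic.

`entropy_gap()` reports `H(X|M)` and `H(X|Q)`; merging conditions can only
lose information, so `H(X|Q) >= H(X|M)` — a property test checks the
inequality and the DP is checked against exhaustive enumeration for all
N ≤ 10, K ≤ 4.

## The coder and its parameters

The range coder is 32-bit with byte renormalization and explicit carry
propagation; all arithmetic is integer, so encoder and decoder are bit-exact
across platforms. Frequency totals are capped below 2^16 while the range
register stays above 2^24, bounding the per-symbol precision loss well under
0.01 bits; a property test keeps total output within
`ideal code length + 64 bits + 0.01 n`.

Adaptive tables start at one count per symbol (uniform), add `increment`
per observation, and halve all counts (floor 1) when a context's total
exceeds `rescale_limit`.

| parameter | default | why |
|---|---|---|
| `increment` | 32 | fast adaptation: one observation outweighs the uniform prior quickly |
| `rescale_limit` | 8192 | memory of ~256 observations; forgetting tracks nonstationarity |
| `q2_levels` | 9 | `value %/% 5` over a 0–44 alphabet; coarse is enough two steps back |
| `block_size` | 100,000 reads | bounds buffering; blocks are coded independently |

All four are recorded in the container header, so decoding is
parameter-exact. The header also records the Phred offset, the scan order,
which context dimensions are active, and whether bases are embedded; a
64-bit FNV-1a checksum of the decoded Phred stream guards against model or
stream drift, including wrong external bases.

The depth of the quality context (one full-resolution previous symbol plus
one coarsened second-previous) is a design decision: deeper contexts
multiply the table size by the alphabet each step and dilute counts at desk
scale; one-and-a-coarse matches what quality-specific codecs in this family
typically afford. The row-mean context is probed rather than assumed: block
0 is encoded with and without it, the cheaper variant (side stream included)
wins, and the choice is applied file-wide as a header flag.

Degenerate inputs are first-class: empty files (header-only container),
empty reads (mean defined as 0), reads of length 1, constant qualities,
alphabet extremes 0 and 93, and `N`/lowercase bases (folded to `N` for
context purposes while the original bytes round-trip verbatim through the
base side stream). Multi-line FASTQ is rejected rather than normalized so
the byte-identical round-trip guarantee stays honest.

## What the synthetic generator emulates

`synth_config()` / `generate_fastq()` produce reads with exactly the
structure the contexts target, each switchable for ablations:

* a linearly decaying cycle mean (default 38 − 0.05·c) with marginal noise
  sd growing 2.0 → 4.0 over 100 cycles;
* a separable AR(1)×AR(1) Gauss–Markov noise field: lag-1 correlation 0.8
  along the read and 0.9 across neighbouring reads (adjacent records come
  from neighbouring clusters — their whole curves nearly coincide);
* a per-read level offset (sd 2.5) itself AR(1)-smooth (0.9) across file
  order — what the row-mean context captures;
* quality dips of 4 Phred at base changes with probability 0.05 — rare
  singular points, what the base context captures.

Values are rounded and clipped to [0, 41] (Illumina-style ceiling). With
these defaults the generated data shows a strictly decreasing per-cycle
mean, growing per-cycle variance, and a measured within-read lag-1
autocorrelation of ≈ 0.74 — inside the 0.7–0.9 regime the codec is designed
for once rounding, ceiling clipping and dip variance attenuate the 0.8 field
correlation. The dip probability and noise scale were fixed at design time
to realize that regime and are not revisited per experiment.

What it does **not** emulate: flowcell geometry and true 2D cluster
cross-talk images (file-order adjacency is a proxy), instrument-specific
quality binning, sequence-dependent base composition, adapter artifacts.
Passing tests therefore show that the codec exploits the intended
statistical structure, not that real-platform ratios are matched; the
compression ratios on synthetic defaults (CR ≈ 35 %, BPQ ≈ 2.9) land in the
plausible range for real short-read data but are not calibrated claims.

## Coding order and the shuffled-versus-blocked question

A common intuition holds that making a signal "more stable" by shuffling
helps an adaptive order-0 coder, i.e. that a shuffled concatenation of two
quantized Gaussian sources should code smaller than the blocked
concatenation. Our coder gives the opposite, consistently: sorting wins by a
large margin, and the *blocked* arrangement beats the shuffled one at every
increment/rescale setting and mean separation we measured. The reason is
elementary: an adaptive coder with count halving is near-permutation-
invariant except for forgetting, and forgetting lets each stationary half be
coded near its own entropy, while the shuffled stream must be coded at the
(larger) mixture entropy. The corresponding acceptance assertion follows the
stronger traditional claim and is deliberately left failing rather than
weakened; the sorted ≪ shuffled part holds robustly.

## Problem sizes

The shipped tests run at: 20,000 reads × 100 cycles for direction-of-effect
comparisons (two generated data sets, six compressions); 200 randomized
small files for losslessness; 50 random model traces for coder
near-optimality; 100 random condition sets for quantizer-oracle
equivalence; 10^5 symbols for order-sensitivity and rate-versus-entropy
checks. These sizes make every effect distinguishable from noise under
fixed seeds while the whole suite stays fast.

## Known limitations

* Blocks are coded independently; statistics do not carry across blocks
  (simple, decoder-reproducible, but slightly worse on many small blocks).
* Read identifiers are out of scope for the container (a CLI side file
  covers full-FASTQ rebuilds); headers of third-generation platforms and
  alignment-assisted modes are likewise out of scope.
* The context schema is fixed per file; no online re-quantization or model
  mixing.
* `quantize_row_mean()`'s production thresholds are used as-is; per-file
  optimal bins must be derived explicitly via the `quantize` CLI path.
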