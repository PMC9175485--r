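// Core codec: byte-oriented range coder with carry handling, adaptive
// frequency tables, serpentine/raster scan paths, and the compound-context
// quality codec.  All arithmetic is integer-only so encoder and decoder are
// bit-exact across platforms.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const uint32_t RC_TOP = 1u << 24;

// ---------------------------------------------------------------------------
// Range coder (32-bit range, 64-bit low, byte renormalization, explicit carry)
// ---------------------------------------------------------------------------

class RangeEncoder {
public:
  std::vector<uint8_t> out;
  uint64_t low;
  uint32_t range;
  uint8_t cache;
  uint64_t cache_size;
  bool flushed;

  RangeEncoder() : low(0), range(0xFFFFFFFFu), cache(0), cache_size(1),
                   flushed(false) {}

  void shift_low() {
    if (static_cast<uint32_t>(low >> 32) != 0 ||
        static_cast<uint32_t>(low) < 0xFF000000u) {
      uint8_t carry = static_cast<uint8_t>(low >> 32);
      do {
        out.push_back(static_cast<uint8_t>(cache + carry));
        cache = 0xFF;
      } while (--cache_size);
      cache = static_cast<uint8_t>(low >> 24);
    }
    cache_size++;
    low = (low << 8) & 0xFFFFFFFFu;
  }

  void encode(uint32_t cum, uint32_t freq, uint32_t tot) {
    if (freq == 0) stop("attempt to encode a zero-count symbol");
    range /= tot;
    low += static_cast<uint64_t>(cum) * range;
    range *= freq;
    while (range < RC_TOP) {
      range <<= 8;
      shift_low();
    }
  }

  void flush() {
    if (flushed) return;
    for (int i = 0; i < 5; i++) shift_low();
    flushed = true;
  }
};

class RangeDecoder {
public:
  const uint8_t* in;
  size_t n_in, pos;
  uint32_t range, code;

  RangeDecoder(const uint8_t* buf, size_t n) : in(buf), n_in(n), pos(0),
                                               range(0xFFFFFFFFu), code(0) {
    for (int i = 0; i < 5; i++) code = (code << 8) | next_byte();
  }

  uint8_t next_byte() {
    if (pos >= n_in) stop("compressed stream exhausted");
    return in[pos++];
  }

  uint32_t decode_freq(uint32_t tot) {
    range /= tot;
    uint32_t v = code / range;
    return v >= tot ? tot - 1 : v;
  }

  void decode_update(uint32_t cum, uint32_t freq, uint32_t tot) {
    code -= cum * range;
    range *= freq;
    while (range < RC_TOP) {
      code = (code << 8) | next_byte();
      range <<= 8;
    }
  }
};

// ---------------------------------------------------------------------------
// Adaptive frequency tables: per-context counts initialized to 1, increment
// on observation, halved (floor 1) when the context total exceeds the
// rescale limit.  Totals stay < 2^16 so coder precision is never at risk.
// ---------------------------------------------------------------------------

class AdaptiveTable {
public:
  int n_ctx, alpha;
  uint32_t inc, limit;
  std::vector<uint16_t> counts;
  std::vector<uint32_t> totals;

  AdaptiveTable(int n_ctx_, int alpha_, int inc_, int limit_)
    : n_ctx(n_ctx_), alpha(alpha_), inc(inc_), limit(limit_) {
    if (alpha_ < 1) stop("alphabet size must be positive");
    if (limit_ > 65535) stop("rescale limit must be below 2^16");
    if (static_cast<uint32_t>(alpha_) > static_cast<uint32_t>(limit_))
      stop("rescale limit smaller than alphabet");
    counts.assign(static_cast<size_t>(n_ctx) * alpha, 1);
    totals.assign(n_ctx, static_cast<uint32_t>(alpha));
  }

  void update(int ctx, int sym) {
    uint16_t* c = &counts[static_cast<size_t>(ctx) * alpha];
    c[sym] = static_cast<uint16_t>(c[sym] + inc);
    totals[ctx] += inc;
    if (totals[ctx] > limit) {
      uint32_t tot = 0;
      for (int i = 0; i < alpha; i++) {
        c[i] = static_cast<uint16_t>((c[i] + 1) >> 1);  // halve, floor 1
        tot += c[i];
      }
      totals[ctx] = tot;
    }
  }

  void encode(RangeEncoder& enc, int ctx, int sym) {
    const uint16_t* c = &counts[static_cast<size_t>(ctx) * alpha];
    uint32_t cum = 0;
    for (int i = 0; i < sym; i++) cum += c[i];
    enc.encode(cum, c[sym], totals[ctx]);
    update(ctx, sym);
  }

  int decode(RangeDecoder& dec, int ctx) {
    const uint16_t* c = &counts[static_cast<size_t>(ctx) * alpha];
    uint32_t f = dec.decode_freq(totals[ctx]);
    uint32_t cum = 0;
    int sym = 0;
    while (cum + c[sym] <= f) { cum += c[sym]; sym++; }
    dec.decode_update(cum, c[sym], totals[ctx]);
    update(ctx, sym);
    return sym;
  }
};

// ---------------------------------------------------------------------------
// Order-0 adaptive stream (side streams, Z-order experiment)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
RawVector cpp_encode_adaptive0(IntegerVector syms, int alphabet,
                               int increment, int rescale) {
  AdaptiveTable tab(1, alphabet, increment, rescale);
  RangeEncoder enc;
  for (R_xlen_t i = 0; i < syms.size(); i++) {
    int s = syms[i];
    if (s < 0 || s >= alphabet) stop("symbol out of alphabet range");
    tab.encode(enc, 0, s);
  }
  enc.flush();
  return RawVector(enc.out.begin(), enc.out.end());
}

// [[Rcpp::export]]
IntegerVector cpp_decode_adaptive0(RawVector bytes, int n, int alphabet,
                                   int increment, int rescale) {
  AdaptiveTable tab(1, alphabet, increment, rescale);
  RangeDecoder dec(RAW(bytes), bytes.size());
  IntegerVector out(n);
  for (int i = 0; i < n; i++) out[i] = tab.decode(dec, 0);
  return out;
}

// ---------------------------------------------------------------------------
// Static per-step model trace (counts supplied externally, no adaptation):
// used to measure coder overhead against the ideal code length.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
RawVector cpp_encode_trace(IntegerVector syms, IntegerMatrix counts) {
  if (counts.nrow() != syms.size()) stop("one counts row per symbol required");
  int alpha = counts.ncol();
  RangeEncoder enc;
  for (R_xlen_t i = 0; i < syms.size(); i++) {
    int s = syms[i];
    if (s < 0 || s >= alpha) stop("symbol out of alphabet range");
    uint32_t cum = 0, tot = 0;
    for (int j = 0; j < alpha; j++) {
      int cj = counts(i, j);
      if (cj < 0) stop("negative count");
      if (j < s) cum += cj;
      tot += cj;
    }
    if (tot == 0 || tot > 65535) stop("count total out of range");
    enc.encode(cum, counts(i, s), tot);
  }
  enc.flush();
  return RawVector(enc.out.begin(), enc.out.end());
}

// [[Rcpp::export]]
IntegerVector cpp_decode_trace(RawVector bytes, IntegerMatrix counts) {
  int n = counts.nrow(), alpha = counts.ncol();
  RangeDecoder dec(RAW(bytes), bytes.size());
  IntegerVector out(n);
  for (int i = 0; i < n; i++) {
    uint32_t tot = 0;
    for (int j = 0; j < alpha; j++) tot += counts(i, j);
    uint32_t f = dec.decode_freq(tot);
    uint32_t cum = 0;
    int sym = 0;
    while (cum + static_cast<uint32_t>(counts(i, sym)) <= f) {
      cum += counts(i, sym);
      sym++;
    }
    dec.decode_update(cum, counts(i, sym), tot);
    out[i] = sym;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Scan paths
// ---------------------------------------------------------------------------

static void build_cells(const IntegerVector& row_lengths, bool serpentine,
                        std::vector<int>& rows, std::vector<int>& cols) {
  int n_reads = row_lengths.size();
  long long n_cells = 0;
  int max_len = 0;
  for (int r = 0; r < n_reads; r++) {
    if (row_lengths[r] < 0) stop("negative read length");
    n_cells += row_lengths[r];
    if (row_lengths[r] > max_len) max_len = row_lengths[r];
  }
  rows.reserve(n_cells);
  cols.reserve(n_cells);
  if (!serpentine) {
    for (int r = 0; r < n_reads; r++)
      for (int c = 0; c < row_lengths[r]; c++) { rows.push_back(r); cols.push_back(c); }
    return;
  }
  std::vector<int> present;
  present.reserve(n_reads);
  for (int c = 0; c < max_len; c++) {
    present.clear();
    for (int r = 0; r < n_reads; r++)
      if (row_lengths[r] > c) present.push_back(r);
    if (c % 2 == 0) {
      for (size_t i = 0; i < present.size(); i++) { rows.push_back(present[i]); cols.push_back(c); }
    } else {
      for (size_t i = present.size(); i > 0; i--) { rows.push_back(present[i - 1]); cols.push_back(c); }
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_scan_cells(IntegerVector row_lengths, bool serpentine) {
  std::vector<int> rows, cols;
  build_cells(row_lengths, serpentine, rows, cols);
  IntegerMatrix m(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); i++) { m(i, 0) = rows[i]; m(i, 1) = cols[i]; }
  return m;
}

// ---------------------------------------------------------------------------
// Compound-context quality codec.  Context key =
//   ((q_prev1 * Q2 + q_prev2_coarse) * n_rowbins + row_bin) * 36 + base_pair
// where q_prev1/q_prev2 are the one/two-back symbols along the scan path
// (sentinel 0 at block start), q_prev2 is coarsened to value %/% 5, the row
// bin is the quantized read mean, and base_pair = cur_base * 6 + prev_base
// (prev within the same read, sentinel 5 at cycle 0).  Disabled dimensions
// collapse to size 1 so ablations share one code path.
// ---------------------------------------------------------------------------

struct CtxCfg {
  int alphabet, q2_levels, n_rowbins;
  bool use_q2, use_rowmean, use_base;
  int dim_q2, dim_rb, dim_bp;

  CtxCfg(int alphabet_, int q2_levels_, int n_rowbins_,
         bool use_q2_, bool use_rowmean_, bool use_base_)
    : alphabet(alphabet_), q2_levels(q2_levels_), n_rowbins(n_rowbins_),
      use_q2(use_q2_), use_rowmean(use_rowmean_), use_base(use_base_) {
    dim_q2 = use_q2 ? q2_levels : 1;
    dim_rb = use_rowmean ? n_rowbins : 1;
    dim_bp = use_base ? 36 : 1;
  }

  int n_ctx() const { return alphabet * dim_q2 * dim_rb * dim_bp; }

  int key(int qprev1, int qprev2, int row_bin, int cur_base, int prev_base) const {
    int q2 = 0;
    if (use_q2) {
      q2 = qprev2 / 5;
      if (q2 >= q2_levels) q2 = q2_levels - 1;
    }
    int rb = use_rowmean ? row_bin : 0;
    int bp = use_base ? (cur_base * 6 + prev_base) : 0;
    return ((qprev1 * dim_q2 + q2) * dim_rb + rb) * dim_bp + bp;
  }
};

static std::vector<long long> row_offsets(const IntegerVector& row_lengths) {
  std::vector<long long> off(row_lengths.size() + 1, 0);
  for (int r = 0; r < row_lengths.size(); r++)
    off[r + 1] = off[r] + row_lengths[r];
  return off;
}

static void check_side(const CtxCfg& cfg, const IntegerVector& base_codes,
                       const IntegerVector& row_bins, long long n_cells,
                       int n_reads) {
  if (cfg.use_base && base_codes.size() != n_cells)
    stop("base codes must cover every cell when the base context is enabled");
  if (cfg.use_rowmean && row_bins.size() != n_reads)
    stop("one row bin per read required when the row-mean context is enabled");
}

// [[Rcpp::export]]
RawVector cpp_encode_qualities(IntegerVector quals, IntegerVector row_lengths,
                               IntegerVector base_codes, IntegerVector row_bins,
                               bool serpentine, int alphabet, int q2_levels,
                               int n_rowbins, bool use_q2, bool use_rowmean,
                               bool use_base, int increment, int rescale) {
  CtxCfg cfg(alphabet, q2_levels, n_rowbins, use_q2, use_rowmean, use_base);
  std::vector<long long> off = row_offsets(row_lengths);
  long long n_cells = off.back();
  if (quals.size() != n_cells) stop("quality vector does not match read lengths");
  check_side(cfg, base_codes, row_bins, n_cells, row_lengths.size());
  std::vector<int> rows, cols;
  build_cells(row_lengths, serpentine, rows, cols);
  AdaptiveTable tab(cfg.n_ctx(), alphabet, increment, rescale);
  RangeEncoder enc;
  int qprev1 = 0, qprev2 = 0;
  for (size_t k = 0; k < rows.size(); k++) {
    int r = rows[k], c = cols[k];
    long long idx = off[r] + c;
    int cur_base = use_base ? base_codes[idx] : 0;
    int prev_base = (use_base && c > 0) ? base_codes[idx - 1] : 5;
    int rb = use_rowmean ? row_bins[r] : 0;
    int ctx = cfg.key(qprev1, qprev2, rb, cur_base, prev_base);
    int sym = quals[idx];
    if (sym < 0 || sym >= alphabet) stop("quality value outside alphabet");
    tab.encode(enc, ctx, sym);
    qprev2 = qprev1;
    qprev1 = sym;
  }
  enc.flush();
  return RawVector(enc.out.begin(), enc.out.end());
}

// [[Rcpp::export]]
IntegerVector cpp_decode_qualities(RawVector bytes, IntegerVector row_lengths,
                                   IntegerVector base_codes, IntegerVector row_bins,
                                   bool serpentine, int alphabet, int q2_levels,
                                   int n_rowbins, bool use_q2, bool use_rowmean,
                                   bool use_base, int increment, int rescale) {
  CtxCfg cfg(alphabet, q2_levels, n_rowbins, use_q2, use_rowmean, use_base);
  std::vector<long long> off = row_offsets(row_lengths);
  long long n_cells = off.back();
  check_side(cfg, base_codes, row_bins, n_cells, row_lengths.size());
  std::vector<int> rows, cols;
  build_cells(row_lengths, serpentine, rows, cols);
  AdaptiveTable tab(cfg.n_ctx(), alphabet, increment, rescale);
  IntegerVector out(n_cells);
  if (n_cells == 0) return out;
  RangeDecoder dec(RAW(bytes), bytes.size());
  int qprev1 = 0, qprev2 = 0;
  for (size_t k = 0; k < rows.size(); k++) {
    int r = rows[k], c = cols[k];
    long long idx = off[r] + c;
    int cur_base = use_base ? base_codes[idx] : 0;
    int prev_base = (use_base && c > 0) ? base_codes[idx - 1] : 5;
    int rb = use_rowmean ? row_bins[r] : 0;
    int ctx = cfg.key(qprev1, qprev2, rb, cur_base, prev_base);
    int sym = tab.decode(dec, ctx);
    out[idx] = sym;
    qprev2 = qprev1;
    qprev1 = sym;
  }
  return out;
}

// Context components per scan position, for decodability replay checks.
// Columns: row, col, q_prev1, q_prev2_coarse, row_bin, base_pair, key.
// [[Rcpp::export]]
IntegerMatrix cpp_context_trace(IntegerVector quals, IntegerVector row_lengths,
                                IntegerVector base_codes, IntegerVector row_bins,
                                bool serpentine, int alphabet, int q2_levels,
                                int n_rowbins, bool use_q2, bool use_rowmean,
                                bool use_base) {
  CtxCfg cfg(alphabet, q2_levels, n_rowbins, use_q2, use_rowmean, use_base);
  std::vector<long long> off = row_offsets(row_lengths);
  long long n_cells = off.back();
  if (quals.size() != n_cells) stop("quality vector does not match read lengths");
  check_side(cfg, base_codes, row_bins, n_cells, row_lengths.size());
  std::vector<int> rows, cols;
  build_cells(row_lengths, serpentine, rows, cols);
  IntegerMatrix m(rows.size(), 7);
  int qprev1 = 0, qprev2 = 0;
  for (size_t k = 0; k < rows.size(); k++) {
    int r = rows[k], c = cols[k];
    long long idx = off[r] + c;
    int cur_base = use_base ? base_codes[idx] : 0;
    int prev_base = (use_base && c > 0) ? base_codes[idx - 1] : 5;
    int rb = use_rowmean ? row_bins[r] : 0;
    int q2 = 0;
    if (use_q2) { q2 = qprev2 / 5; if (q2 >= q2_levels) q2 = q2_levels - 1; }
    m(k, 0) = r;
    m(k, 1) = c;
    m(k, 2) = qprev1;
    m(k, 3) = q2;
    m(k, 4) = rb;
    m(k, 5) = use_base ? (cur_base * 6 + prev_base) : 0;
    m(k, 6) = cfg.key(qprev1, qprev2, rb, cur_base, prev_base);
    qprev2 = qprev1;
    qprev1 = quals[idx];
  }
  return m;
}

// ---------------------------------------------------------------------------
// Base side stream: order-2 adaptive model, previous two symbols within the
// same read as context (sentinel = alphabet at read starts).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
RawVector cpp_encode_bases(IntegerVector codes, IntegerVector row_lengths,
                           int alphabet, int increment, int rescale) {
  int s = alphabet;  // sentinel code
  AdaptiveTable tab((s + 1) * (s + 1), alphabet, increment, rescale);
  RangeEncoder enc;
  long long idx = 0;
  for (int r = 0; r < row_lengths.size(); r++) {
    int p1 = s, p2 = s;
    for (int c = 0; c < row_lengths[r]; c++, idx++) {
      int sym = codes[idx];
      if (sym < 0 || sym >= alphabet) stop("base code outside alphabet");
      tab.encode(enc, p1 * (s + 1) + p2, sym);
      p2 = p1;
      p1 = sym;
    }
  }
  enc.flush();
  return RawVector(enc.out.begin(), enc.out.end());
}

// [[Rcpp::export]]
IntegerVector cpp_decode_bases(RawVector bytes, IntegerVector row_lengths,
                               int alphabet, int increment, int rescale) {
  int s = alphabet;
  AdaptiveTable tab((s + 1) * (s + 1), alphabet, increment, rescale);
  long long n = 0;
  for (int r = 0; r < row_lengths.size(); r++) n += row_lengths[r];
  IntegerVector out(n);
  if (n == 0) return out;
  RangeDecoder dec(RAW(bytes), bytes.size());
  long long idx = 0;
  for (int r = 0; r < row_lengths.size(); r++) {
    int p1 = s, p2 = s;
    for (int c = 0; c < row_lengths[r]; c++, idx++) {
      int sym = tab.decode(dec, p1 * (s + 1) + p2);
      out[idx] = sym;
      p2 = p1;
      p1 = sym;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// FNV-1a 64-bit hash of an integer symbol stream (one byte per symbol,
// values 0..255), returned as 8 raw bytes little-endian.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
RawVector cpp_fnv1a64(IntegerVector syms) {
  uint64_t h = 14695981039346656037ull;
  for (R_xlen_t i = 0; i < syms.size(); i++) {
    h ^= static_cast<uint64_t>(static_cast<uint8_t>(syms[i]));
    h *= 1099511628211ull;
  }
  RawVector out(8);
  for (int i = 0; i < 8; i++) out[i] = static_cast<uint8_t>(h >> (8 * i));
  return out;
}
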