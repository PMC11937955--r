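#include "core.h"
#include <Rcpp.h>
#include <unordered_map>

using namespace Rcpp;

namespace {

using namespace ba;

// Stored state of one computed 64 x tcols tile, sufficient to reconstruct
// every interior H value during traceback: the H value at the tile's
// top-left corner, the entering vertical differences, the horizontal
// differences along the top row (packed 2 bits/column) and the vertical
// differences of every computed column (2 bits/cell).
struct TileTrace {
  int a, c, tcols;
  long long corner;
  uint64_t left_vp, left_vn;
  uint64_t top_hp, top_hn;
  std::vector<uint64_t> cvp, cvn;
  size_t bytes() const { return 80 + 16 * (size_t)tcols; }
};

struct RowState {
  uint64_t vp = ONES, vn = 0;
  long long corner = 0;
  bool valid = false;
};

struct SweepOut {
  bool reached = false;
  bool disconnected = false;
  long long score = SCORE_INF;
  long long tiles = 0;
  size_t trace_bytes = 0;
  std::vector<TileTrace> traces;
  std::unordered_map<long long, int> tindex;
  std::vector<long long> col_scores;  // H at the stop column, SCORE_INF outside
};

// Tile sweep over the DP-matrix, column of tiles by column of tiles.
//
// band_mode = false: score-bounded mode.  The active tile-row range per
//   column follows the admission test H + d_k <= limit (d_k = distance to
//   the target diagonal m - n, H read from the entry boundary of the
//   tile), never narrower than the tiles covering +-96 diagonals around
//   the target diagonal (3 tiles).
// band_mode = true: banded mode.  Tiles restricted to the diagonal set
//   {|d| <= limit and |d - (m-n)| <= limit}; with dyn_cutoff, in-band
//   tiles whose best entry-boundary score plus d_k exceeds the band are
//   skipped.
//
// Boundaries of tiles that were not computed are synthesized as +1-growth
// from the nearest known corner, which is always an upper bound on the
// true H; computed values are therefore upper bounds everywhere and exact
// on every cell of any optimal path that fits inside the admitted region.
void sweep(const std::string& P, const std::string& T, long long limit,
           bool band_mode, bool dyn_cutoff, long long stop_col,
           bool store_traces, bool want_col_scores, SweepOut& out) {
  const long long n = (long long)P.size(), m = (long long)T.size();
  const int AR = (int)((n + 63) / 64);
  const int AC = (int)((stop_col + 63) / 64);
  const long long mn = m - n;
  std::vector<PeqBlock> peq = build_peq(P);
  std::vector<RowState> st((size_t)AR);
  for (int a = 0; a < AR; ++a) {  // global left boundary: H(i, 0) = i
    st[(size_t)a].vp = ONES; st[(size_t)a].vn = 0;
    st[(size_t)a].corner = 64LL * a; st[(size_t)a].valid = true;
  }

  long long lo_d = 0, hi_d = 0;
  if (band_mode) {
    lo_d = std::max(-limit, mn - limit);
    hi_d = std::min(limit, mn + limit);
    if (lo_d > hi_d) { out.disconnected = true; return; }
  }

  int palo = 0, pahi = -1;  // processed range of the previous column
  std::vector<signed char> toph(64), both(64);
  // bottom-right corner values of the previous column's tiles: exact
  // H(64*(a+1), 64*c) anchors for rows entering along the diagonal
  std::vector<long long> pbr((size_t)AR, 0);
  std::vector<char> pbr_ok((size_t)AR, 0);
  std::vector<long long> nbr((size_t)AR, 0);
  std::vector<char> nbr_ok((size_t)AR, 0);

  for (int c = 0; c < AC; ++c) {
    long long j0 = 64LL * c;
    int tcols = (int)std::min<long long>(64, stop_col - j0);
    long long dbase = j0 - 0;  // 64c

    auto dlow = [&](int a) { return 64LL * c - 64LL * a - 63; };
    auto dhigh = [&](int a) { return 64LL * c - 64LL * a + tcols - 1; };
    auto straddle = [&](int a) { return dlow(a) <= mn && mn <= dhigh(a); };
    (void)dbase;

    int rlo, rhi;
    int flo = 0, fhi = AR - 1;
    if (band_mode) {
      rlo = (int)std::max(0LL, ceil_div64(64LL * c - 63 - hi_d));
      rhi = (int)std::min<long long>(AR - 1,
                                     floor_div64(64LL * c + tcols - 1 - lo_d));
      if (rlo > rhi) { out.disconnected = true; return; }
    } else {
      // minimum active band: the tile row(s) straddling the target
      // diagonal plus one row on each side, at most 3 tile rows (192
      // DP-elements) in total
      long long a_lo_str = ceil_div64(64LL * c - mn - 63);
      long long a_hi_str = floor_div64(64LL * c + tcols - 1 - mn);
      if (a_hi_str - a_lo_str + 1 >= 2) { flo = (int)a_lo_str; fhi = (int)(a_lo_str + 2); }
      else { flo = (int)(a_lo_str - 1); fhi = (int)(a_lo_str + 1); }
      flo = (int)std::min<long long>(std::max(0, flo), AR - 1);
      fhi = (int)std::min<long long>(std::max(0, fhi), AR - 1);
      if (fhi < flo) fhi = flo;
      // retract from the top while strictly-above tiles fail admission
      int a = palo;
      while (a < flo) {
        bool pass = false;
        if (st[(size_t)a].valid) {
          uint64_t lm = (a == AR - 1) ? row_mask((int)(n - 64LL * a)) : ONES;
          long long i_bl = std::min(64LL * a + 64, n);
          long long h_bl =
              st[(size_t)a].corner +
              delta_sum(st[(size_t)a].vp, st[(size_t)a].vn, lm);
          long long dk = llabs((j0 + 1 - i_bl) - mn);
          pass = (h_bl + dk <= limit);
        }
        if (pass) break;
        st[(size_t)a].valid = false;
        ++a;
      }
      rlo = a;
      rhi = AR - 1;  // actual bottom decided during extension
    }

    bool have_prev = false;
    long long prev_leftcorner = 0, prev_br = 0, prev_bl = 0;
    bool prev_br_known = false;
    bool prev_row_done = false;  // row a-1 produced bottom_h this column
    int done_lo = -1, done_hi = -2;

    for (int a = rlo; a <= rhi; ++a) {
      RowState& s = st[(size_t)a];
      long long leftcorner;
      if (s.valid) {
        leftcorner = s.corner;
      } else {
        // A row entering the active set: its corner must be consistent
        // with the top boundary it will receive.  If the row above was
        // computed this column, the corner is that row's exact bottom-left
        // value; otherwise fall back to +1-growth upper bounds.
        if (c == 0) leftcorner = 64LL * a;
        else if (a == 0) leftcorner = j0;
        else if (prev_row_done) leftcorner = prev_bl;
        else {
          leftcorner = 64LL * a + j0;  // H <= i + j, a sound generic bound
          if (have_prev) leftcorner = std::min(leftcorner, prev_leftcorner + 64);
          if (a > 0 && pbr_ok[(size_t)(a - 1)])
            leftcorner = std::min(leftcorner, pbr[(size_t)(a - 1)]);
        }
        s.vp = ONES; s.vn = 0;
      }
      uint64_t lm = (a == AR - 1) ? row_mask((int)(n - 64LL * a)) : ONES;
      long long bl_in = leftcorner + delta_sum(s.vp, s.vn, lm);

      bool skip = false;
      if (band_mode && dyn_cutoff && !straddle(a)) {
        long long v;
        if (dlow(a) > mn) {  // strictly above: bottom-left check
          long long i_bl = std::min(64LL * a + 64, n);
          v = bl_in + llabs((j0 + 1 - i_bl) - mn);
        } else {             // strictly below: upper-right check
          long long h_ur = prev_br_known ? prev_br : leftcorner + tcols;
          v = h_ur + llabs((j0 + tcols - (64LL * a + 1)) - mn);
        }
        skip = (v > limit);
      }

      if (skip) {
        s.valid = false;
        prev_br = bl_in + tcols;  // +1-growth synthetic, still an upper bound
        prev_br_known = true;
        if (64LL * (a + 1) <= n) {
          nbr[(size_t)a] = prev_br; nbr_ok[(size_t)a] = 1;
        }
        prev_leftcorner = leftcorner; have_prev = true;
        prev_row_done = false;
        continue;
      }

      // top boundary: bottom_h of the row above if computed this column,
      // otherwise the global border (+1) or a synthesized +1 boundary
      if (prev_row_done) {
        toph = both;
      } else {
        std::fill(toph.begin(), toph.begin() + tcols, (signed char)1);
      }

      uint64_t lvp = s.vp, lvn = s.vn;
      uint64_t* cvp_ptr = nullptr; uint64_t* cvn_ptr = nullptr;
      int ti = -1;
      if (store_traces) {
        out.traces.emplace_back();
        ti = (int)out.traces.size() - 1;
        TileTrace& tt = out.traces[(size_t)ti];
        tt.a = a; tt.c = c; tt.tcols = tcols; tt.corner = leftcorner;
        tt.left_vp = lvp; tt.left_vn = lvn;
        tt.cvp.resize((size_t)tcols); tt.cvn.resize((size_t)tcols);
        uint64_t hp = 0, hn = 0;
        for (int k = 0; k < tcols; ++k) {
          if (toph[(size_t)k] > 0) hp |= 1ULL << k;
          else if (toph[(size_t)k] < 0) hn |= 1ULL << k;
        }
        tt.top_hp = hp; tt.top_hn = hn;
        cvp_ptr = tt.cvp.data(); cvn_ptr = tt.cvn.data();
        out.tindex[(long long)a * AC + c] = ti;
        out.trace_bytes += tt.bytes();
      }

      int tsum = tile_pass(peq[(size_t)a].peq.data(),
                           (const unsigned char*)T.data() + j0, tcols, s.vp,
                           s.vn, toph.data(), both.data(), cvp_ptr, cvn_ptr);
      ++out.tiles;
      if (done_lo < 0) done_lo = a;
      done_hi = a;

      long long br = bl_in;
      for (int k = 0; k < tcols; ++k) br += both[(size_t)k];
      s.corner = leftcorner + tsum;
      s.valid = true;
      prev_leftcorner = leftcorner; have_prev = true;
      prev_br = br; prev_br_known = true;
      prev_bl = bl_in;
      prev_row_done = true;
      if (64LL * (a + 1) <= n) {
        nbr[(size_t)a] = br; nbr_ok[(size_t)a] = 1;
      }

      if (!band_mode && a + 1 > fhi) {
        // extend downward only while the upper-right check admits
        if (a + 1 > AR - 1) break;
        long long dk = llabs((j0 + tcols - (64LL * (a + 1) + 1)) - mn);
        if (br + dk > limit) break;
      }
    }

    // rows processed before but not in this column lose their state
    int clo = (c == 0) ? 0 : palo, chi = (c == 0) ? AR - 1 : pahi;
    for (int a = clo; a <= chi; ++a)
      if (a < done_lo || a > done_hi) st[(size_t)a].valid = false;
    if (done_lo < 0) { out.disconnected = true; return; }
    palo = done_lo; pahi = done_hi;
    std::swap(pbr, nbr); std::swap(pbr_ok, nbr_ok);
    std::fill(nbr_ok.begin(), nbr_ok.end(), (char)0);
  }

  if (want_col_scores) {
    out.col_scores.assign((size_t)n + 1, SCORE_INF);
    for (int a = palo; a <= pahi; ++a) {
      const RowState& s = st[(size_t)a];
      if (!s.valid) continue;
      int live = (a == AR - 1) ? (int)(n - 64LL * a) : 64;
      long long run = s.corner;
      if (out.col_scores[(size_t)(64LL * a)] > run)
        out.col_scores[(size_t)(64LL * a)] = run;
      for (int r = 1; r <= live; ++r) {
        run += ((s.vp >> (r - 1)) & 1ULL) ? 1 : (((s.vn >> (r - 1)) & 1ULL) ? -1 : 0);
        if (out.col_scores[(size_t)(64LL * a + r)] > run)
          out.col_scores[(size_t)(64LL * a + r)] = run;
      }
    }
  }

  if (stop_col == m) {
    const RowState& s = st[(size_t)(AR - 1)];
    if (s.valid) {
      int live = (int)(n - 64LL * (AR - 1));
      out.score = s.corner + delta_sum(s.vp, s.vn, row_mask(live));
      out.reached = true;
    }
  }
}

// Reconstruct H for any cell covered by the stored tiles.  Cells in tiles
// that were cut off return SCORE_INF, except cells on the left/top edge
// of a stored tile, which resolve through that tile's stored entry
// boundary (these carry the values the tile was actually computed with).
struct TraceReader {
  const SweepOut& sw;
  int AC;

  const TileTrace* tile(long long a, long long c) const {
    if (a < 0 || c < 0) return nullptr;
    auto it = sw.tindex.find(a * AC + c);
    return it == sw.tindex.end() ? nullptr : &sw.traces[(size_t)it->second];
  }

  long long cellH(long long i, long long j) const {
    if (i == 0) return j;
    if (j == 0) return i;
    long long a = (i - 1) / 64, c = (j - 1) / 64;
    if (const TileTrace* tt = tile(a, c)) {
      int k = (int)(j - 64 * c);
      int r = (int)(i - 64 * a);
      uint64_t km = row_mask(k);
      long long toph = tt->corner +
                       (long long)__builtin_popcountll(tt->top_hp & km) -
                       (long long)__builtin_popcountll(tt->top_hn & km);
      return toph + delta_sum(tt->cvp[(size_t)(k - 1)],
                              tt->cvn[(size_t)(k - 1)], row_mask(r));
    }
    if (j % 64 == 0) {  // left edge of the tile to the right
      if (const TileTrace* tt = tile(a, j / 64)) {
        int r = (int)(i - 64 * a);
        return tt->corner + delta_sum(tt->left_vp, tt->left_vn, row_mask(r));
      }
    }
    if (i % 64 == 0) {  // top edge of the tile below
      if (const TileTrace* tt = tile(i / 64, c)) {
        int k = (int)(j - 64 * c);
        uint64_t km = row_mask(k);
        return tt->corner + (long long)__builtin_popcountll(tt->top_hp & km) -
               (long long)__builtin_popcountll(tt->top_hn & km);
      }
    }
    return SCORE_INF;
  }
};

std::string rle_cigar(const std::vector<char>& ops) {
  std::string out;
  size_t i = 0;
  while (i < ops.size()) {
    size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    out += std::to_string(j - i);
    out += ops[i];
    i = j;
  }
  return out;
}

// Walk Eq.-style predecessors from (n, m) to (0, 0).  Tie-break:
// diagonal (match preferred over mismatch), then vertical (I, consumes
// pattern), then horizontal (D, consumes text).
bool traceback(const std::string& P, const std::string& T, const SweepOut& sw,
               int AC, std::string& cigar) {
  long long n = (long long)P.size(), m = (long long)T.size();
  TraceReader rd{sw, AC};
  std::vector<char> ops;
  ops.reserve((size_t)(n + m));
  long long i = n, j = m;
  while (i > 0 && j > 0) {
    long long h = rd.cellH(i, j);
    if (h >= SCORE_INF) return false;
    bool eq = P[(size_t)(i - 1)] == T[(size_t)(j - 1)];
    long long hd = rd.cellH(i - 1, j - 1);
    if (hd < SCORE_INF && hd + (eq ? 0 : 1) == h) {
      ops.push_back(eq ? '=' : 'X'); --i; --j;
    } else {
      long long hu = rd.cellH(i - 1, j);
      if (hu < SCORE_INF && hu + 1 == h) { ops.push_back('I'); --i; }
      else {
        long long hl = rd.cellH(i, j - 1);
        if (hl < SCORE_INF && hl + 1 == h) { ops.push_back('D'); --j; }
        else return false;
      }
    }
  }
  while (i > 0) { ops.push_back('I'); --i; }
  while (j > 0) { ops.push_back('D'); --j; }
  std::reverse(ops.begin(), ops.end());
  cigar = rle_cigar(ops);
  return true;
}

}  // namespace

// Score-bounded exact alignment with stored-trace traceback.  If the
// supplied bound turns out to be below the optimum, the bound is doubled
// transparently until the computed score certifies itself (score <= bound).
// [[Rcpp::export]]
List cpp_bounded_align(std::string p, std::string t, double s_hat) {
  long long n = (long long)p.size(), m = (long long)t.size();
  if (n == 0 || m == 0) {
    std::string cig;
    if (n > 0) cig = std::to_string(n) + "I";
    else if (m > 0) cig = std::to_string(m) + "D";
    return List::create(_["score"] = (double)(n + m), _["cigar"] = cig,
                        _["tiles"] = 0.0, _["total_tiles"] = 0.0,
                        _["bound_used"] = (double)(n + m), _["retries"] = 0,
                        _["trace_bytes"] = 0.0);
  }
  long long s = std::max(0.0, std::min((double)(n + m), s_hat));
  int AC = (int)((m + 63) / 64);
  long long total_tiles = 0;
  int retries = 0;
  while (true) {
    SweepOut sw;
    sweep(p, t, s, false, false, m, true, false, sw);
    total_tiles += sw.tiles;
    if (sw.reached && sw.score <= s) {
      std::string cig;
      if (traceback(p, t, sw, AC, cig)) {
        return List::create(
            _["score"] = (double)sw.score, _["cigar"] = cig,
            _["tiles"] = (double)sw.tiles, _["total_tiles"] = (double)total_tiles,
            _["bound_used"] = (double)s, _["retries"] = retries,
            _["trace_bytes"] = (double)sw.trace_bytes);
      }
    }
    if (s >= n + m) stop("internal error: alignment failed at the full bound");
    s = std::min(n + m, std::max(1LL, 2 * s));
    ++retries;
  }
}

// Score-only bounded sweep up to stop_col; H at that column for every
// pattern row, +Inf outside the admitted region.  The cutoff uses the
// full problem's target diagonal, so the caller passes the (sub)problem
// whose corner the alignment must reach.
// [[Rcpp::export]]
NumericVector cpp_score_pass(std::string p, std::string t, double s_hat,
                             double stop_col) {
  long long n = (long long)p.size(), m = (long long)t.size();
  long long sc = (long long)stop_col;
  if (n == 0) {
    NumericVector out(1);
    out[0] = (double)sc;
    return out;
  }
  if (sc < 1 || sc > m) stop("stop_col out of range");
  long long s = std::max(0.0, std::min((double)(n + m), s_hat));
  SweepOut sw;
  sweep(p, t, s, false, false, sc, false, true, sw);
  NumericVector out((R_xlen_t)(n + 1));
  for (long long i = 0; i <= n; ++i)
    out[(R_xlen_t)i] = (sw.col_scores.empty() || sw.col_scores[(size_t)i] >= SCORE_INF)
                           ? R_PosInf
                           : (double)sw.col_scores[(size_t)i];
  return out;
}

// Banded score: tiles restricted to |d| <= b and |d-(m-n)| <= b, with an
// optional dynamic cutoff.  Finite results are upper bounds of the true
// distance; score <= b certifies optimality.
// [[Rcpp::export]]
List cpp_banded(std::string p, std::string t, double band, bool cutoff) {
  long long n = (long long)p.size(), m = (long long)t.size();
  long long b = std::max(0.0, band);
  if (n == 0 || m == 0) {
    long long sc = n + m;
    bool ok = sc <= b;
    return List::create(_["score"] = ok ? (double)sc : R_PosInf,
                        _["exact"] = ok, _["tiles"] = 0.0);
  }
  SweepOut sw;
  sweep(p, t, b, true, cutoff, m, false, false, sw);
  if (!sw.reached || sw.disconnected)
    return List::create(_["score"] = R_PosInf, _["exact"] = false,
                        _["tiles"] = (double)sw.tiles);
  return List::create(_["score"] = (double)sw.score,
                      _["exact"] = sw.score <= b, _["tiles"] = (double)sw.tiles);
}

// Band doubling: repeat banded alignment with b, 2b, 4b, ... until the
// computed score fits inside the band, which certifies optimality.
// [[Rcpp::export]]
List cpp_band_doubling(std::string p, std::string t, double b0) {
  long long n = (long long)p.size(), m = (long long)t.size();
  long long b = std::max(1.0, b0);
  long long total = 0;
  int rounds = 0;
  while (true) {
    SweepOut sw;
    ++rounds;
    if (n == 0 || m == 0) {
      if (n + m <= b)
        return List::create(_["score"] = (double)(n + m),
                            _["final_band"] = (double)b, _["rounds"] = rounds,
                            _["tiles_total"] = 0.0);
    } else {
      sweep(p, t, b, true, true, m, false, false, sw);
      total += sw.tiles;
      if (sw.reached && !sw.disconnected && sw.score <= b)
        return List::create(_["score"] = (double)sw.score,
                            _["final_band"] = (double)b, _["rounds"] = rounds,
                            _["tiles_total"] = (double)total);
    }
    b *= 2;
    if (b > 2 * (n + m + 1)) b = std::max(1LL, n + m);  // always terminates
  }
}

// [[Rcpp::export]]
std::string cpp_revstr(std::string x) {
  std::reverse(x.begin(), x.end());
  return x;
}
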