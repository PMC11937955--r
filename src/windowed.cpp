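#include "core.h"
#include <Rcpp.h>

using namespace Rcpp;

namespace {

using namespace ba;

// One W x W window of the DP-matrix, anchored so that every path enters
// through the anchor cell with score `entry` (border cells cost +1 per
// step away from the anchor, i.e. real gap operations, which keeps the
// chained per-window paths a feasible global alignment).
struct WinOut {
  long long er, ec, exit_score;   // chosen exit cell (global DP coords)
  long long ar, ac, anchor_entry; // next anchor + its entry score
  double window_error;
};

struct WinState {
  std::vector<PeqBlock> peq;
  std::vector<uint64_t> cvp, cvn;  // B x wc column snapshots
  long long r0, c0, wr, wc, entry;
  int B;

  long long cellH(long long i, long long j) const {
    if (i == 0) return entry + j;
    if (j == 0) return entry + i;
    long long h = entry + j;
    int bi = (int)((i - 1) / 64);
    const uint64_t* vp = &cvp[(size_t)(j - 1) * B];
    const uint64_t* vn = &cvn[(size_t)(j - 1) * B];
    for (int b = 0; b < bi; ++b) h += delta_sum(vp[b], vn[b], ONES);
    h += delta_sum(vp[bi], vn[bi], row_mask((int)(i - 64 * bi)));
    return h;
  }
};

WinOut run_window(const std::string& P, const std::string& T, long long r0,
                  long long c0, long long entry, int W, int O, bool force_end) {
  long long n = (long long)P.size(), m = (long long)T.size();
  long long r1 = std::min(r0 + W, n), c1 = std::min(c0 + W, m);
  long long wr = r1 - r0, wc = c1 - c0;
  WinOut res;
  if (wr == 0 || wc == 0) {
    // degenerate strip along an edge of the matrix: pure gap movement
    res.er = r1; res.ec = c1;
    res.exit_score = entry + wr + wc;
    res.ar = r1; res.ac = c1; res.anchor_entry = res.exit_score;
    res.window_error =
        (double)(wr + wc) / (double)std::max(std::max(wr, wc), 1LL);
    return res;
  }

  WinState st;
  st.r0 = r0; st.c0 = c0; st.wr = wr; st.wc = wc; st.entry = entry;
  st.B = (int)((wr + 63) / 64);
  st.peq = build_peq(P.substr((size_t)r0, (size_t)wr));
  st.cvp.assign((size_t)st.B * wc, 0);
  st.cvn.assign((size_t)st.B * wc, 0);

  std::vector<uint64_t> vp((size_t)st.B, ONES), vn((size_t)st.B, 0);
  std::vector<long long> bottom((size_t)wc + 1);
  bottom[0] = entry + wr;
  for (long long j = 1; j <= wc; ++j) {
    unsigned char tc = (unsigned char)T[(size_t)(c0 + j - 1)];
    int h = 1;
    for (int b = 0; b < st.B; ++b)
      h = advance_word(st.peq[b].peq[tc], vp[b], vn[b], h);
    for (int b = 0; b < st.B; ++b) {
      st.cvp[(size_t)(j - 1) * st.B + b] = vp[b];
      st.cvn[(size_t)(j - 1) * st.B + b] = vn[b];
    }
    long long s = entry + j;
    for (int b = 0; b < st.B - 1; ++b) s += delta_sum(vp[b], vn[b], ONES);
    s += delta_sum(vp[st.B - 1], vn[st.B - 1],
                   row_mask((int)(wr - 64 * (st.B - 1))));
    bottom[(size_t)j] = s;
  }

  long long ei, ej;  // exit, window-local
  if (force_end) {
    ei = wr; ej = wc;
  } else {
    ei = wr; ej = wc;
    long long best = SCORE_INF;
    auto consider = [&](long long i, long long j, long long s) {
      if (s < best || (s == best && (i + j > ei + ej ||
                                     (i + j == ei + ej && i > ei)))) {
        best = s; ei = i; ej = j;
      }
    };
    best = SCORE_INF; ei = -1; ej = -1;
    for (long long j = 1; j <= wc; ++j) consider(wr, j, bottom[(size_t)j]);
    for (long long i = 1; i <= wr; ++i) consider(i, wc, st.cellH(i, wc));
  }
  long long exit_score = (ei == wr) ? ((ej >= 1) ? bottom[(size_t)ej] : entry + wr)
                                    : st.cellH(ei, ej);
  if (force_end) exit_score = st.cellH(ei, ej);

  // within-window traceback to locate the next anchor O cells back
  long long i = ei, j = ej, ai = ei, aj = ej;
  bool found = false;
  while (i > 0 || j > 0) {
    if (ei - i >= O && ej - j >= O) { ai = i; aj = j; found = true; break; }
    if (i == 0) { --j; continue; }
    if (j == 0) { --i; continue; }
    long long h = st.cellH(i, j);
    bool eq = P[(size_t)(r0 + i - 1)] == T[(size_t)(c0 + j - 1)];
    long long hd = st.cellH(i - 1, j - 1);
    if (hd + (eq ? 0 : 1) == h) { --i; --j; }
    else if (st.cellH(i - 1, j) + 1 == h) { --i; }
    else { --j; }
  }
  if (!found) { ai = ei; aj = ej; }  // fall back to the exit itself

  res.er = r0 + ei; res.ec = c0 + ej;
  res.exit_score = exit_score;
  res.ar = r0 + ai; res.ac = c0 + aj;
  res.anchor_entry = st.cellH(ai, aj);
  res.window_error =
      (double)(exit_score - entry) / (double)std::max(std::max(ei, ej), 1LL);
  return res;
}

}  // namespace

// Single window, test-facing.  anchor is the 0-based DP cell (row, col).
// [[Rcpp::export]]
List cpp_window_single(std::string p, std::string t, double anchor_row,
                       double anchor_col, double entry_score, int W, int O) {
  long long n = (long long)p.size(), m = (long long)t.size();
  long long r0 = (long long)anchor_row, c0 = (long long)anchor_col;
  if (r0 < 0 || c0 < 0 || r0 > n || c0 > m) stop("anchor outside the DP-matrix");
  bool fin = (r0 + W >= n && c0 + W >= m);
  WinOut w = run_window(p, t, r0, c0, (long long)entry_score, W, O, fin);
  return List::create(
      _["exit"] = NumericVector::create((double)w.er, (double)w.ec),
      _["exit_score"] = (double)w.exit_score,
      _["next_anchor"] = NumericVector::create((double)w.ar, (double)w.ac),
      _["next_entry"] = (double)w.anchor_entry,
      _["window_error"] = w.window_error, _["is_final"] = fin);
}

// Full windowed score bound (forward over the strings as given; the
// caller reverses both strings for a backward run).
// [[Rcpp::export]]
List cpp_windowed(std::string p, std::string t, int W, int O,
                  double hew_threshold) {
  long long n = (long long)p.size(), m = (long long)t.size();
  if (n == 0 || m == 0)
    return List::create(_["s_hat"] = (double)(n + m), _["windows"] = 0,
                        _["hews"] = 0);
  long long r0 = 0, c0 = 0, entry = 0;
  long long windows = 0, hews = 0, s_hat = -1;
  long long guard = (n + m) / std::max(W - O, 1) + 8;
  while (true) {
    bool fin = (r0 + W >= n && c0 + W >= m);
    WinOut w = run_window(p, t, r0, c0, entry, W, O, fin);
    ++windows;
    if (w.window_error > hew_threshold) ++hews;
    if (fin) { s_hat = w.exit_score; break; }
    if (w.ar == r0 && w.ac == c0)
      stop("internal error: window anchor failed to advance");
    r0 = w.ar; c0 = w.ac; entry = w.anchor_entry;
    if (windows > guard)
      stop("internal error: window count exceeded progress bound");
  }
  return List::create(_["s_hat"] = (double)s_hat, _["windows"] = (double)windows,
                      _["hews"] = (double)hews);
}
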