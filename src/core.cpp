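#include "core.h"
#include <Rcpp.h>

using namespace Rcpp;

namespace ba {

std::vector<PeqBlock> build_peq(const std::string& pat) {
  int n = (int)pat.size();
  int nb = (n + 63) / 64;
  std::vector<PeqBlock> out((size_t)nb);
  for (int b = 0; b < nb; ++b) {
    out[b].peq.fill(0);
    int live = std::min(64, n - 64 * b);
    out[b].live = live;
    for (int r = 0; r < live; ++r)
      out[b].peq[(unsigned char)pat[64 * b + r]] |= 1ULL << r;
  }
  return out;
}

}  // namespace ba

// Plain quadratic dynamic-programming oracle: full (n+1) x (m+1) matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_oracle_matrix(std::string p, std::string t) {
  int n = (int)p.size(), m = (int)t.size();
  if ((double)(n + 1) * (m + 1) > 6e7)
    stop("oracle matrix too large; use cpp_oracle_score()");
  IntegerMatrix H(n + 1, m + 1);
  for (int i = 0; i <= n; ++i) H(i, 0) = i;
  for (int j = 0; j <= m; ++j) H(0, j) = j;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      int d = H(i - 1, j - 1) + (p[i - 1] == t[j - 1] ? 0 : 1);
      int v = H(i - 1, j) + 1;
      int h = H(i, j - 1) + 1;
      H(i, j) = std::min(d, std::min(v, h));
    }
  return H;
}

// Score-only oracle with two rolling rows.
// [[Rcpp::export]]
int cpp_oracle_score(std::string p, std::string t) {
  int n = (int)p.size(), m = (int)t.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int d = prev[j - 1] + (p[i - 1] == t[j - 1] ? 0 : 1);
      cur[j] = std::min(d, std::min(prev[j], cur[j - 1]) + 1);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

static uint64_t pack_bits(const LogicalVector& v, const char* what) {
  if (v.size() != 64) stop("%s must have length 64", what);
  uint64_t x = 0;
  for (int i = 0; i < 64; ++i)
    if (v[i]) x |= 1ULL << i;
  return x;
}

static LogicalVector unpack_bits(uint64_t x) {
  LogicalVector v(64);
  for (int i = 0; i < 64; ++i) v[i] = (x >> i) & 1ULL;
  return v;
}

// Single kernel step, test-facing: masks as 64-element logical vectors.
// [[Rcpp::export]]
List cpp_advance_column(LogicalVector peq, LogicalVector vp, LogicalVector vn,
                        int h_in) {
  uint64_t e = pack_bits(peq, "peq"), p = pack_bits(vp, "vp"),
           q = pack_bits(vn, "vn");
  if (p & q) stop("malformed delta vector: vp and vn overlap");
  if (h_in < -1 || h_in > 1) stop("h_in must be in {-1, 0, +1}");
  int hout = ba::advance_word(e, p, q, h_in);
  return List::create(_["vp"] = unpack_bits(p), _["vn"] = unpack_bits(q),
                      _["h_out"] = hout);
}

// One 64 x tcols tile, test-facing.  Returns exit score at the live
// bottom-right corner, the exiting boundary differences, and the
// per-column vertical differences as a 64 x tcols matrix in {-1,0,+1}.
// [[Rcpp::export]]
List cpp_compute_tile(std::string pattern_block, std::string text_block,
                      LogicalVector left_vp, LogicalVector left_vn,
                      IntegerVector top_h, int entry_score) {
  int live = (int)pattern_block.size();
  int tcols = (int)text_block.size();
  if (live < 1 || live > 64) stop("pattern block must have 1..64 rows");
  if (tcols < 1 || tcols > 64) stop("text block must have 1..64 columns");
  if (top_h.size() != tcols) stop("top_h must have one entry per text column");
  std::vector<ba::PeqBlock> pq = ba::build_peq(pattern_block);
  uint64_t vp = pack_bits(left_vp, "left_vp"), vn = pack_bits(left_vn, "left_vn");
  if (vp & vn) stop("malformed delta vector: vp and vn overlap");
  std::vector<signed char> th(tcols), bh(tcols);
  for (int k = 0; k < tcols; ++k) {
    if (top_h[k] < -1 || top_h[k] > 1) stop("top_h values must be in {-1,0,+1}");
    th[k] = (signed char)top_h[k];
  }
  std::vector<uint64_t> cvp(tcols), cvn(tcols);
  int tsum = ba::tile_pass(pq[0].peq.data(),
                           (const unsigned char*)text_block.data(), tcols, vp,
                           vn, th.data(), bh.data(), cvp.data(), cvn.data());
  IntegerMatrix dv(64, tcols);
  for (int k = 0; k < tcols; ++k)
    for (int r = 0; r < 64; ++r)
      dv(r, k) = ((cvp[k] >> r) & 1ULL) ? 1 : (((cvn[k] >> r) & 1ULL) ? -1 : 0);
  long long exit_score =
      entry_score + tsum + ba::delta_sum(vp, vn, ba::row_mask(live));
  IntegerVector bout(tcols);
  for (int k = 0; k < tcols; ++k) bout[k] = bh[k];
  return List::create(
      _["right_vp"] = unpack_bits(vp), _["right_vn"] = unpack_bits(vn),
      _["bottom_h"] = bout, _["exit_score"] = (double)exit_score,
      _["topright_score"] = (double)(entry_score + tsum), _["dv_cols"] = dv,
      _["live"] = live);
}
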