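#ifndef BOUNDALIGN_CORE_H
#define BOUNDALIGN_CORE_H

#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <array>

namespace ba {

constexpr int TILE = 64;
constexpr uint64_t ONES = ~0ULL;
constexpr uint64_t MSB = 1ULL << 63;
constexpr long long SCORE_INF = 1LL << 60;

// Equality masks for one 64-row pattern block: bit r of peq[b] is set iff
// the pattern byte at row (base + r) equals b.  Padding rows of a final
// partial block match nothing, so they never contribute a diagonal match.
struct PeqBlock {
  std::array<uint64_t, 256> peq;
  int live;  // rows of the block actually covered by the pattern (1..64)
};

std::vector<PeqBlock> build_peq(const std::string& pat);

// One column step of the bit-parallel edit-distance kernel over a 64-row
// block.  vp/vn encode the vertical score differences of the entering
// column (+1 rows in vp, -1 rows in vn, bit 0 = top row of the block);
// hin is the horizontal difference entering at the block's top row.
// Returns the horizontal difference leaving at the block's bottom row
// and replaces vp/vn with the differences of the exiting column.
inline int advance_word(uint64_t eq, uint64_t& vp, uint64_t& vn, int hin) {
  uint64_t xv = eq | vn;
  if (hin < 0) eq |= 1ULL;
  uint64_t xh = (((eq & vp) + vp) ^ vp) | eq;
  uint64_t ph = vn | ~(xh | vp);
  uint64_t mh = vp & xh;
  int hout = 0;
  if (ph & MSB) hout = 1;
  else if (mh & MSB) hout = -1;
  ph <<= 1;
  mh <<= 1;
  if (hin > 0) ph |= 1ULL;
  else if (hin < 0) mh |= 1ULL;
  vp = mh | ~(xv | ph);
  vn = ph & xv;
  return hout;
}

inline uint64_t row_mask(int k) {  // bits 0..k-1
  return k >= 64 ? ONES : ((1ULL << k) - 1);
}

inline long long delta_sum(uint64_t vp, uint64_t vn, uint64_t mask) {
  return (long long)__builtin_popcountll(vp & mask) -
         (long long)__builtin_popcountll(vn & mask);
}

// Advance one 64-row block across tcols text characters (one DP tile).
// top_h[k] is the horizontal difference entering column k at the block's
// top row; bottom_h (optional) receives the differences leaving at the
// block's bit-63 row; col_vp/col_vn (optional) receive per-column
// vertical-difference snapshots.  Returns the sum of top_h, i.e. the
// score change along the tile's top row.
inline int tile_pass(const uint64_t* peq, const unsigned char* text, int tcols,
                     uint64_t& vp, uint64_t& vn, const signed char* top_h,
                     signed char* bottom_h, uint64_t* col_vp, uint64_t* col_vn) {
  int tsum = 0;
  for (int k = 0; k < tcols; ++k) {
    int hout = advance_word(peq[text[k]], vp, vn, top_h[k]);
    if (bottom_h) bottom_h[k] = (signed char)hout;
    if (col_vp) { col_vp[k] = vp; col_vn[k] = vn; }
    tsum += top_h[k];
  }
  return tsum;
}

inline long long ceil_div64(long long a) {
  return a >= 0 ? (a + 63) / 64 : -((-a) / 64);
}
inline long long floor_div64(long long a) {
  return a >= 0 ? a / 64 : -(((-a) + 63) / 64);
}

}  // namespace ba

#endif
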