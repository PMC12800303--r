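// Binary-image morphology used by the length and counting pipelines:
// Zhang-Suen thinning and 8-connected component labelling.
#include <Rcpp.h>
using namespace Rcpp;

// Neighbour order P2..P9: N, NE, E, SE, S, SW, W, NW (row decreases upward;
// here "N" means row - 1).
static inline void neighbours(const IntegerMatrix& m, int r, int c, int* p) {
  const int H = m.nrow(), W = m.ncol();
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  for (int i = 0; i < 8; ++i) {
    const int rr = r + dr[i], cc = c + dc[i];
    p[i] = (rr >= 0 && rr < H && cc >= 0 && cc < W) ? m(rr, cc) : 0;
  }
}

// [[Rcpp::export]]
Rcpp::IntegerMatrix thin_zhang_suen(Rcpp::IntegerMatrix img) {
  IntegerMatrix m = clone(img);
  const int H = m.nrow(), W = m.ncol();
  bool changed = true;
  std::vector<std::pair<int, int>> kill;
  int p[8];
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
          if (!m(r, c)) continue;
          neighbours(m, r, c, p);
          int B = 0;
          for (int i = 0; i < 8; ++i) B += p[i];
          if (B < 2 || B > 6) continue;
          int A = 0;
          for (int i = 0; i < 8; ++i)
            if (p[i] == 0 && p[(i + 1) % 8] == 1) ++A;
          if (A != 1) continue;
          // p[0]=P2(N), p[2]=P4(E), p[4]=P6(S), p[6]=P8(W)
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.push_back({r, c});
        }
      for (auto& rc : kill) m(rc.first, rc.second) = 0;
      if (!kill.empty()) changed = true;
    }
  }
  return m;
}

// [[Rcpp::export]]
Rcpp::IntegerMatrix label_components8(Rcpp::IntegerMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int c0 = 0; c0 < W; ++c0)
    for (int r0 = 0; r0 < H; ++r0) {
      if (!img(r0, c0) || lab(r0, c0)) continue;
      ++next;
      stack.push_back({r0, c0});
      lab(r0, c0) = next;
      while (!stack.empty()) {
        const auto rc = stack.back();
        stack.pop_back();
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            const int rr = rc.first + dr, cc = rc.second + dc;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            if (img(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.push_back({rr, cc});
            }
          }
      }
    }
  return lab;
}
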