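// Hot board primitives: run detection and valid-move enumeration.
// Boards are integer matrices (h rows x w cols, tile ids 0..t-1);
// moves are reported 1-based as (r1, c1, r2, c2) with the smaller cell
// first, matching the R-side canonical form.

#include <Rcpp.h>
using namespace Rcpp;

static inline bool run_through(const IntegerMatrix& m, int r, int c) {
  const int v = m(r, c);
  const int h = m.nrow(), w = m.ncol();
  int le = c;
  while (le > 0 && m(r, le - 1) == v) --le;
  int ri = c;
  while (ri < w - 1 && m(r, ri + 1) == v) ++ri;
  if (ri - le >= 2) return true;
  int up = r;
  while (up > 0 && m(up - 1, c) == v) --up;
  int dn = r;
  while (dn < h - 1 && m(dn + 1, c) == v) ++dn;
  return (dn - up) >= 2;
}

// [[Rcpp::export]]
bool cpp_has_run(const IntegerMatrix& m) {
  const int h = m.nrow(), w = m.ncol();
  for (int r = 0; r < h; ++r)
    for (int c = 0; c + 2 < w; ++c)
      if (m(r, c) == m(r, c + 1) && m(r, c) == m(r, c + 2)) return true;
  for (int c = 0; c < w; ++c)
    for (int r = 0; r + 2 < h; ++r)
      if (m(r, c) == m(r + 1, c) && m(r, c) == m(r + 2, c)) return true;
  return false;
}

// Swap in place, test, swap back. A swap of identical tiles never
// creates a run (it changes nothing); on a stable board any new run
// must pass through one of the swapped cells.
static inline bool swap_creates(IntegerMatrix& m, int r1, int c1,
                                int r2, int c2) {
  if (m(r1, c1) == m(r2, c2)) return false;
  std::swap(m(r1, c1), m(r2, c2));
  const bool ok = run_through(m, r1, c1) || run_through(m, r2, c2);
  std::swap(m(r1, c1), m(r2, c2));
  return ok;
}

// Run statistics (count of maximal runs >= 3 and their maximum length)
// after applying the swap (1-based coordinates). The matrix is restored
// before returning.
// [[Rcpp::export]]
IntegerVector cpp_swap_run_stats(IntegerMatrix m, int r1, int c1,
                                 int r2, int c2) {
  std::swap(m(r1 - 1, c1 - 1), m(r2 - 1, c2 - 1));
  const int h = m.nrow(), w = m.ncol();
  int n = 0, maxlen = 0;
  for (int r = 0; r < h; ++r) {
    int c = 0;
    while (c < w) {
      int j = c;
      while (j + 1 < w && m(r, j + 1) == m(r, c)) ++j;
      const int len = j - c + 1;
      if (len >= 3) {
        ++n;
        if (len > maxlen) maxlen = len;
      }
      c = j + 1;
    }
  }
  for (int c = 0; c < w; ++c) {
    int r = 0;
    while (r < h) {
      int j = r;
      while (j + 1 < h && m(j + 1, c) == m(r, c)) ++j;
      const int len = j - r + 1;
      if (len >= 3) {
        ++n;
        if (len > maxlen) maxlen = len;
      }
      r = j + 1;
    }
  }
  std::swap(m(r1 - 1, c1 - 1), m(r2 - 1, c2 - 1));
  return IntegerVector::create(n, maxlen);
}

// All valid moves on a stable board, in row-major scan order, stopping
// once `cap` moves are found. Returns an n x 4 matrix (r1 c1 r2 c2).
// [[Rcpp::export]]
IntegerMatrix cpp_valid_moves(IntegerMatrix m, int cap) {
  const int h = m.nrow(), w = m.ncol();
  std::vector<int> found;
  int n = 0;
  for (int r = 0; r < h && n < cap; ++r) {
    for (int c = 0; c < w && n < cap; ++c) {
      if (c + 1 < w && swap_creates(m, r, c, r, c + 1)) {
        found.push_back(r + 1);
        found.push_back(c + 1);
        found.push_back(r + 1);
        found.push_back(c + 2);
        if (++n >= cap) break;
      }
      if (r + 1 < h && swap_creates(m, r, c, r + 1, c)) {
        found.push_back(r + 1);
        found.push_back(c + 1);
        found.push_back(r + 2);
        found.push_back(c + 1);
        ++n;
      }
    }
  }
  const int k = static_cast<int>(found.size()) / 4;
  IntegerMatrix res(k, 4);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < 4; ++j) res(i, j) = found[4 * i + j];
  return res;
}
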