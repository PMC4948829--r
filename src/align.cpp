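#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Semi-global affine-gap (Gotoh) alignment of a clone against a reference
// telomere. Both sequences are anchored at the proximal (left) end; trailing
// gaps at the distal (right) end of the shorter aligned sequence are free.
// Gap of length L costs gap_open + L * gap_extend.
//
// Tie-breaks (fixed for reproducibility): on equal score prefer the
// diagonal (match/mismatch) move, then a gap in the reference, then a gap
// in the clone; among end cells prefer the one consuming more total
// sequence, then more reference.

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".align_semiglobal_cpp")]]
List align_semiglobal_cpp(std::string ref, std::string clone,
                          double match, double mismatch,
                          double gap_open, double gap_extend) {
  const int n = ref.size();    // reference, rows
  const int m = clone.size();  // clone, cols
  if (n == 0 || m == 0)
    stop("both sequences must be non-empty");

  // state 0 = M (diagonal), 1 = X (gap in clone, consumes ref),
  // 2 = Y (gap in reference, consumes clone)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[at(i, 0)] = gap_open + i * gap_extend;
  for (int j = 1; j <= m; ++j) Y[at(0, j)] = gap_open + j * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = (ref[i - 1] == clone[j - 1]) ? match : mismatch;
      double d = M[at(i - 1, j - 1)];
      if (X[at(i - 1, j - 1)] > d) d = X[at(i - 1, j - 1)];
      if (Y[at(i - 1, j - 1)] > d) d = Y[at(i - 1, j - 1)];
      M[at(i, j)] = (d <= NEG_INF / 2) ? NEG_INF : d + s;

      double xo = M[at(i - 1, j)] + gap_open + gap_extend;
      double xe = X[at(i - 1, j)] + gap_extend;
      double xy = Y[at(i - 1, j)] + gap_open + gap_extend;
      double x = xo > xe ? xo : xe;
      if (xy > x) x = xy;
      X[at(i, j)] = x;

      double yo = M[at(i, j - 1)] + gap_open + gap_extend;
      double ye = Y[at(i, j - 1)] + gap_extend;
      double yx = X[at(i, j - 1)] + gap_open + gap_extend;
      double y = yo > ye ? yo : ye;
      if (yx > y) y = yx;
      Y[at(i, j)] = y;
    }
  }

  auto H = [&](int i, int j) {
    double h = M[at(i, j)];
    if (X[at(i, j)] > h) h = X[at(i, j)];
    if (Y[at(i, j)] > h) h = Y[at(i, j)];
    return h;
  };

  // end cell: last column (clone fully consumed, remaining reference free)
  // or last row (reference fully consumed, remaining clone free)
  int bi = n, bj = m;
  double best = H(n, m);
  for (int i = n - 1; i >= 1; --i) {
    double h = H(i, m);
    if (h > best) { best = h; bi = i; bj = m; }
  }
  for (int j = m - 1; j >= 1; --j) {
    double h = H(n, j);
    if (h > best) { best = h; bi = n; bj = j; }
  }

  // state at the chosen end cell, preference M > Y > X
  int state;
  if (M[at(bi, bj)] >= best) state = 0;
  else if (Y[at(bi, bj)] >= best) state = 2;
  else state = 1;

  std::string ra, ca;
  ra.reserve(n + m);
  ca.reserve(n + m);
  // free trailing gaps beyond the chosen end cell
  for (int j = m; j > bj; --j) { ra.push_back('-'); ca.push_back(clone[j - 1]); }
  for (int i = n; i > bi; --i) { ra.push_back(ref[i - 1]); ca.push_back('-'); }

  int i = bi, j = bj;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {  // M: came from diagonal
      ra.push_back(ref[i - 1]);
      ca.push_back(clone[j - 1]);
      const double s = (ref[i - 1] == clone[j - 1]) ? match : mismatch;
      const double target = M[at(i, j)] - s;
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[at(i, j)] >= target - eps) state = 0;
      else if (Y[at(i, j)] >= target - eps) state = 2;
      else state = 1;
    } else if (state == 1) {  // X: gap in clone, consumed ref
      ra.push_back(ref[i - 1]);
      ca.push_back('-');
      const double cur = X[at(i, j)];
      --i;
      if (i == 0 && j == 0) break;
      if (M[at(i, j)] + gap_open + gap_extend >= cur - eps) state = 0;
      else if (Y[at(i, j)] + gap_open + gap_extend >= cur - eps) state = 2;
      else state = 1;
    } else {  // Y: gap in reference, consumed clone
      ra.push_back('-');
      ca.push_back(clone[j - 1]);
      const double cur = Y[at(i, j)];
      --j;
      if (i == 0 && j == 0) break;
      if (M[at(i, j)] + gap_open + gap_extend >= cur - eps) state = 0;
      else if (Y[at(i, j)] + gap_extend >= cur - eps) state = 2;
      else state = 1;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(ca.begin(), ca.end());

  return List::create(_["ref_aln"] = ra, _["clone_aln"] = ca,
                      _["score"] = best);
}
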