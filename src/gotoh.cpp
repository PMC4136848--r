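#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh) over a precomputed column-score
// matrix S (n1 x n2): S(i, j) is the score of aligning column i of
// profile 1 with column j of profile 2. A gap of length k costs
// gap_open + k * gap_extend; terminal gaps are penalized (global mode).
// Returns 1-based aligned index vectors with 0 marking a gap, plus the
// optimal score. Ties prefer (diagonal, gap-in-2, gap-in-1), which keeps
// the traceback deterministic.
// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(NumericMatrix S, double gap_open, double gap_extend) {
  const int n1 = S.nrow(), n2 = S.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();
  const double gi = gap_open + gap_extend;   // cost of opening (first residue)

  std::vector<double> M((n1 + 1) * (n2 + 1), NEG);
  std::vector<double> X((n1 + 1) * (n2 + 1), NEG);  // gap in profile 2
  std::vector<double> Y((n1 + 1) * (n2 + 1), NEG);  // gap in profile 1
  auto at = [n2](int i, int j) { return i * (n2 + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n1; ++i) X[at(i, 0)] = -gap_open - i * gap_extend;
  for (int j = 1; j <= n2; ++j) Y[at(0, j)] = -gap_open - j * gap_extend;

  for (int i = 1; i <= n1; ++i) {
    for (int j = 1; j <= n2; ++j) {
      double dm = M[at(i - 1, j - 1)], dx = X[at(i - 1, j - 1)],
             dy = Y[at(i - 1, j - 1)];
      double best = dm >= dx ? (dm >= dy ? dm : dy) : (dx >= dy ? dx : dy);
      M[at(i, j)] = best + S(i - 1, j - 1);

      double xo = M[at(i - 1, j)] - gi, xe = X[at(i - 1, j)] - gap_extend;
      X[at(i, j)] = xo >= xe ? xo : xe;

      double yo = M[at(i, j - 1)] - gi, ye = Y[at(i, j - 1)] - gap_extend;
      Y[at(i, j)] = yo >= ye ? yo : ye;
    }
  }

  // traceback
  int i = n1, j = n2, state;
  double fm = M[at(i, j)], fx = X[at(i, j)], fy = Y[at(i, j)];
  double score = fm; state = 0;
  if (fx > score) { score = fx; state = 1; }
  if (fy > score) { score = fy; state = 2; }

  std::vector<int> p1, p2;
  while (i > 0 || j > 0) {
    if (state == 0) {
      // came into M via diagonal
      p1.push_back(i); p2.push_back(j);
      double target = M[at(i, j)] - S(i - 1, j - 1);
      double dm = M[at(i - 1, j - 1)], dx = X[at(i - 1, j - 1)];
      --i; --j;
      if (dm >= target - 1e-9) state = 0;
      else if (dx >= target - 1e-9) state = 1;
      else state = 2;
      if (i == 0 && j == 0) break;
      if (i == 0 && state != 2) state = 2;
      if (j == 0 && state != 1) state = 1;
    } else if (state == 1) {
      p1.push_back(i); p2.push_back(0);
      double target = X[at(i, j)];
      double open = M[at(i - 1, j)] - gi;
      --i;
      state = (open >= target - 1e-9) ? 0 : 1;
      if (i == 0 && j > 0 && state == 0) state = 2;
    } else {
      p1.push_back(0); p2.push_back(j);
      double target = Y[at(i, j)];
      double open = M[at(i, j - 1)] - gi;
      --j;
      state = (open >= target - 1e-9) ? 0 : 2;
      if (j == 0 && i > 0 && state == 0) state = 1;
    }
  }
  std::reverse(p1.begin(), p1.end());
  std::reverse(p2.begin(), p2.end());
  return List::create(_["path1"] = IntegerVector(p1.begin(), p1.end()),
                      _["path2"] = IntegerVector(p2.begin(), p2.end()),
                      _["score"] = score);
}
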