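#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Three-state (M / gap-in-B / gap-in-A) global alignment with affine gap
// costs. The first column of a gap costs gap_open, every further column
// gap_extend. Traceback is deterministic: at every decision the preference
// is match/mismatch, then gap in the destination (B), then gap in the
// source (A), evaluated from the terminal cell.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".affineNW")]]
List affineNW(std::string a, std::string b, double match, double mismatch,
              double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF);
  std::vector<double> X((n + 1) * W, NEG_INF); // gap in B (consumes A)
  std::vector<double> Y((n + 1) * W, NEG_INF); // gap in A (consumes B)
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i * W] = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y[j] = gap_open + (j - 1) * gap_extend;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      const int d = (i - 1) * W + (j - 1);
      double best = M[d];
      if (X[d] > best) best = X[d];
      if (Y[d] > best) best = Y[d];
      M[i * W + j] = best + s;
      const int up = (i - 1) * W + j;
      double bx = M[up] + gap_open;
      if (X[up] + gap_extend > bx) bx = X[up] + gap_extend;
      if (Y[up] + gap_open > bx) bx = Y[up] + gap_open;
      X[i * W + j] = bx;
      const int lf = i * W + (j - 1);
      double by = M[lf] + gap_open;
      if (X[lf] + gap_open > by) by = X[lf] + gap_open;
      if (Y[lf] + gap_extend > by) by = Y[lf] + gap_extend;
      Y[i * W + j] = by;
    }
  }
  const double eps = 1e-9;
  int i = n, j = m;
  const int t = n * W + m;
  double score = M[t];
  int state = 0; // 0 = M, 1 = X, 2 = Y
  if (X[t] > score + eps) { score = X[t]; state = 1; }
  if (Y[t] > score + eps) { score = Y[t]; state = 2; }
  // re-apply preference among ties M > X > Y
  if (state != 0 && M[t] >= score - eps) { state = 0; score = M[t]; }
  else if (state == 2 && X[t] >= score - eps) { state = 1; score = X[t]; }

  std::vector<int> aPos, bPos;
  while (i > 0 || j > 0) {
    if (state == 0) {
      // column consumes a[i-1] and b[j-1]
      aPos.push_back(i); bPos.push_back(j);
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      const double target = M[i * W + j] - s;
      const int d = (i - 1) * W + (j - 1);
      if (M[d] >= target - eps) state = 0;
      else if (X[d] >= target - eps) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      aPos.push_back(i); bPos.push_back(NA_INTEGER);
      const double cur = X[i * W + j];
      const int up = (i - 1) * W + j;
      if (i == 1 && j == 0) { --i; continue; }
      if (M[up] + gap_open >= cur - eps) state = 0;
      else if (X[up] + gap_extend >= cur - eps) state = 1;
      else state = 2;
      --i;
    } else {
      aPos.push_back(NA_INTEGER); bPos.push_back(j);
      const double cur = Y[i * W + j];
      const int lf = i * W + (j - 1);
      if (i == 0 && j == 1) { --j; continue; }
      if (M[lf] + gap_open >= cur - eps) state = 0;
      else if (X[lf] + gap_open >= cur - eps) state = 1;
      else state = 2;
      --j;
    }
  }
  std::reverse(aPos.begin(), aPos.end());
  std::reverse(bPos.begin(), bPos.end());
  return List::create(_["score"] = score,
                      _["aPos"] = IntegerVector(aPos.begin(), aPos.end()),
                      _["bPos"] = IntegerVector(bPos.begin(), bPos.end()));
}
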