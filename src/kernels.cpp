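#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment over pre-computed column scores.
// S[i,j] is the score of aligning column i of profile A with column j of
// profile B. A gap of length L costs gapOpen + L * gapExtend, end gaps
// included. Traceback prefers match, then gap-in-B, then gap-in-A, so the
// result is deterministic. Returns 1-based column indices with 0 marking a
// gap column.
// [[Rcpp::export(name = ".gotohAlign")]]
List gotohAlign(NumericMatrix S, double gapOpen, double gapExtend) {
  const int m = S.nrow(), n = S.ncol();
  const double NEG = -1e30;
  NumericMatrix M(m + 1, n + 1), X(m + 1, n + 1), Y(m + 1, n + 1);
  // X: gap in B (consume A row), Y: gap in A (consume B column)
  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= m; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -(gapOpen + gapExtend * i);
  }
  for (int j = 1; j <= n; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -(gapOpen + gapExtend * j);
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double diag = std::max(M(i - 1, j - 1), std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = diag + S(i - 1, j - 1);
      X(i, j) = std::max(M(i - 1, j) - gapOpen - gapExtend,
                         X(i - 1, j) - gapExtend);
      double yFromM = M(i, j - 1) - gapOpen - gapExtend;
      Y(i, j) = std::max(yFromM, Y(i, j - 1) - gapExtend);
    }
  }
  // traceback
  std::vector<int> pa, pb;
  int i = m, j = n;
  int state; // 0 = M, 1 = X, 2 = Y
  double best = M(m, n); state = 0;
  if (X(m, n) > best) { best = X(m, n); state = 1; }
  if (Y(m, n) > best) { best = Y(m, n); state = 2; }
  double score = best;
  while (i > 0 || j > 0) {
    if (i == 0) { pa.push_back(0); pb.push_back(j); --j; continue; }
    if (j == 0) { pa.push_back(i); pb.push_back(0); --i; continue; }
    if (state == 0) {
      pa.push_back(i); pb.push_back(j);
      double diag = M(i, j) - S(i - 1, j - 1);
      --i; --j;
      if (std::abs(M(i, j) - diag) < 1e-9) state = 0;
      else if (std::abs(X(i, j) - diag) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1) {
      pa.push_back(i); pb.push_back(0);
      double cur = X(i, j);
      --i;
      if (std::abs((M(i, j) - gapOpen - gapExtend) - cur) < 1e-9) state = 0;
      else state = 1;
    } else {
      pa.push_back(0); pb.push_back(j);
      double cur = Y(i, j);
      --j;
      if (std::abs((M(i, j) - gapOpen - gapExtend) - cur) < 1e-9) state = 0;
      else state = 2;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["a"] = wrap(pa), _["b"] = wrap(pb), _["score"] = score);
}

// Pairwise p-distances (mismatches / compared columns, pairwise deletion of
// gap positions) on an integer-encoded alignment. `aln` is nseq x ncol with
// 0 encoding a gap; `cols` is a 1-based column index vector (allows
// bootstrap resampling without copying). A pair with no comparable column
// is reported with distance NA (callers decide whether that is an error).
// [[Rcpp::export(name = ".pDistC")]]
NumericMatrix pDistC(IntegerMatrix aln, IntegerVector cols) {
  const int n = aln.nrow(), m = cols.size();
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int comp = 0, mis = 0;
      for (int c = 0; c < m; ++c) {
        int cc = cols[c] - 1;
        int a = aln(i, cc), b = aln(j, cc);
        if (a != 0 && b != 0) {
          ++comp;
          if (a != b) ++mis;
        }
      }
      double v = comp > 0 ? (double)mis / comp : NA_REAL;
      d(i, j) = v; d(j, i) = v;
    }
  }
  return d;
}
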