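#include <Rcpp.h>
using namespace Rcpp;

// Gotoh three-state global alignment, maximizing. Sequences are 1-based
// integer codes into `mat`. A gap of length L costs gap_open + L * gap_extend
// (both penalties are negative). Tie-break order M > X > Y so the traceback
// is deterministic.
//
// States: M = a[i] aligned to b[j]; X = a[i] against a gap; Y = gap against
// b[j].

static const double NEG_INF = -1e18;

// [[Rcpp::export]]
List pairwise_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix mat,
                        double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix tM(n + 1, m + 1), tX(n + 1, m + 1), tY(n + 1, m + 1);

  M(0, 0) = 0.0;
  X(0, 0) = NEG_INF;
  Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF;
    Y(i, 0) = NEG_INF;
    X(i, 0) = gap_open + i * gap_extend;
    tX(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF;
    X(0, j) = NEG_INF;
    Y(0, j) = gap_open + j * gap_extend;
    tY(0, j) = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = mat(a[i - 1] - 1, b[j - 1] - 1);
      // M
      double best = M(i - 1, j - 1);
      int arg = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); arg = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); arg = 2; }
      M(i, j) = s + best;
      tM(i, j) = arg;
      // X: consume a[i], gap in b
      best = M(i - 1, j) + gap_open + gap_extend;
      arg = 0;
      double cand = X(i - 1, j) + gap_extend;
      if (cand > best) { best = cand; arg = 1; }
      cand = Y(i - 1, j) + gap_open + gap_extend;
      if (cand > best) { best = cand; arg = 2; }
      X(i, j) = best;
      tX(i, j) = arg;
      // Y: consume b[j], gap in a
      best = M(i, j - 1) + gap_open + gap_extend;
      arg = 0;
      cand = X(i, j - 1) + gap_open + gap_extend;
      if (cand > best) { best = cand; arg = 1; }
      cand = Y(i, j - 1) + gap_extend;
      if (cand > best) { best = cand; arg = 2; }
      Y(i, j) = best;
      tY(i, j) = arg;
    }
  }

  double score = M(n, m);
  int state = 0;
  if (X(n, m) > score) { score = X(n, m); state = 1; }
  if (Y(n, m) > score) { score = Y(n, m); state = 2; }

  // traceback
  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tM(i, j);
      pa.push_back(i);
      pb.push_back(j);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      int prev = tX(i, j);
      pa.push_back(i);
      pb.push_back(0);
      --i;
      state = prev;
    } else {
      int prev = tY(i, j);
      pa.push_back(0);
      pb.push_back(j);
      --j;
      state = prev;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());

  return List::create(_["score"] = score,
                      _["a"] = IntegerVector(pa.begin(), pa.end()),
                      _["b"] = IntegerVector(pb.begin(), pb.end()));
}

// Profile-profile alignment with sum-of-pairs column scores. Profiles are
// integer matrices (rows = member sequences, columns = alignment columns,
// 0 = gap, otherwise 1-based code into `mat`). Gap penalties against a
// profile column are scaled by the number of residues (non-gaps) in that
// column times the number of rows of the other profile, so the scheme
// degenerates to the pairwise recurrence for 1-row profiles and columns rich
// in gaps are cheap to gap again.
// [[Rcpp::export]]
List profile_align_cpp(IntegerMatrix A, IntegerMatrix B, NumericMatrix mat,
                       double gap_open, double gap_extend) {
  int nA = A.nrow(), la = A.ncol();
  int nB = B.nrow(), lb = B.ncol();

  // residue counts per column
  std::vector<double> cA(la), cB(lb);
  for (int i = 0; i < la; ++i) {
    int c = 0;
    for (int r = 0; r < nA; ++r) if (A(r, i) > 0) ++c;
    cA[i] = c;
  }
  for (int j = 0; j < lb; ++j) {
    int c = 0;
    for (int r = 0; r < nB; ++r) if (B(r, j) > 0) ++c;
    cB[j] = c;
  }

  // sum-of-pairs substitution score between columns
  NumericMatrix S(la, lb);
  for (int i = 0; i < la; ++i) {
    for (int j = 0; j < lb; ++j) {
      double s = 0.0;
      for (int r = 0; r < nA; ++r) {
        int ai = A(r, i);
        if (ai == 0) continue;
        for (int q = 0; q < nB; ++q) {
          int bj = B(q, j);
          if (bj == 0) continue;
          s += mat(ai - 1, bj - 1);
        }
      }
      S(i, j) = s;
    }
  }

  NumericMatrix M(la + 1, lb + 1), X(la + 1, lb + 1), Y(la + 1, lb + 1);
  IntegerMatrix tM(la + 1, lb + 1), tX(la + 1, lb + 1), tY(la + 1, lb + 1);

  M(0, 0) = 0.0;
  X(0, 0) = NEG_INF;
  Y(0, 0) = NEG_INF;
  double acc = 0.0;
  for (int i = 1; i <= la; ++i) {
    double w = cA[i - 1] * nB;
    acc += (i == 1 ? gap_open + gap_extend : gap_extend) * w;
    // open charged once at the first gapped column, scaled by that column
    M(i, 0) = NEG_INF;
    Y(i, 0) = NEG_INF;
    X(i, 0) = acc;
    tX(i, 0) = (i == 1) ? 0 : 1;
  }
  acc = 0.0;
  for (int j = 1; j <= lb; ++j) {
    double w = cB[j - 1] * nA;
    acc += (j == 1 ? gap_open + gap_extend : gap_extend) * w;
    M(0, j) = NEG_INF;
    X(0, j) = NEG_INF;
    Y(0, j) = acc;
    tY(0, j) = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= la; ++i) {
    double wX = cA[i - 1] * nB;
    for (int j = 1; j <= lb; ++j) {
      double wY = cB[j - 1] * nA;
      double best = M(i - 1, j - 1);
      int arg = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); arg = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); arg = 2; }
      M(i, j) = S(i - 1, j - 1) + best;
      tM(i, j) = arg;

      best = M(i - 1, j) + (gap_open + gap_extend) * wX;
      arg = 0;
      double cand = X(i - 1, j) + gap_extend * wX;
      if (cand > best) { best = cand; arg = 1; }
      cand = Y(i - 1, j) + (gap_open + gap_extend) * wX;
      if (cand > best) { best = cand; arg = 2; }
      X(i, j) = best;
      tX(i, j) = arg;

      best = M(i, j - 1) + (gap_open + gap_extend) * wY;
      arg = 0;
      cand = X(i, j - 1) + (gap_open + gap_extend) * wY;
      if (cand > best) { best = cand; arg = 1; }
      cand = Y(i, j - 1) + gap_extend * wY;
      if (cand > best) { best = cand; arg = 2; }
      Y(i, j) = best;
      tY(i, j) = arg;
    }
  }

  double score = M(la, lb);
  int state = 0;
  if (X(la, lb) > score) { score = X(la, lb); state = 1; }
  if (Y(la, lb) > score) { score = Y(la, lb); state = 2; }

  std::vector<int> pa, pb;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tM(i, j);
      pa.push_back(i); pb.push_back(j);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      int prev = tX(i, j);
      pa.push_back(i); pb.push_back(0);
      --i;
      state = prev;
    } else {
      int prev = tY(i, j);
      pa.push_back(0); pb.push_back(j);
      --j;
      state = prev;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());

  return List::create(_["score"] = score,
                      _["a"] = IntegerVector(pa.begin(), pa.end()),
                      _["b"] = IntegerVector(pb.begin(), pb.end()));
}

// Unit-cost global edit distance (substitution 1, indel 1, match 0) between
// two integer-coded strings.
// [[Rcpp::export]]
int edit_distance_cpp(IntegerVector a, IntegerVector b) {
  int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
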