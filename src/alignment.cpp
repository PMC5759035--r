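// Affine-gap pairwise alignment with USEARCH-like identity bookkeeping.
//
// Gap cost convention: a gap of length L costs gap_open + L * gap_extend
// (both positive). Identity is matching columns / alignment columns after
// terminal-gap columns are stripped; 'N' never counts as a match.
//
// Modes:
//   global      - Needleman-Wunsch over both sequences end to end
//   semiglobal  - the query (a) is aligned end to end, gaps at the
//                 subject's (b) ends are free (glocal)

#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

static const double NINF = -1e18;

enum State { SM = 0, SX = 1, SY = 2 };  // match/mismatch, gap-in-b, gap-in-a

struct AlnResult {
  double score;
  int matches;
  int columns;        // after terminal-gap stripping
  int query_cols;     // query bases inside the stripped region
};

static inline int enc(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2;
  case 'T': return 3; default: return 4;  // N and anything else
  }
}

static AlnResult align_one(const std::string &a, const std::string &b,
                           double match, double mismatch,
                           double gap_open, double gap_extend,
                           bool semiglobal) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> ea(n), eb(m);
  for (int i = 0; i < n; ++i) ea[i] = enc(a[i]);
  for (int j = 0; j < m; ++j) eb[j] = enc(b[j]);

  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NINF), X((n + 1) * W, NINF),
      Y((n + 1) * W, NINF);
  // traceback: predecessor state per cell per state
  std::vector<unsigned char> tM((n + 1) * W), tX((n + 1) * W),
      tY((n + 1) * W);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -(gap_open + gap_extend * i);
    tX[i * W] = (i == 1) ? SM : SX;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = semiglobal ? 0.0 : -(gap_open + gap_extend * j);
    tY[j] = (j == 1) ? SM : SY;
  }

  for (int i = 1; i <= n; ++i) {
    const int r = i * W, rp = (i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      // M
      double best = M[rp + j - 1]; unsigned char bs = SM;
      if (X[rp + j - 1] > best) { best = X[rp + j - 1]; bs = SX; }
      if (Y[rp + j - 1] > best) { best = Y[rp + j - 1]; bs = SY; }
      double sub = (ea[i - 1] == eb[j - 1] && ea[i - 1] != 4) ? match
                                                             : mismatch;
      M[r + j] = best + sub; tM[r + j] = bs;
      // X: consume a[i] against a gap
      double xo = M[rp + j] - gap_open - gap_extend; unsigned char xs = SM;
      double xe = X[rp + j] - gap_extend;
      double xy = Y[rp + j] - gap_open - gap_extend;
      double xb = xo;
      if (xe > xb) { xb = xe; xs = SX; }
      if (xy > xb) { xb = xy; xs = SY; }
      X[r + j] = xb; tX[r + j] = xs;
      // Y: consume b[j] against a gap
      double yo = M[r + j - 1] - gap_open - gap_extend; unsigned char ys = SM;
      double ye = Y[r + j - 1] - gap_extend;
      double yx = X[r + j - 1] - gap_open - gap_extend;
      double yb = yo;
      if (ye > yb) { yb = ye; ys = SY; }
      if (yx > yb) { yb = yx; ys = SX; }
      Y[r + j] = yb; tY[r + j] = ys;
    }
  }

  // end cell/state
  int ei = n, ej = m; unsigned char es = SM; double best = NINF;
  if (semiglobal) {
    // free trailing subject gaps: end anywhere on row n (M or X)
    for (int j = 0; j <= m; ++j) {
      if (M[n * W + j] > best) { best = M[n * W + j]; ej = j; es = SM; }
      if (X[n * W + j] > best) { best = X[n * W + j]; ej = j; es = SX; }
    }
  } else {
    best = M[n * W + m]; es = SM;
    if (X[n * W + m] > best) { best = X[n * W + m]; es = SX; }
    if (Y[n * W + m] > best) { best = Y[n * W + m]; es = SY; }
  }

  // traceback, recording column types from the end
  std::vector<unsigned char> cols;  // 0 match, 1 mismatch, 2 gap-in-b, 3 gap-in-a
  cols.reserve(n + m);
  int i = ei, j = ej; unsigned char s = es;
  while (i > 0 || j > 0) {
    if (semiglobal && i == 0) break;  // free leading subject bases
    unsigned char prev;
    if (s == SM) {
      prev = tM[i * W + j];
      bool is_match = (ea[i - 1] == eb[j - 1] && ea[i - 1] != 4);
      cols.push_back(is_match ? 0 : 1);
      --i; --j;
    } else if (s == SX) {
      prev = tX[i * W + j];
      cols.push_back(2);
      --i;
    } else {
      prev = tY[i * W + j];
      cols.push_back(3);
      --j;
    }
    s = prev;
  }
  // cols is reversed; strip terminal gap runs from both ends
  int lo = 0, hi = (int)cols.size() - 1;
  while (hi >= lo && cols[(size_t)(cols.size() - 1 - lo)] >= 2) ++lo;
  while (hi >= lo && cols[(size_t)(cols.size() - 1 - hi)] >= 2) --hi;

  AlnResult res;
  res.score = best;
  res.matches = 0; res.columns = 0; res.query_cols = 0;
  for (int kk = lo; kk <= hi; ++kk) {
    unsigned char c = cols[(size_t)(cols.size() - 1 - kk)];
    ++res.columns;
    if (c == 0) ++res.matches;
    if (c <= 2) ++res.query_cols;  // columns consuming a query base
  }
  return res;
}

// [[Rcpp::export(name = ".align_many_cpp")]]
NumericMatrix align_many_cpp(CharacterVector queries, std::string subject,
                             double match, double mismatch,
                             double gap_open, double gap_extend,
                             bool semiglobal) {
  const int n = queries.size();
  NumericMatrix out(n, 4);
  colnames(out) = CharacterVector::create("score", "matches", "columns",
                                          "query_cols");
  for (int q = 0; q < n; ++q) {
    std::string a = as<std::string>(queries[q]);
    AlnResult r = align_one(a, subject, match, mismatch, gap_open,
                            gap_extend, semiglobal);
    out(q, 0) = r.score; out(q, 1) = r.matches;
    out(q, 2) = r.columns; out(q, 3) = r.query_cols;
  }
  return out;
}
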