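#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh). A gap run of length L costs
// gap_open + L * gap_extend (both parameters are negative contributions
// added to the score). Traceback tie-break: diagonal, then up (gap in b),
// then left (gap in a) -- fixed so outputs are bit-reproducible.

static const double NEG = -1e30;

static inline double subscore(char x, char y, double match, double mismatch) {
  if (x == 'N' || y == 'N') return 0.0;  // ambiguous: neutral
  return (x == y) ? match : mismatch;
}

// [[Rcpp::export]]
List nw_affine_cpp(std::string a, std::string b,
                   double match, double mismatch,
                   double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  // matrices stored row-major, (n+1) x (m+1)
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG);  // gap in b (consume a)
  std::vector<double> Y((n + 1) * (m + 1), NEG);  // gap in a (consume b)
  // traceback: predecessor state for each matrix (0=M,1=X,2=Y)
  std::vector<signed char> tbM((n + 1) * (m + 1), -1);
  std::vector<signed char> tbX((n + 1) * (m + 1), -1);
  std::vector<signed char> tbY((n + 1) * (m + 1), -1);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[idx(i, 0)] = gap_open + i * gap_extend;
    tbX[idx(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[idx(0, j)] = gap_open + j * gap_extend;
    tbY[idx(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = subscore(a[i - 1], b[j - 1], match, mismatch);
      // M: from any state diagonally; priority M > X > Y on ties
      double dM = M[idx(i - 1, j - 1)], dX = X[idx(i - 1, j - 1)],
             dY = Y[idx(i - 1, j - 1)];
      double best = dM; signed char st = 0;
      if (dX > best) { best = dX; st = 1; }
      if (dY > best) { best = dY; st = 2; }
      M[idx(i, j)] = best + s; tbM[idx(i, j)] = st;
      // X: consume a[i-1] against a gap
      double oM = M[idx(i - 1, j)] + gap_open + gap_extend;
      double oX = X[idx(i - 1, j)] + gap_extend;
      double oY = Y[idx(i - 1, j)] + gap_open + gap_extend;
      best = oM; st = 0;
      if (oX > best) { best = oX; st = 1; }
      if (oY > best) { best = oY; st = 2; }
      X[idx(i, j)] = best; tbX[idx(i, j)] = st;
      // Y: consume b[j-1] against a gap
      double pM = M[idx(i, j - 1)] + gap_open + gap_extend;
      double pX = X[idx(i, j - 1)] + gap_open + gap_extend;
      double pY = Y[idx(i, j - 1)] + gap_extend;
      best = pM; st = 0;
      if (pX > best) { best = pX; st = 1; }
      if (pY > best) { best = pY; st = 2; }
      Y[idx(i, j)] = best; tbY[idx(i, j)] = st;
    }
  }
  double fM = M[idx(n, m)], fX = X[idx(n, m)], fY = Y[idx(n, m)];
  double score = fM; int state = 0;
  if (fX > score) { score = fX; state = 1; }
  if (fY > score) { score = fY; state = 2; }

  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char prev = tbM[idx(i, j)];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      signed char prev = tbX[idx(i, j)];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = prev;
    } else {
      signed char prev = tbY[idx(i, j)];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = score);
}

// Score-only variant, used to test whether the ungapped column stack of
// equal-length sequences is already optimal.
// [[Rcpp::export]]
double nw_affine_score_cpp(std::string a, std::string b,
                           double match, double mismatch,
                           double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  std::vector<double> Mp(m + 1, NEG), Xp(m + 1, NEG), Yp(m + 1, NEG);
  std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);
  Mp[0] = 0.0;
  for (int j = 1; j <= m; ++j) Yp[j] = gap_open + j * gap_extend;
  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG; Yc[0] = NEG;
    Xc[0] = gap_open + i * gap_extend;
    for (int j = 1; j <= m; ++j) {
      double s = subscore(a[i - 1], b[j - 1], match, mismatch);
      Mc[j] = s + std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
      Xc[j] = std::max(std::max(Mp[j], Yp[j]) + gap_open + gap_extend,
                       Xp[j] + gap_extend);
      Yc[j] = std::max(std::max(Mc[j - 1], Xc[j - 1]) + gap_open + gap_extend,
                       Yc[j - 1] + gap_extend);
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  return std::max(Mp[m], std::max(Xp[m], Yp[m]));
}

// Profile-profile global alignment for progressive MSA. Profiles are
// 6 x width count matrices (rows A,C,G,T,N,-). Column pairs score the
// average substitution score over base pairs; gaps and N score 0.
// Returns, for each merged column, the source column in A and B (0 = new
// gap). Affine gap costs as above.
// [[Rcpp::export]]
List profile_nw_cpp(NumericMatrix A, NumericMatrix B,
                    double match, double mismatch,
                    double gap_open, double gap_extend) {
  const int n = A.ncol(), m = B.ncol();
  double nA = 0, nB = 0;
  for (int r = 0; r < 6; ++r) { nA += A(r, 0); nB += B(r, 0); }

  // pairwise column score matrix
  std::vector<double> S(n * m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double tot = 0;
      for (int x = 0; x < 4; ++x) {
        if (A(x, i) == 0) continue;
        for (int y = 0; y < 4; ++y) {
          if (B(y, j) == 0) continue;
          tot += A(x, i) * B(y, j) * ((x == y) ? match : mismatch);
        }
      }
      S[i * m + j] = tot / (nA * nB);
    }
  }
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  std::vector<signed char> tbM((n + 1) * (m + 1), -1),
      tbX((n + 1) * (m + 1), -1), tbY((n + 1) * (m + 1), -1);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[idx(i, 0)] = gap_open + i * gap_extend;
    tbX[idx(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[idx(0, j)] = gap_open + j * gap_extend;
    tbY[idx(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = S[(i - 1) * m + (j - 1)];
      double dM = M[idx(i - 1, j - 1)], dX = X[idx(i - 1, j - 1)],
             dY = Y[idx(i - 1, j - 1)];
      double best = dM; signed char st = 0;
      if (dX > best) { best = dX; st = 1; }
      if (dY > best) { best = dY; st = 2; }
      M[idx(i, j)] = best + s; tbM[idx(i, j)] = st;
      double oM = M[idx(i - 1, j)] + gap_open + gap_extend;
      double oX = X[idx(i - 1, j)] + gap_extend;
      double oY = Y[idx(i - 1, j)] + gap_open + gap_extend;
      best = oM; st = 0;
      if (oX > best) { best = oX; st = 1; }
      if (oY > best) { best = oY; st = 2; }
      X[idx(i, j)] = best; tbX[idx(i, j)] = st;
      double pM = M[idx(i, j - 1)] + gap_open + gap_extend;
      double pX = X[idx(i, j - 1)] + gap_open + gap_extend;
      double pY = Y[idx(i, j - 1)] + gap_extend;
      best = pM; st = 0;
      if (pX > best) { best = pX; st = 1; }
      if (pY > best) { best = pY; st = 2; }
      Y[idx(i, j)] = best; tbY[idx(i, j)] = st;
    }
  }
  double fM = M[idx(n, m)], fX = X[idx(n, m)], fY = Y[idx(n, m)];
  int state = 0; double score = fM;
  if (fX > score) { score = fX; state = 1; }
  if (fY > score) { score = fY; state = 2; }
  std::vector<int> ca, cb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char prev = tbM[idx(i, j)];
      ca.push_back(i); cb.push_back(j); --i; --j; state = prev;
    } else if (state == 1) {
      signed char prev = tbX[idx(i, j)];
      ca.push_back(i); cb.push_back(0); --i; state = prev;
    } else {
      signed char prev = tbY[idx(i, j)];
      ca.push_back(0); cb.push_back(j); --j; state = prev;
    }
  }
  std::reverse(ca.begin(), ca.end());
  std::reverse(cb.begin(), cb.end());
  return List::create(_["cols_a"] = ca, _["cols_b"] = cb,
                      _["score"] = score);
}

// Hamming-style mismatch count between equal-length gap-free strings;
// used by distance and variant code paths where no alignment is needed.
// [[Rcpp::export]]
IntegerVector pair_site_counts_cpp(std::string a, std::string b) {
  int diff = 0, comp = 0;
  const int n = a.size();
  for (int i = 0; i < n; ++i) {
    char x = a[i], y = b[i];
    bool xb = (x == 'A' || x == 'C' || x == 'G' || x == 'T');
    bool yb = (y == 'A' || y == 'C' || y == 'G' || y == 'T');
    if (xb && yb) { ++comp; if (x != y) ++diff; }
  }
  return IntegerVector::create(diff, comp);
}

// Exact score-only NW restricted to the band |i - j| <= band, for
// equal-length sequences. Used by the trivial-stack optimality test:
// any alignment using more than `band` gap bases per row is provably
// worse than the ungapped stack, so searching the band decides
// optimality exactly.
// [[Rcpp::export]]
double nw_affine_score_banded_cpp(std::string a, std::string b,
                                  double match, double mismatch,
                                  double gap_open, double gap_extend,
                                  int band) {
  const int n = a.size(), m = b.size();
  const int W = 2 * band + 1;
  std::vector<double> Mp(W, NEG), Xp(W, NEG), Yp(W, NEG);
  std::vector<double> Mc(W, NEG), Xc(W, NEG), Yc(W, NEG);
  // column offset: for row i, j ranges over [i-band, i+band]; slot
  // index s = j - (i - band)
  Mp[band] = 0.0;  // i=0, j=0
  for (int j = 1; j <= band && j <= m; ++j)
    Yp[band + j] = gap_open + j * gap_extend;
  for (int i = 1; i <= n; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Xc.begin(), Xc.end(), NEG);
    std::fill(Yc.begin(), Yc.end(), NEG);
    int jlo = std::max(0, i - band), jhi = std::min(m, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      int s = j - (i - band);           // slot in current row
      int sp = j - (i - 1 - band);      // same j in previous row
      if (j == 0) {
        Xc[s] = gap_open + i * gap_extend;
        continue;
      }
      double sc = subscore(a[i - 1], b[j - 1], match, mismatch);
      double dM = NEG, dX = NEG, dY = NEG;
      if (sp - 1 >= 0 && sp - 1 < W) {
        dM = Mp[sp - 1]; dX = Xp[sp - 1]; dY = Yp[sp - 1];
      }
      Mc[s] = sc + std::max(dM, std::max(dX, dY));
      double uM = NEG, uX = NEG, uY = NEG;
      if (sp >= 0 && sp < W) { uM = Mp[sp]; uX = Xp[sp]; uY = Yp[sp]; }
      Xc[s] = std::max(std::max(uM, uY) + gap_open + gap_extend,
                       uX + gap_extend);
      if (s - 1 >= 0) {
        Yc[s] = std::max(std::max(Mc[s - 1], Xc[s - 1]) +
                             gap_open + gap_extend,
                         Yc[s - 1] + gap_extend);
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  int s = m - (n - band);
  if (s < 0 || s >= W) return NEG;
  return std::max(Mp[s], std::max(Xp[s], Yp[s]));
}
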