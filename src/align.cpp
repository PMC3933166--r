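#include <Rcpp.h>
using namespace Rcpp;

// Global pairwise alignment (Needleman-Wunsch / Gotoh) over arbitrary
// single-byte alphabets. Gap of length L costs gap_open + (L - 1) * gap_ext,
// so gap_open == gap_ext gives a linear gap penalty. Tie-break on traceback
// is deterministic: diagonal first, then gap in b (consume a), then gap in a.

// [[Rcpp::export]]
List align_pair_cpp(std::string a, std::string b,
                    double match, double mismatch,
                    double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  // 0 = M (diagonal), 1 = X (gap in b, consumes a), 2 = Y (gap in a)
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[at(i, 0)] = gap_open + (i - 1) * gap_ext;
  for (int j = 1; j <= m; ++j) Y[at(0, j)] = gap_open + (j - 1) * gap_ext;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)],
             dY = Y[at(i - 1, j - 1)];
      M[at(i, j)] = std::max(dM, std::max(dX, dY)) + s;
      double xo = M[at(i - 1, j)] + gap_open, xe = X[at(i - 1, j)] + gap_ext,
             xy = Y[at(i - 1, j)] + gap_open;
      X[at(i, j)] = std::max(xo, std::max(xe, xy));
      double yo = M[at(i, j - 1)] + gap_open, ye = Y[at(i, j - 1)] + gap_ext,
             yx = X[at(i, j - 1)] + gap_open;
      Y[at(i, j)] = std::max(yo, std::max(ye, yx));
    }
  }

  // traceback
  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  double best = std::max(M[at(i, j)], std::max(X[at(i, j)], Y[at(i, j)]));
  int state;  // prefer M, then X, then Y
  if (M[at(i, j)] >= X[at(i, j)] && M[at(i, j)] >= Y[at(i, j)])
    state = 0;
  else if (X[at(i, j)] >= Y[at(i, j)])
    state = 1;
  else
    state = 2;

  const double EPS = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) {  // only gaps remain
        state = (i > 0) ? 1 : 2;
        continue;
      }
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double target = M[at(i, j)] - s;
      --i; --j;
      if (std::abs(M[at(i, j)] - target) < EPS)
        state = 0;
      else if (std::abs(X[at(i, j)] - target) < EPS)
        state = 1;
      else
        state = 2;
    } else if (state == 1) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      double cur = X[at(i, j)];
      --i;
      if (i >= 0 && std::abs(M[at(i, j)] + gap_open - cur) < EPS)
        state = 0;
      else if (std::abs(X[at(i, j)] + gap_ext - cur) < EPS)
        state = 1;
      else
        state = 2;
      if (i == 0 && j == 0) break;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      double cur = Y[at(i, j)];
      --j;
      if (std::abs(M[at(i, j)] + gap_open - cur) < EPS)
        state = 0;
      else if (std::abs(Y[at(i, j)] + gap_ext - cur) < EPS)
        state = 2;
      else
        state = 1;
      if (i == 0 && j == 0) break;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = best);
}

// Count matching positions between two equal-length strings. Columns where
// both rows are gaps ('-') are never counted. A column with one gap is
// skipped under pairwise deletion, otherwise counted as a mismatch.
// Returns (matches, counted).
// [[Rcpp::export]]
IntegerVector identity_counts_cpp(std::string a, std::string b,
                                  bool pairwise_deletion) {
  if (a.size() != b.size()) stop("sequences must have equal length");
  int matches = 0, counted = 0;
  for (size_t k = 0; k < a.size(); ++k) {
    bool ga = (a[k] == '-'), gb = (b[k] == '-');
    if (ga && gb) continue;
    if (pairwise_deletion && (ga || gb)) continue;
    ++counted;
    if (a[k] == b[k]) ++matches;
  }
  return IntegerVector::create(matches, counted);
}
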