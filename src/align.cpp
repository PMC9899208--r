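#include <Rcpp.h>
#include <cstring>
#include <limits>
using namespace Rcpp;

// Global (end-to-end) pairwise alignment with affine gap costs
// (Gotoh three-state DP). A gap of length L costs gap_open + gap_ext * L,
// matching the opening/extension convention of the common DNA and protein
// aligners. Traceback prefers diagonal, then a gap in the second sequence,
// then a gap in the first, which makes results deterministic under ties.

namespace {

const double NEG_INF = -std::numeric_limits<double>::max() / 4.0;

struct CharMap {
  int idx[256];
  CharMap(const std::string &alphabet) {
    for (int i = 0; i < 256; ++i) idx[i] = -1;
    for (size_t i = 0; i < alphabet.size(); ++i)
      idx[(unsigned char)alphabet[i]] = (int)i;
  }
  int at(char c) const {
    int v = idx[(unsigned char)c];
    if (v < 0) stop("character '%s' not in scoring alphabet",
                    std::string(1, c).c_str());
    return v;
  }
};

struct AlignResult {
  std::string a, b;
  double score;
};

AlignResult gotoh(const std::string &a, const std::string &b,
                  const NumericMatrix &sub, const CharMap &cm,
                  double gap_open, double gap_ext) {
  const int n = (int)a.size(), m = (int)b.size();
  const double open1 = gap_open + gap_ext;  // cost of a length-1 gap

  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) ai[i] = cm.at(a[i]);
  for (int j = 0; j < m; ++j) bi[j] = cm.at(b[j]);

  // Three layers: M (diagonal), X (gap in b: consume a), Y (gap in a).
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  const int W = m + 1;
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i * W] = -(gap_open + gap_ext * i);
  for (int j = 1; j <= m; ++j) Y[j] = -(gap_open + gap_ext * j);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1);
      const int up = (i - 1) * W + j, lf = i * W + (j - 1);
      double best = M[d];
      if (X[d] > best) best = X[d];
      if (Y[d] > best) best = Y[d];
      M[c] = best + sub(ai[i - 1], bi[j - 1]);
      double x = M[up] - open1;
      if (X[up] - gap_ext > x) x = X[up] - gap_ext;
      if (Y[up] - open1 > x) x = Y[up] - open1;
      X[c] = x;
      double y = M[lf] - open1;
      if (Y[lf] - gap_ext > y) y = Y[lf] - gap_ext;
      if (X[lf] - open1 > y) y = X[lf] - open1;
      Y[c] = y;
    }
  }

  // Traceback.
  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  const int end = n * W + m;
  int state;  // 0 = M, 1 = X, 2 = Y
  double sc = M[end];
  state = 0;
  if (X[end] > sc) { sc = X[end]; state = 1; }
  if (Y[end] > sc) { sc = Y[end]; state = 2; }
  const double eps = 1e-9;

  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) stop("traceback failure");  // M undefined on edges
      const int d = (i - 1) * W + (j - 1);
      const double need = M[i * W + j] - sub(ai[i - 1], bi[j - 1]);
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      if (std::abs(M[d] - need) < eps) state = 0;
      else if (std::abs(X[d] - need) < eps) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      const int up = (i - 1) * W + j;
      const double cur = X[i * W + j];
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      if (i - 1 == 0 && j == 0) { --i; break; }
      if (std::abs(M[up] - (cur + open1)) < eps) state = 0;
      else if (std::abs(X[up] - (cur + gap_ext)) < eps) state = 1;
      else state = 2;
      --i;
    } else {
      const int lf = i * W + (j - 1);
      const double cur = Y[i * W + j];
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      if (i == 0 && j - 1 == 0) { --j; break; }
      if (std::abs(M[lf] - (cur + open1)) < eps) state = 0;
      else if (std::abs(Y[lf] - (cur + gap_ext)) < eps) state = 2;
      else state = 1;
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return AlignResult{ra, rb, sc};
}

// identical aligned columns; when exclude_n is true an 'N'/'N' column is
// never identical (masked bases must not inflate identity)
double identity_from_alignment(const std::string &ra, const std::string &rb,
                               bool exclude_n) {
  int id = 0;
  const int L = (int)ra.size();
  for (int k = 0; k < L; ++k) {
    if (ra[k] == '-' || rb[k] == '-') continue;
    if (ra[k] == rb[k] && !(exclude_n && ra[k] == 'N')) ++id;
  }
  return 100.0 * (double)id / (double)L;
}

std::string alphabet_of(const NumericMatrix &sub) {
  CharacterVector rn = rownames(sub);
  std::string alphabet;
  for (int i = 0; i < rn.size(); ++i) {
    std::string s = as<std::string>(rn[i]);
    if (s.size() != 1) stop("scoring matrix row names must be single characters");
    alphabet.push_back(s[0]);
  }
  return alphabet;
}

}  // namespace

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, NumericMatrix sub,
                  double gap_open, double gap_ext) {
  CharMap cm(alphabet_of(sub));
  AlignResult r = gotoh(a, b, sub, cm, gap_open, gap_ext);
  return List::create(_["aligned_a"] = r.a, _["aligned_b"] = r.b,
                      _["score"] = r.score);
}

// [[Rcpp::export]]
NumericVector pair_identities_cpp(CharacterVector seqs, IntegerMatrix pairs,
                                  NumericMatrix sub, double gap_open,
                                  double gap_ext, bool exclude_n) {
  CharMap cm(alphabet_of(sub));
  const int np = pairs.nrow();
  NumericVector out(np);
  std::vector<std::string> ss(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) ss[i] = as<std::string>(seqs[i]);
  for (int p = 0; p < np; ++p) {
    const std::string &a = ss[pairs(p, 0) - 1];
    const std::string &b = ss[pairs(p, 1) - 1];
    AlignResult r = gotoh(a, b, sub, cm, gap_open, gap_ext);
    out[p] = identity_from_alignment(r.a, r.b, exclude_n);
    if (p % 256 == 0) checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
NumericVector hamming_identities_cpp(CharacterVector seqs, IntegerMatrix pairs,
                                     bool exclude_n) {
  const int np = pairs.nrow();
  NumericVector out(np);
  std::vector<std::string> ss(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) ss[i] = as<std::string>(seqs[i]);
  for (int p = 0; p < np; ++p) {
    const std::string &a = ss[pairs(p, 0) - 1];
    const std::string &b = ss[pairs(p, 1) - 1];
    if (a.size() != b.size())
      stop("ungapped identity requires equal-length fragments");
    int id = 0;
    for (size_t k = 0; k < a.size(); ++k)
      if (a[k] == b[k] && !(exclude_n && a[k] == 'N')) ++id;
    out[p] = 100.0 * (double)id / (double)a.size();
  }
  return out;
}
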