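#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Gotoh affine-gap local alignment. A gap of length L costs
// gap_open + L * gap_extend (BLAST convention). Traceback ties are broken
// diagonal > up (gap in b, consumes a) > left (gap in a, consumes b), and the
// traceback start cell is the earliest (smallest i, then j) maximum, so runs
// are reproducible byte-for-byte.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static std::vector<int> encode(const std::string &s, const std::string &alphabet,
                               const char *label) {
  int lut[256];
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    lut[(unsigned char)alphabet[i]] = (int)i;
  std::vector<int> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int v = lut[(unsigned char)s[i]];
    if (v < 0)
      stop("character '%s' in %s sequence not in scoring alphabet",
           std::string(1, s[i]).c_str(), label);
    out[i] = v;
  }
  return out;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, NumericMatrix mat,
                  std::string alphabet, double gap_open, double gap_extend,
                  int band, int diag, bool traceback) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  std::vector<int> ea = encode(a, alphabet, "first"), eb = encode(b, alphabet, "second");
  const int na = (int)alphabet.size();
  if (mat.nrow() != na || mat.ncol() != na)
    stop("scoring matrix does not match alphabet size");

  const bool banded = band >= 0;
  // H, E, F over (n+1) x (m+1); trace codes: 0 stop, 1 diag, 2 up, 3 left
  // E: gap in a (horizontal, consumes b); F: gap in b (vertical, consumes a)
  std::vector<double> H((size_t)(n + 1) * (m + 1), 0.0);
  std::vector<double> E((size_t)(n + 1) * (m + 1), NEG_INF);
  std::vector<double> F((size_t)(n + 1) * (m + 1), NEG_INF);
  std::vector<signed char> TH, TE, TF;
  if (traceback) {
    TH.assign((size_t)(n + 1) * (m + 1), 0);
    TE.assign((size_t)(n + 1) * (m + 1), 0); // 0: open from H, 1: extend
    TF.assign((size_t)(n + 1) * (m + 1), 0);
  }
  auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  const double gofirst = gap_open + gap_extend;

  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (banded) {
      jlo = std::max(1, i + diag - band);
      jhi = std::min(m, i + diag + band);
      if (jlo > jhi) continue;
    }
    for (int j = jlo; j <= jhi; ++j) {
      size_t c = idx(i, j);
      // E: gap consuming b[j]
      double e_open = (!banded || std::abs(j - 1 - i - diag) <= band)
                          ? H[idx(i, j - 1)] - gofirst : NEG_INF;
      double e_ext = E[idx(i, j - 1)] - gap_extend;
      double e = std::max(e_open, e_ext);
      E[c] = e;
      if (traceback) TE[c] = (e_ext > e_open) ? 1 : 0;
      // F: gap consuming a[i]
      double f_open = (!banded || std::abs(j - (i - 1) - diag) <= band)
                          ? H[idx(i - 1, j)] - gofirst : NEG_INF;
      double f_ext = F[idx(i - 1, j)] - gap_extend;
      double f = std::max(f_open, f_ext);
      F[c] = f;
      if (traceback) TF[c] = (f_ext > f_open) ? 1 : 0;
      // H
      double dscore = H[idx(i - 1, j - 1)] + mat(ea[i - 1], eb[j - 1]);
      double h = 0.0;
      signed char th = 0;
      if (dscore > h) { h = dscore; th = 1; }
      if (f > h) { h = f; th = 2; }
      if (e > h) { h = e; th = 3; }
      H[c] = h;
      if (traceback) TH[c] = th;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (!traceback || best <= 0.0) {
    return List::create(_["score"] = best, _["a_start"] = NA_INTEGER,
                        _["a_end"] = NA_INTEGER, _["b_start"] = NA_INTEGER,
                        _["b_end"] = NA_INTEGER, _["n_ident"] = 0,
                        _["n_cols"] = 0, _["a_aln"] = "", _["b_aln"] = "");
  }

  // traceback from (bi, bj) in state H
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  int n_ident = 0, n_cols = 0;
  std::string aal, bal;
  int a_end = bi, b_end = bj;
  while (true) {
    size_t c = idx(i, j);
    if (state == 0) {
      signed char t = TH[c];
      if (t == 0) break;
      if (t == 1) {
        aal.push_back(a[i - 1]);
        bal.push_back(b[j - 1]);
        if (a[i - 1] == b[j - 1]) ++n_ident;
        ++n_cols;
        --i; --j;
      } else if (t == 2) {
        state = 2;
      } else {
        state = 1;
      }
    } else if (state == 1) { // E: gap in a, consumes b[j]
      aal.push_back('-');
      bal.push_back(b[j - 1]);
      ++n_cols;
      signed char t = TE[c];
      --j;
      state = (t == 1) ? 1 : 0;
    } else { // F: gap in b, consumes a[i]
      aal.push_back(a[i - 1]);
      bal.push_back('-');
      ++n_cols;
      signed char t = TF[c];
      --i;
      state = (t == 1) ? 2 : 0;
    }
  }
  std::reverse(aal.begin(), aal.end());
  std::reverse(bal.begin(), bal.end());
  // i, j are now positions just before the alignment start
  return List::create(_["score"] = best, _["a_start"] = i + 1,
                      _["a_end"] = a_end, _["b_start"] = j + 1,
                      _["b_end"] = b_end, _["n_ident"] = n_ident,
                      _["n_cols"] = n_cols, _["a_aln"] = aal, _["b_aln"] = bal);
}

// Score-only batch: one query against many subjects (two-row DP, O(min) memory).
// [[Rcpp::export]]
NumericVector sw_score_many_cpp(std::string a, CharacterVector bs,
                                NumericMatrix mat, std::string alphabet,
                                double gap_open, double gap_extend) {
  const int n = (int)a.size();
  if (n == 0) stop("empty sequence");
  std::vector<int> ea = encode(a, alphabet, "first");
  const int na = (int)alphabet.size();
  if (mat.nrow() != na || mat.ncol() != na)
    stop("scoring matrix does not match alphabet size");
  const double gofirst = gap_open + gap_extend;
  NumericVector out(bs.size());
  for (R_xlen_t q = 0; q < bs.size(); ++q) {
    std::string b = as<std::string>(bs[q]);
    const int m = (int)b.size();
    if (m == 0) { out[q] = 0.0; continue; }
    std::vector<int> eb = encode(b, alphabet, "second");
    std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
    std::vector<double> Fprev(m + 1, NEG_INF), Fcur(m + 1, NEG_INF);
    double best = 0.0;
    for (int i = 1; i <= n; ++i) {
      double e = NEG_INF;
      Hcur[0] = 0.0;
      Fcur[0] = NEG_INF;
      for (int j = 1; j <= m; ++j) {
        e = std::max(Hcur[j - 1] - gofirst, e - gap_extend);
        double f = std::max(Hprev[j] - gofirst, Fprev[j] - gap_extend);
        Fcur[j] = f;
        double h = Hprev[j - 1] + mat(ea[i - 1], eb[j - 1]);
        if (h < 0.0) h = 0.0;
        if (f > h) h = f;
        if (e > h) h = e;
        Hcur[j] = h;
        if (h > best) best = h;
      }
      std::swap(Hprev, Hcur);
      std::swap(Fprev, Fcur);
    }
    out[q] = best;
  }
  return out;
}
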