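#include <Rcpp.h>
#include <cstring>
#include <vector>

using namespace Rcpp;

// Ends-free pairwise protein alignment with affine gaps (Gotoh). Terminal
// gaps are free, so the optimum is the best-scoring contiguous aligned core;
// gap runs inside the core cost open + extend * length. Traceback prefers
// diagonal > up (gap in query) > left (gap in pattern) for determinism.
//
// Returns one row per pattern: score, matches, aligned_columns,
// pattern_span, query_span.

static const double NEG = -1e18;

struct AlnStats {
  double score;
  int matches, columns, a_span, b_span;
};

static AlnStats align_one(const char *a, int n, const char *b, int m,
                          const std::vector<double> &sub, const int *code,
                          double go, double ge) {
  // DP over states: M (a_i aligned to b_j), E (gap in a, consumes b),
  // F (gap in b, consumes a). Row-major (n+1) x (m+1).
  const int w = m + 1;
  std::vector<double> M((n + 1) * w, NEG), E((n + 1) * w, NEG),
      F((n + 1) * w, NEG);
  double best = 0;
  int bi = 0, bj = 0;
  const double gopen = go + ge;
  for (int i = 1; i <= n; ++i) {
    const int ci = code[(unsigned char)a[i - 1]];
    for (int j = 1; j <= m; ++j) {
      const int cj = code[(unsigned char)b[j - 1]];
      const double s = sub[ci * 32 + cj];
      double diag = 0;  // leading gaps are free: a core may start anywhere
      const int dji = (i - 1) * w + (j - 1);
      if (M[dji] > diag) diag = M[dji];
      if (E[dji] > diag) diag = E[dji];
      if (F[dji] > diag) diag = F[dji];
      const int ij = i * w + j;
      M[ij] = diag + s;
      const int lft = i * w + (j - 1), up = (i - 1) * w + j;
      E[ij] = std::max(M[lft] - gopen, E[lft] - ge);
      F[ij] = std::max(M[up] - gopen, F[up] - ge);
      if (M[ij] > best) { best = M[ij]; bi = i; bj = j; }
    }
  }
  AlnStats out{0, 0, 0, 0, 0};
  if (best <= 0) return out;  // nothing aligns above the empty core
  out.score = best;
  // traceback from the best M cell to the start of its core
  int i = bi, j = bj, a_end = bi, b_end = bj;
  char state = 'M';
  while (true) {
    if (state == 'M') {
      out.columns++;
      if (code[(unsigned char)a[i - 1]] == code[(unsigned char)b[j - 1]] &&
          a[i - 1] == b[j - 1]) {
        out.matches++;
      }
      const int dji = (i - 1) * w + (j - 1);
      const double need = M[i * w + j] -
          sub[code[(unsigned char)a[i - 1]] * 32 + code[(unsigned char)b[j - 1]]];
      i--; j--;
      if (i >= 1 && j >= 1 && M[dji] == need) { state = 'M'; continue; }
      if (i >= 1 && j >= 0 && F[dji] == need) { state = 'F'; continue; }
      if (i >= 0 && j >= 1 && E[dji] == need) { state = 'E'; continue; }
      break;  // core started here (fresh start, value 0)
    } else if (state == 'F') {  // gap in query: consumes a_i, move up
      out.columns++;
      const double cur = F[i * w + j];
      const int up = (i - 1) * w + j;
      i--;
      if (M[up] - (go + ge) == cur) { state = 'M'; continue; }
      state = 'F';
    } else {  // E: gap in pattern, consumes b_j, move left
      out.columns++;
      const double cur = E[i * w + j];
      const int lft = i * w + (j - 1);
      j--;
      if (M[lft] - (go + ge) == cur) { state = 'M'; continue; }
      state = 'E';
    }
  }
  out.a_span = a_end - i;
  out.b_span = b_end - j;
  return out;
}

// [[Rcpp::export]]
NumericMatrix semiglobal_align_batch(CharacterVector patterns,
                                     std::string query,
                                     NumericMatrix sub_matrix,
                                     double gap_open, double gap_extend) {
  // residue lookup from the substitution matrix dimnames
  List dn = sub_matrix.attr("dimnames");
  CharacterVector letters = dn[0];
  const int L = letters.size();
  if (L > 32) stop("substitution matrix too large");
  int code[256];
  for (int i = 0; i < 256; ++i) code[i] = 0;
  for (int i = 0; i < L; ++i) {
    code[(unsigned char)CHAR(STRING_ELT(letters, i))[0]] = i;
  }
  std::vector<double> sub(32 * 32, 0.0);
  for (int i = 0; i < L; ++i) {
    for (int j = 0; j < L; ++j) sub[i * 32 + j] = sub_matrix(i, j);
  }
  const int m = (int)query.size();
  NumericMatrix out(patterns.size(), 5);
  colnames(out) = CharacterVector::create("score", "matches",
                                          "aligned_columns", "pattern_span",
                                          "query_span");
  for (int p = 0; p < patterns.size(); ++p) {
    const char *a = CHAR(STRING_ELT(patterns, p));
    AlnStats st = align_one(a, (int)std::strlen(a), query.c_str(), m, sub,
                            code, gap_open, gap_extend);
    out(p, 0) = st.score;
    out(p, 1) = st.matches;
    out(p, 2) = st.columns;
    out(p, 3) = st.a_span;
    out(p, 4) = st.b_span;
  }
  return out;
}
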