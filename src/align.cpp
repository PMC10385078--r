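#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Unit-cost global alignment (match 0, mismatch 1, gap 1).
// Among all edit-optimal alignments we report the one with the fewest
// columns (i.e. fewest gap columns), so alignment length is deterministic.
// DP state: (edits, columns) compared lexicographically.
static inline void align_pair(const std::string &a, const std::string &b,
                              int &edits, int &cols) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> e_prev(m + 1), e_cur(m + 1);
  std::vector<int> l_prev(m + 1), l_cur(m + 1);
  for (int j = 0; j <= m; ++j) { e_prev[j] = j; l_prev[j] = j; }
  for (int i = 1; i <= n; ++i) {
    e_cur[0] = i; l_cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int ed = e_prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int ld = l_prev[j - 1] + 1;
      int eu = e_prev[j] + 1, lu = l_prev[j] + 1;
      int el = e_cur[j - 1] + 1, ll = l_cur[j - 1] + 1;
      int e = ed, l = ld;
      if (eu < e || (eu == e && lu < l)) { e = eu; l = lu; }
      if (el < e || (el == e && ll < l)) { e = el; l = ll; }
      e_cur[j] = e; l_cur[j] = l;
    }
    std::swap(e_prev, e_cur);
    std::swap(l_prev, l_cur);
  }
  edits = e_prev[m];
  cols = l_prev[m];
}

// [[Rcpp::export(name = ".edit_align_c")]]
IntegerVector edit_align_c(std::string a, std::string b) {
  int edits = 0, cols = 0;
  align_pair(a, b, edits, cols);
  return IntegerVector::create(_["edits"] = edits, _["aln_len"] = cols);
}

// [[Rcpp::export(name = ".identity_matrix_c")]]
NumericMatrix identity_matrix_c(CharacterVector queries, CharacterVector refs) {
  const int nq = queries.size(), nr = refs.size();
  NumericMatrix out(nq, nr);
  std::vector<std::string> rs(nr);
  for (int j = 0; j < nr; ++j) rs[j] = as<std::string>(refs[j]);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    for (int j = 0; j < nr; ++j) {
      int edits = 0, cols = 0;
      align_pair(q, rs[j], edits, cols);
      out(i, j) = 100.0 * (double)(cols - edits) / (double)cols;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".edit_distance_matrix_c")]]
IntegerMatrix edit_distance_matrix_c(CharacterVector queries, CharacterVector refs) {
  const int nq = queries.size(), nr = refs.size();
  IntegerMatrix out(nq, nr);
  std::vector<std::string> rs(nr);
  for (int j = 0; j < nr; ++j) rs[j] = as<std::string>(refs[j]);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    for (int j = 0; j < nr; ++j) {
      int edits = 0, cols = 0;
      align_pair(q, rs[j], edits, cols);
      out(i, j) = edits;
    }
  }
  return out;
}
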