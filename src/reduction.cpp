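#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Standard persistence column reduction over Z/2.
//
// Columns arrive in filtration order; column j holds the (1-based, ascending)
// positions of the boundary faces of simplex j. Repeatedly add (xor) the
// already-reduced column owning the current pivot (lowest one) until the
// column is empty or owns a fresh pivot. Returns, per column, the pivot row
// it owns after reduction (0 = column reduced to zero).
//
// [[Rcpp::export]]
IntegerVector reduce_boundary(List columns) {
  const int m = columns.size();
  std::vector< std::vector<int> > col(m);
  for (int j = 0; j < m; ++j) {
    IntegerVector cj = columns[j];
    col[j].assign(cj.begin(), cj.end());
  }
  std::vector<int> owner(m + 1, -1);   // pivot row -> owning column
  IntegerVector low(m, 0);
  std::vector<int> tmp;
  for (int j = 0; j < m; ++j) {
    std::vector<int> &cur = col[j];
    while (!cur.empty()) {
      int piv = cur.back();
      int own = owner[piv];
      if (own < 0) {
        owner[piv] = j;
        low[j] = piv;
        break;
      }
      // cur ^= col[own] (symmetric difference of sorted vectors)
      const std::vector<int> &other = col[own];
      tmp.clear();
      tmp.reserve(cur.size() + other.size());
      size_t a = 0, b = 0;
      while (a < cur.size() && b < other.size()) {
        if (cur[a] < other[b]) tmp.push_back(cur[a++]);
        else if (other[b] < cur[a]) tmp.push_back(other[b++]);
        else { ++a; ++b; }
      }
      while (a < cur.size()) tmp.push_back(cur[a++]);
      while (b < other.size()) tmp.push_back(other[b++]);
      cur.swap(tmp);
    }
  }
  return low;
}
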