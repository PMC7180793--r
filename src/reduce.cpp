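#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Persistence pairing by boundary-matrix column reduction over Z/2.
//
// `columns` holds, for each simplex in filtration order, the 1-based
// filtration indices of its boundary facets (empty for vertices). The
// standard reduction adds earlier columns (mod 2) until each column is
// either empty (the simplex creates a homology class) or has a pivot row
// not yet used by any earlier column (the simplex destroys the class
// created at the pivot).
//
// Returns an integer matrix with one row per simplex: column 1 is the
// simplex's 1-based creator index if this simplex destroys a class
// (0 otherwise), column 2 is 1 if the simplex is a creator.
// [[Rcpp::export(name = ".reduceBoundary")]]
IntegerMatrix reduceBoundary(List columns) {
  const int m = columns.size();
  std::vector<std::vector<int> > cols(m);
  for (int j = 0; j < m; ++j) {
    IntegerVector cj = columns[j];
    cols[j].assign(cj.begin(), cj.end());
    std::sort(cols[j].begin(), cols[j].end());
    for (size_t t = 0; t < cols[j].size(); ++t) {
      if (cols[j][t] < 1 || cols[j][t] > j)
        stop("invalid filtration order: facet %d of simplex %d does not precede it",
             cols[j][t], j + 1);
    }
  }
  std::vector<int> pivot_owner(m + 1, -1); // low value -> column index
  IntegerMatrix out(m, 2);
  std::vector<int> buf;
  for (int j = 0; j < m; ++j) {
    std::vector<int>& col = cols[j];
    while (!col.empty()) {
      int low = col.back();
      int owner = pivot_owner[low];
      if (owner < 0) break;
      // col <- col XOR cols[owner] (both sorted ascending)
      const std::vector<int>& other = cols[owner];
      buf.clear();
      std::set_symmetric_difference(col.begin(), col.end(),
                                    other.begin(), other.end(),
                                    std::back_inserter(buf));
      col.swap(buf);
    }
    if (col.empty()) {
      out(j, 1) = 1; // creator
    } else {
      int low = col.back();
      pivot_owner[low] = j;
      out(j, 0) = low; // destroys the class created at `low`
    }
  }
  return out;
}
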