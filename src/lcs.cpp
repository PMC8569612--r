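#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Longest common substring between query q and reference r by rolling-row
// dynamic programming. Returns length and 1-based start positions of the
// leftmost witness (smallest query start, then smallest reference start):
// cells are visited in increasing query end position, then increasing
// reference end position, and a strictly-greater test keeps the first
// maximum, which for a fixed length is also the leftmost start.
// [[Rcpp::export(name = ".lcsPair")]]
IntegerVector lcsPair(std::string q, std::string r) {
  const int n = q.size(), m = r.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0, qEnd = 0, rEnd = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (q[i - 1] == r[j - 1]) {
        cur[j] = prev[j - 1] + 1;
        if (cur[j] > best) {
          best = cur[j];
          qEnd = i;
          rEnd = j;
        }
      } else {
        cur[j] = 0;
      }
    }
    std::swap(prev, cur);
  }
  return IntegerVector::create(best,
                               best > 0 ? qEnd - best + 1 : 0,
                               best > 0 ? rEnd - best + 1 : 0);
}
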