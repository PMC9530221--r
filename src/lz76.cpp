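#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive-history Lempel-Ziv (LZ76) phrase count, Kaspar-Schuster
// formulation. Counts the number of distinct phrases produced when the
// sequence is parsed so that each new phrase is the shortest substring
// not reproducible from the history by copy-extension.
// [[Rcpp::export(name = ".lz76_count")]]
int lz76_count(IntegerVector s) {
  int n = s.size();
  if (n == 0) stop("sequence must be nonempty");
  int c = 1, l = 1, i = 0, k = 1, k_max = 1;
  if (n == 1) return 1;
  while (true) {
    if (s[i + k - 1] != s[l + k - 1]) {
      if (k > k_max) k_max = k;
      ++i;
      if (i == l) {
        ++c;
        l += k_max;
        if (l + 1 > n) break;
        i = 0;
        k = 1;
        k_max = 1;
      } else {
        k = 1;
      }
    } else {
      ++k;
      if (l + k > n) {
        ++c;
        break;
      }
    }
  }
  return c;
}
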