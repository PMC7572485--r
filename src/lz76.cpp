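#include <Rcpp.h>
using namespace Rcpp;

// Lempel-Ziv 1976 complexity: number of words in the exhaustive
// left-to-right parsing. The current word is extended while it can be
// reproduced from the prior history (self-overlapping copies allowed); when
// extension fails the word is closed and a new one starts. The terminal
// word counts even if still reproducible. O(n^2) scan in the style of
// Kaspar & Schuster.
// [[Rcpp::export(name = ".lz76_count")]]
int lz76_count(IntegerVector s) {
  const int n = s.size();
  if (n == 0) return 0;
  if (n == 1) return 1;
  int c = 1;      // words found so far (the first symbol is a word)
  int l = 1;      // start (0-based) of the current word
  int i = 0;      // candidate copy start within the history
  int k = 1;      // current match length
  int kmax = 1;   // longest reproducible extension found from any i
  for (;;) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { // reached the end while reproducible: terminal word
        ++c;
        return c;
      }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) { // no copy source works: close the word
        ++c;
        l += kmax;
        if (l + 1 > n) return c;
        i = 0;
        k = 1;
        kmax = 1;
      } else {
        k = 1;
      }
    }
  }
}
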