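#include <Rcpp.h>
using namespace Rcpp;

// Exact permutation null of Spearman's statistic for tie-free samples of
// size n: enumerates all n! rank permutations (Heap's algorithm) and counts
// occurrences of D = sum (rank difference)^2. rho = 1 - 6 D / (n (n^2 - 1)),
// so the counts give the full exact distribution of rho.
// Feasible up to n = 10 (10! = 3,628,800).
// [[Rcpp::export]]
NumericVector spearman_null_counts(int n) {
  if (n < 2 || n > 10) stop("exact Spearman null supported for 2 <= n <= 10");
  int dmax = n * (n * n - 1) / 3;
  NumericVector counts(dmax + 1);
  std::vector<int> a(n), c(n, 0);
  for (int i = 0; i < n; ++i) a[i] = i;

  auto dval = [&]() {
    int d = 0;
    for (int i = 0; i < n; ++i) {
      int diff = a[i] - i;
      d += diff * diff;
    }
    return d;
  };

  counts[dval()] += 1;
  int i = 0;
  while (i < n) {
    if (c[i] < i) {
      if (i % 2 == 0) std::swap(a[0], a[i]); else std::swap(a[c[i]], a[i]);
      counts[dval()] += 1;
      ++c[i];
      i = 0;
    } else {
      c[i] = 0;
      ++i;
    }
  }
  return counts;
}
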