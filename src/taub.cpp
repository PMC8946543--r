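#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Merge sort on y counting inversions (strict: y[i] > y[j] for i < j).
static double merge_count(std::vector<double>& y, std::vector<double>& buf,
                          std::size_t lo, std::size_t hi) {
  if (hi - lo < 2) return 0.0;
  std::size_t mid = lo + (hi - lo) / 2;
  double inv = merge_count(y, buf, lo, mid) + merge_count(y, buf, mid, hi);
  std::size_t i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (y[j] < y[i]) {
      inv += static_cast<double>(mid - i);
      buf[k++] = y[j++];
    } else {
      buf[k++] = y[i++];
    }
  }
  while (i < mid) buf[k++] = y[i++];
  while (j < hi) buf[k++] = y[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
  return inv;
}

static double tie_sum(const std::vector<double>& v) {
  double s = 0.0, run = 1.0;
  for (std::size_t i = 1; i < v.size(); ++i) {
    if (v[i] == v[i - 1]) {
      run += 1.0;
    } else {
      s += run * (run - 1.0) / 2.0;
      run = 1.0;
    }
  }
  s += run * (run - 1.0) / 2.0;
  return s;
}

// Kendall tau-b by Knight's O(n log n) algorithm with tie correction.
// [[Rcpp::export]]
double taub_fast(NumericVector x, NumericVector y) {
  const std::size_t n = x.size();
  if (n < 2 || static_cast<std::size_t>(y.size()) != n)
    return NA_REAL;
  std::vector<std::size_t> ord(n);
  for (std::size_t i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](std::size_t a, std::size_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });

  const double n0 = static_cast<double>(n) * (n - 1.0) / 2.0;

  // ties in x, and joint ties in (x, y), over the sorted order
  double n1 = 0.0, n3 = 0.0, runx = 1.0, runxy = 1.0;
  for (std::size_t i = 1; i < n; ++i) {
    if (x[ord[i]] == x[ord[i - 1]]) {
      runx += 1.0;
      if (y[ord[i]] == y[ord[i - 1]]) {
        runxy += 1.0;
      } else {
        n3 += runxy * (runxy - 1.0) / 2.0;
        runxy = 1.0;
      }
    } else {
      n1 += runx * (runx - 1.0) / 2.0;
      n3 += runxy * (runxy - 1.0) / 2.0;
      runx = 1.0;
      runxy = 1.0;
    }
  }
  n1 += runx * (runx - 1.0) / 2.0;
  n3 += runxy * (runxy - 1.0) / 2.0;

  std::vector<double> ys(n), buf(n);
  for (std::size_t i = 0; i < n; ++i) ys[i] = y[ord[i]];
  double disc = merge_count(ys, buf, 0, n); // ys now sorted

  double n2 = tie_sum(ys);

  const double denom = std::sqrt((n0 - n1) * (n0 - n2));
  if (denom <= 0.0) return NA_REAL;
  const double s = n0 - n1 - n2 + n3 - 2.0 * disc;
  return s / denom;
}
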