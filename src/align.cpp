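#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Needleman-Wunsch global alignment, linear gap penalty.
// Traceback tie-break is fixed: prefer match/mismatch (diagonal), then a
// gap in `a`, then a gap in `b`, so identical inputs always give an
// identical alignment.
// [[Rcpp::export(name = ".nwAlign")]]
List nwAlign(std::string a, std::string b,
             double match = 1.0, double mismatch = -1.0, double gap = -2.0) {
  const size_t n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("alignGlobal: empty input sequence");
  // full matrix needed for traceback; keep it as one block
  std::vector<double> H((n + 1) * (m + 1));
  for (size_t j = 0; j <= m; ++j) H[j] = gap * (double)j;
  for (size_t i = 1; i <= n; ++i) {
    H[i * (m + 1)] = gap * (double)i;
    for (size_t j = 1; j <= m; ++j) {
      double diag = H[(i - 1) * (m + 1) + (j - 1)] +
                    (a[i - 1] == b[j - 1] ? match : mismatch);
      double up   = H[(i - 1) * (m + 1) + j] + gap;  // consume a -> gap in b
      double left = H[i * (m + 1) + (j - 1)] + gap;  // consume b -> gap in a
      double best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      H[i * (m + 1) + j] = best;
    }
  }
  // traceback
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  size_t i = n, j = m;
  while (i > 0 || j > 0) {
    double cell = H[i * (m + 1) + j];
    if (i > 0 && j > 0 &&
        cell == H[(i - 1) * (m + 1) + (j - 1)] +
                (a[i - 1] == b[j - 1] ? match : mismatch)) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (j > 0 && cell == H[i * (m + 1) + (j - 1)] + gap) {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;   // gap in a
    } else if (i > 0 && cell == H[(i - 1) * (m + 1) + j] + gap) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;   // gap in b
    } else {
      stop("alignGlobal: traceback failed (internal error)");
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = H[n * (m + 1) + m],
                      _["a"] = ra, _["b"] = rb);
}
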