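#include <Rcpp.h>
using namespace Rcpp;

// Otsu threshold over a 256-bin histogram: maximize the between-class
// variance over cuts t in 1..255 with classes {q < t} and {q >= t}; among
// exact ties take the smallest t. The criterion
//   w0 * w1 * (mu0 - mu1)^2 = (sum0 * total - sum * w0)^2 / (w0 * w1)
// is compared exactly with 128-bit integer cross-multiplication, so the
// tie-break is deterministic. Returns 0 for degenerate histograms (fewer
// than two distinct levels): no pixel satisfies q < 0, i.e. background.
static int otsu_cut(const int *hist, long long total) {
  long long sum = 0;
  int nonzero = 0;
  for (int i = 0; i < 256; ++i) {
    if (hist[i] > 0) ++nonzero;
    sum += (long long)i * hist[i];
  }
  if (nonzero < 2 || total < 2) return 0;
  long long w0 = 0, sum0 = 0;
  __int128 best_num = -1, best_den = 1;
  int best_t = 0;
  for (int t = 1; t <= 255; ++t) {
    w0 += hist[t - 1];
    sum0 += (long long)(t - 1) * hist[t - 1];
    long long w1 = total - w0;
    if (w0 == 0 || w1 == 0) continue;
    long long d = sum0 * total - sum * w0;
    __int128 num = (__int128)d * d;
    __int128 den = (__int128)w0 * w1;
    if (best_num < 0 || num * best_den > best_num * den) {
      best_num = num;
      best_den = den;
      best_t = t;
    }
  }
  return best_t;
}

// [[Rcpp::export]]
IntegerMatrix cpp_local_otsu(IntegerMatrix q, LogicalMatrix valid, int window) {
  int nr = q.nrow(), nc = q.ncol();
  int half = window / 2;
  IntegerMatrix thr(nr, nc);
  int hist[256];
  for (int j = 0; j < nc; ++j) {
    int c0 = std::max(0, j - half), c1 = std::min(nc - 1, j + half);
    for (int i = 0; i < nr; ++i) {
      if (!valid(i, j)) { thr(i, j) = 0; continue; }
      int r0 = std::max(0, i - half), r1 = std::min(nr - 1, i + half);
      std::fill(hist, hist + 256, 0);
      long long total = 0;
      for (int c = c0; c <= c1; ++c)
        for (int r = r0; r <= r1; ++r)
          if (valid(r, c)) { ++hist[q(r, c)]; ++total; }
      thr(i, j) = otsu_cut(hist, total);
    }
  }
  return thr;
}

// [[Rcpp::export]]
int cpp_global_otsu(IntegerVector q) {
  int hist[256];
  std::fill(hist, hist + 256, 0);
  for (int i = 0; i < q.size(); ++i) ++hist[q[i]];
  return otsu_cut(hist, (long long)q.size());
}
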