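#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <functional>
using namespace Rcpp;

// Reflect index into [0, n-1] ("mirror without repeating the edge pixel"
// degenerates to clamping for n == 1).
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * (n - 1);
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - i;
}

// Separable 2-D Gaussian convolution on a numeric matrix.
// Kernel truncated at `truncate` * sigma, normalized to sum 1; reflect
// border handling; accumulation in double. Rounding/clipping to 8 bits is
// left to the R wrapper so the unsaturated response stays inspectable.
// [[Rcpp::export(name = ".gaussian_smooth_cpp")]]
NumericMatrix gaussian_smooth_cpp(NumericMatrix x, double sigma,
                                  double truncate = 4.0) {
  const int nr = x.nrow(), nc = x.ncol();
  if (sigma <= 0) return clone(x);

  const int radius = std::max(1, (int)std::floor(truncate * sigma + 0.5));
  std::vector<double> k(2 * radius + 1);
  double ksum = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    ksum += k[i + radius];
  }
  for (double& w : k) w /= ksum;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // pass 1: along rows (vertical neighbourhood, R matrices are column-major)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -radius; i <= radius; ++i)
        acc += k[i + radius] * x(reflect_index(r + i, nr), c);
      tmp(r, c) = acc;
    }
  // pass 2: along columns (horizontal neighbourhood)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -radius; i <= radius; ++i)
        acc += k[i + radius] * tmp(r, reflect_index(c + i, nc));
      out(r, c) = acc;
    }
  return out;
}

// Connected-component labeling of a binary mask (two-pass union-find).
// connectivity 4 or 8; final labels are renumbered 1..n by the raster
// (row-major: left-to-right, top-to-bottom) position of each component's
// first pixel, so output is deterministic and stable for CSV export.
// [[Rcpp::export(name = ".label_connected_cpp")]]
IntegerMatrix label_connected_cpp(IntegerMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0); // parent[0] unused

  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  int next = 1;
  // raster scan: rows outer, columns inner
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) == 0) continue;
      int up    = (r > 0) ? lab(r - 1, c) : 0;
      int left  = (c > 0) ? lab(r, c - 1) : 0;
      int upl = 0, upr = 0;
      if (connectivity == 8) {
        upl = (r > 0 && c > 0)      ? lab(r - 1, c - 1) : 0;
        upr = (r > 0 && c < nc - 1) ? lab(r - 1, c + 1) : 0;
      }
      int m = 0;
      for (int nb : {up, left, upl, upr})
        if (nb > 0 && (m == 0 || nb < m)) m = nb;
      if (m == 0) {
        lab(r, c) = next;
        parent.push_back(next);
        ++next;
      } else {
        lab(r, c) = m;
        for (int nb : {up, left, upl, upr}) if (nb > 0) unite(m, nb);
      }
    }
  }

  // second pass: resolve, then renumber by raster order of first pixel
  std::vector<int> newlab(next, 0);
  int n_regions = 0;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (lab(r, c) > 0) {
        int root = find(lab(r, c));
        if (newlab[root] == 0) newlab[root] = ++n_regions;
        lab(r, c) = newlab[root];
      }
  lab.attr("n_regions") = n_regions;
  return lab;
}
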