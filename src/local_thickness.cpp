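#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Exact squared Euclidean distance transform and local-thickness transform.
//
// Digitization rule shared with the R-level brute-force oracle: a circle of
// radius rho centred at pixel c contains pixel p iff the centre-to-centre
// distance is <= rho; radii live on the half-pixel lattice, so the diameter
// 2*rho is an integer number of pixels. A circle "fits" iff every contained
// pixel is foreground; pixels outside the image grid count as background.

// One-dimensional squared EDT pass (Felzenszwalb & Huttenlocher 2012).
// f holds squared distances from a previous pass (or 0 / INF seeds); all
// values are exact integers representable in double, and the envelope
// arithmetic only compares integers, so the output is exact.
static void edt_1d(const std::vector<double> &f, std::vector<double> &d,
                   std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      int p = v[k];
      s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) / (2.0 * q - 2.0 * p);
      if (s > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    double dq = (double)(q - p);
    d[q] = dq * dq + f[p];
  }
}

// Squared distance from every pixel to the nearest background pixel centre,
// where everything outside the grid is background (nearest outside centre is
// axis-aligned, one step beyond the border).
// [[Rcpp::export(name = ".cppSquaredEdt")]]
IntegerMatrix cppSquaredEdt(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  std::vector<double> g(nr * nc);
  // column pass: distance along rows to nearest background in the column
  {
    std::vector<double> f(nr), d(nr), z(nr + 1);
    std::vector<int> v(nr);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? INF : 0.0;
      edt_1d(f, d, v, z, nr);
      for (int i = 0; i < nr; ++i) g[(size_t)j * nr + i] = d[i];
    }
  }
  IntegerMatrix out(nr, nc);
  {
    std::vector<double> f(nc), d(nc), z(nc + 1);
    std::vector<int> v(nc);
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) f[j] = g[(size_t)j * nr + i];
      edt_1d(f, d, v, z, nc);
      for (int j = 0; j < nc; ++j) {
        double d2 = d[j];
        // outside the grid counts as background
        double rim = (double)std::min(std::min(i + 1, nr - i),
                                      std::min(j + 1, nc - j));
        double out2 = rim * rim;
        if (out2 < d2) d2 = out2;
        out(i, j) = (int)std::llround(d2);
      }
    }
  }
  return out;
}

// Largest integer k with k*k <= x (exact for the magnitudes used here).
static int isqrt_le(long long x) {
  if (x < 0) return -1;
  long long k = (long long)std::floor(std::sqrt((double)x));
  while (k * k > x) --k;
  while ((k + 1) * (k + 1) <= x) ++k;
  return (int)k;
}

// Local thickness: per-pixel diameter (integer, in pixels) of the largest
// digitized circle contained in the mask and covering that pixel.
// [[Rcpp::export(name = ".cppLocalThickness")]]
IntegerMatrix cppLocalThickness(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix d2 = cppSquaredEdt(mask);
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      // largest half-lattice radius rho = k/2 with rho < dist to background:
      // k^2 < 4*d2  <=>  k = isqrt(4*d2 - 1)
      long long dd = (long long)d2(i, j);
      int k = isqrt_le(4 * dd - 1);
      if (k <= 0) continue;
      long long k2 = (long long)k * k;
      int rad = k / 2 + 1; // bounding box of the circle (rho <= rad)
      int ilo = std::max(0, i - rad), ihi = std::min(nr - 1, i + rad);
      int jlo = std::max(0, j - rad), jhi = std::min(nc - 1, j + rad);
      for (int q = jlo; q <= jhi; ++q) {
        long long dj = (long long)(q - j);
        for (int p = ilo; p <= ihi; ++p) {
          long long di = (long long)(p - i);
          if (4 * (di * di + dj * dj) <= k2 && out(p, q) < k) out(p, q) = k;
        }
      }
    }
  }
  return out;
}
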