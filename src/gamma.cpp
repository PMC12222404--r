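#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 3D gamma index between a reference and an evaluated dose map on a shared
// grid. For each evaluated reference voxel the minimum over sub-voxel search
// positions of sqrt(dist^2/DTA^2 + ddiff^2/(DD*Dnorm)^2) is taken, with the
// evaluated map sampled trilinearly on a refinement grid of 1/refine voxel.
// Search positions are bounded by |offset| <= cap*DTA; offsets are visited in
// order of increasing distance so the scan can stop as soon as the spatial
// term alone exceeds the best gamma^2 found.
//
// dnorm: per-voxel normalisation dose (constant vector in global mode,
// D_ref(v) in local mode). Voxels with evalmask == false get NaN.

struct Offset {
  double dx, dy, dz;  // fractional voxel offsets
  double dist2;       // squared physical distance, mm^2
};

static inline double trilinear(const double* a, int nx, int ny, int nz,
                               double px, double py, double pz) {
  int i0, j0, k0;
  double fx, fy, fz;
  if (nx == 1) { i0 = 0; fx = 0.0; }
  else {
    i0 = (int)std::floor(px);
    if (i0 > nx - 2) i0 = nx - 2;
    if (i0 < 0) i0 = 0;
    fx = px - i0;
  }
  if (ny == 1) { j0 = 0; fy = 0.0; }
  else {
    j0 = (int)std::floor(py);
    if (j0 > ny - 2) j0 = ny - 2;
    if (j0 < 0) j0 = 0;
    fy = py - j0;
  }
  if (nz == 1) { k0 = 0; fz = 0.0; }
  else {
    k0 = (int)std::floor(pz);
    if (k0 > nz - 2) k0 = nz - 2;
    if (k0 < 0) k0 = 0;
    fz = pz - k0;
  }
  const int i1 = (nx == 1) ? i0 : i0 + 1;
  const int j1 = (ny == 1) ? j0 : j0 + 1;
  const int k1 = (nz == 1) ? k0 : k0 + 1;
  #define AT(i, j, k) a[(i) + (std::size_t)nx * ((j) + (std::size_t)ny * (k))]
  double v =
    (1 - fx) * (1 - fy) * (1 - fz) * AT(i0, j0, k0) +
        fx  * (1 - fy) * (1 - fz) * AT(i1, j0, k0) +
    (1 - fx) *     fy  * (1 - fz) * AT(i0, j1, k0) +
        fx  *     fy  * (1 - fz) * AT(i1, j1, k0) +
    (1 - fx) * (1 - fy) *     fz  * AT(i0, j0, k1) +
        fx  * (1 - fy) *     fz  * AT(i1, j0, k1) +
    (1 - fx) *     fy  *     fz  * AT(i0, j1, k1) +
        fx  *     fy  *     fz  * AT(i1, j1, k1);
  #undef AT
  return v;
}

// [[Rcpp::export]]
NumericVector cpp_gamma(NumericVector ref, NumericVector evalv,
                        IntegerVector dims, NumericVector spacing,
                        double dta, double dd_frac, NumericVector dnorm,
                        int refine, double cap, LogicalVector evalmask) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const std::size_t n = (std::size_t)nx * ny * nz;
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double radius = cap * dta;
  const double dta2 = dta * dta;

  const int rx = (int)std::floor(radius * refine / sx);
  const int ry = (int)std::floor(radius * refine / sy);
  const int rz = (int)std::floor(radius * refine / sz);

  std::vector<Offset> offs;
  offs.reserve((std::size_t)(2 * rx + 1) * (2 * ry + 1) * (2 * rz + 1) / 2);
  for (int i = -rx; i <= rx; ++i) {
    for (int j = -ry; j <= ry; ++j) {
      for (int k = -rz; k <= rz; ++k) {
        const double dx = (double)i / refine;
        const double dy = (double)j / refine;
        const double dz = (double)k / refine;
        const double d2 = dx * sx * dx * sx + dy * sy * dy * sy +
                          dz * sz * dz * sz;
        if (d2 <= radius * radius) offs.push_back({dx, dy, dz, d2});
      }
    }
  }
  std::sort(offs.begin(), offs.end(),
            [](const Offset& a, const Offset& b) { return a.dist2 < b.dist2; });

  const double* e = evalv.begin();
  NumericVector out(n, NA_REAL);

  std::size_t v = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++v) {
        if (!evalmask[v]) continue;
        const double dr = ref[v];
        const double denom = dd_frac * dnorm[v];
        double best = R_PosInf;
        for (const Offset& o : offs) {
          const double sterm = o.dist2 / dta2;
          if (sterm >= best) break;  // sorted: nothing closer remains
          const double px = i + o.dx, py = j + o.dy, pz = k + o.dz;
          if (px < 0 || px > nx - 1 || py < 0 || py > ny - 1 ||
              pz < 0 || pz > nz - 1) continue;
          const double de = trilinear(e, nx, ny, nz, px, py, pz);
          const double diff = de - dr;
          double dterm;
          if (denom > 0) dterm = (diff / denom) * (diff / denom);
          else dterm = (diff == 0.0) ? 0.0 : R_PosInf;
          const double g2 = sterm + dterm;
          if (g2 < best) best = g2;
        }
        double g = std::sqrt(best);
        if (g > cap) g = cap;
        out[v] = g;
      }
    }
  }
  return out;
}
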