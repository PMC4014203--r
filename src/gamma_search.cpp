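#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Tri-/bilinear interpolation at a mm position on a voxel-center lattice.
// Degenerate axes (extent 1) interpolate as constants. Returns false when
// the position lies outside the voxel-center extent (tol mm slack).
static inline bool interp_lattice(const double *v, const int *d,
                                  const double *sp, const double *o,
                                  const double *pos, double tol, double *out) {
  double f[3];
  int i0[3], i1[3];
  double t[3];
  for (int a = 0; a < 3; ++a) {
    f[a] = (pos[a] - o[a]) / sp[a];
    double tf = tol / sp[a];
    if (f[a] < -tf || f[a] > d[a] - 1 + tf)
      return false;
    if (f[a] < 0) f[a] = 0;
    if (f[a] > d[a] - 1) f[a] = d[a] - 1;
    if (d[a] == 1) {
      i0[a] = 0; i1[a] = 0; t[a] = 0.0;
    } else {
      int ii = (int)std::floor(f[a]);
      if (ii > d[a] - 2) ii = d[a] - 2;
      if (ii < 0) ii = 0;
      i0[a] = ii; i1[a] = ii + 1; t[a] = f[a] - ii;
    }
  }
  const int nx = d[0], nxy = d[0] * d[1];
  double acc = 0.0;
  for (int ck = 0; ck < 2; ++ck) {
    double wk = ck ? t[2] : 1.0 - t[2];
    if (wk == 0.0) continue;
    int kk = (ck ? i1[2] : i0[2]) * nxy;
    for (int cj = 0; cj < 2; ++cj) {
      double wj = cj ? t[1] : 1.0 - t[1];
      if (wj == 0.0) continue;
      int jj = (cj ? i1[1] : i0[1]) * nx + kk;
      double w0 = wk * wj * (1.0 - t[0]);
      double w1 = wk * wj * t[0];
      acc += w0 * v[i0[0] + jj] + w1 * v[i1[0] + jj];
    }
  }
  *out = acc;
  return true;
}

struct Offset {
  double dx, dy, dz, dist2;
};

// Exhaustive minimisation of the gamma objective over a displacement lattice
// (spacing `step` mm, within `radius` mm), with an exact early-exit: offsets
// are visited in order of increasing distance, and the scan stops once the
// spatial term alone exceeds the current best — the reported minimum is
// identical to a full scan of the lattice.
//
// ref/ev are column-major arrays with dims *_dim (length 3; planar inputs
// pass a third extent of 1), spacings *_sp (mm) and voxel-center origins
// *_or (mm). dd_abs gives the absolute dose tolerance (cGy) per reference
// point (a vector of length 1 recycles). compute flags the reference points
// to evaluate; others (and points with no valid candidate or dd_abs <= 0)
// return NA.
// [[Rcpp::export]]
NumericVector gamma_search_cpp(NumericVector ref, IntegerVector ref_dim,
                               NumericVector ref_sp, NumericVector ref_or,
                               NumericVector ev, IntegerVector ev_dim,
                               NumericVector ev_sp, NumericVector ev_or,
                               NumericVector dd_abs, double dta, double step,
                               double radius, int ndim_search,
                               LogicalVector compute) {
  const int rd[3] = {ref_dim[0], ref_dim[1], ref_dim[2]};
  const int ed[3] = {ev_dim[0], ev_dim[1], ev_dim[2]};
  const double tol = 1e-9;
  const int n = rd[0] * rd[1] * rd[2];
  if (dta <= 0 || step <= 0 || radius <= 0)
    stop("dta, step and radius must be positive");

  // displacement lattice sorted by distance
  int m = (int)std::ceil(radius / step);
  std::vector<Offset> offs;
  double r2max = radius * radius * (1.0 + 1e-12) + 1e-12;
  int mk = (ndim_search >= 3) ? m : 0;
  for (int k = -mk; k <= mk; ++k)
    for (int j = -m; j <= m; ++j)
      for (int i = -m; i <= m; ++i) {
        double dx = i * step, dy = j * step, dz = k * step;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= r2max)
          offs.push_back({dx, dy, dz, d2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset &a, const Offset &b) { return a.dist2 < b.dist2; });

  const double dta2 = dta * dta;
  NumericVector gamma(n, NA_REAL);
  const double *rv = REAL(ref), *evv = REAL(ev);
  const bool dd_scalar = dd_abs.size() == 1;

  for (int p = 0; p < n; ++p) {
    if (!compute[p]) continue;
    double dd = dd_scalar ? dd_abs[0] : dd_abs[p];
    if (!(dd > 0)) continue;
    int i = p % rd[0];
    int j = (p / rd[0]) % rd[1];
    int k = p / (rd[0] * rd[1]);
    double pos0[3] = {ref_or[0] + i * ref_sp[0], ref_or[1] + j * ref_sp[1],
                      ref_or[2] + k * ref_sp[2]};
    double dr = rv[p];
    double best = R_PosInf;
    bool any = false;
    for (size_t q = 0; q < offs.size(); ++q) {
      double s2 = offs[q].dist2 / dta2;
      if (s2 >= best) break; // sorted: no later offset can improve
      double pos[3] = {pos0[0] + offs[q].dx, pos0[1] + offs[q].dy,
                       pos0[2] + offs[q].dz};
      double de;
      if (!interp_lattice(evv, ed, &ev_sp[0], &ev_or[0], pos, tol, &de))
        continue;
      double dterm = (de - dr) / dd;
      double g2 = s2 + dterm * dterm;
      if (g2 < best) best = g2;
      any = true;
    }
    if (any)
      gamma[p] = std::sqrt(best);
  }
  return gamma;
}
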