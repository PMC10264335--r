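#pragma once
#include <Rcpp.h>
#include <cmath>
#include "geom.h"

// Axis-aligned voxel grid; origin is the minimum corner of voxel (0,0,0),
// voxel centres at origin + (i + 0.5) * spacing. Linear index is
// column-major (x fastest), matching R arrays.
struct Grid {
  double o[3], v[3];
  int n[3];
  static Grid make(const Rcpp::NumericVector& origin,
                   const Rcpp::NumericVector& spacing,
                   const Rcpp::IntegerVector& dims) {
    Grid g;
    for (int j = 0; j < 3; ++j) {
      g.o[j] = origin[j];
      g.v[j] = spacing[j];
      g.n[j] = dims[j];
    }
    return g;
  }
  long long nvox() const { return (long long)n[0] * n[1] * n[2]; }
  long long idx(int i, int j, int k) const {
    return (long long)i + (long long)n[0] * (j + (long long)n[1] * k);
  }
};

// Amanatides-Woo voxel traversal of the segment p1 -> p2.
// Calls f(linear_index, intersection_length_mm, mid_param) for every voxel
// crossed; mid_param in [0,1] is the parametric midpoint along p1 -> p2.
template <typename F>
inline void trace_segment(const Grid& g, const double* p1, const double* p2,
                          F&& f) {
  double d[3];
  double L2 = 0.0;
  for (int j = 0; j < 3; ++j) {
    d[j] = p2[j] - p1[j];
    L2 += d[j] * d[j];
  }
  double L = std::sqrt(L2);
  if (L < 1e-12) return;
  double t0 = 0.0, t1 = 1.0;
  for (int j = 0; j < 3; ++j)
    if (!axis_clip(p1[j] - g.o[j], d[j], 0.0, g.n[j] * g.v[j], t0, t1)) return;
  if (t1 <= t0) return;
  double tin = t0 + 1e-10 * (t1 - t0);
  int i[3], step[3];
  double tmax[3], tdelta[3];
  for (int j = 0; j < 3; ++j) {
    double pj = p1[j] + tin * d[j] - g.o[j];
    i[j] = (int)std::floor(pj / g.v[j]);
    if (i[j] < 0) i[j] = 0;
    if (i[j] >= g.n[j]) i[j] = g.n[j] - 1;
    if (std::fabs(d[j]) < 1e-14) {
      step[j] = 0;
      tmax[j] = 1e300;
      tdelta[j] = 1e300;
    } else if (d[j] > 0.0) {
      step[j] = 1;
      tmax[j] = ((i[j] + 1) * g.v[j] - pj) / d[j] + tin;
      tdelta[j] = g.v[j] / d[j];
    } else {
      step[j] = -1;
      tmax[j] = (i[j] * g.v[j] - pj) / d[j] + tin;
      tdelta[j] = -g.v[j] / d[j];
    }
  }
  double tcur = t0;
  for (;;) {
    int ax = 0;
    if (tmax[1] < tmax[ax]) ax = 1;
    if (tmax[2] < tmax[ax]) ax = 2;
    double tnext = std::min(tmax[ax], t1);
    if (tnext > tcur) {
      double len = (tnext - tcur) * L;
      f(g.idx(i[0], i[1], i[2]), len, 0.5 * (tcur + tnext));
    }
    if (tmax[ax] >= t1) break;
    tcur = tmax[ax];
    i[ax] += step[ax];
    if (i[ax] < 0 || i[ax] >= g.n[ax]) break;
    tmax[ax] += tdelta[ax];
  }
}
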