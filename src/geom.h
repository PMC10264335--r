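#pragma once
#include <Rcpp.h>
#include <cmath>
#include <vector>

// Cylindrical scanner of flat monolithic slabs tangent to the bore cylinder.
// Module local frame: u = outward radial at module azimuth, v = tangential,
// w = z. Slab occupies u in [r_in, r_out], |v| <= half_t, |w - z_ring| <= half_a.
struct Geom {
  double r_in, r_out, half_t, half_a, dphi;
  int n_azim;
  std::vector<double> ring_z;

  static Geom from_list(const Rcpp::List& g) {
    Geom G;
    G.r_in = Rcpp::as<double>(g["r_inner"]);
    G.r_out = Rcpp::as<double>(g["r_outer"]);
    G.half_t = Rcpp::as<double>(g["half_transaxial"]);
    G.half_a = Rcpp::as<double>(g["half_axial"]);
    G.n_azim = Rcpp::as<int>(g["modules_per_ring"]);
    G.dphi = 2.0 * M_PI / G.n_azim;
    Rcpp::NumericVector rz = g["ring_z"];
    G.ring_z.assign(rz.begin(), rz.end());
    return G;
  }
};

struct Hit {
  int module;      // 0-based ring * n_azim + azim; -1 if none
  double t_entry;  // distance from origin to slab entry
  double chord;    // path length through the slab
};

inline bool axis_clip(double o, double d, double lo, double hi,
                      double& t0, double& t1) {
  if (std::fabs(d) < 1e-12) return o >= lo && o <= hi;
  double ta = (lo - o) / d, tb = (hi - o) / d;
  if (ta > tb) std::swap(ta, tb);
  if (ta > t0) t0 = ta;
  if (tb < t1) t1 = tb;
  return t0 <= t1;
}

inline bool box_intersect(const Geom& G, const double* o, const double* d,
                          double phik, double zc, double& t0, double& t1) {
  double cph = std::cos(phik), sph = std::sin(phik);
  double ou = o[0] * cph + o[1] * sph, du = d[0] * cph + d[1] * sph;
  double ov = -o[0] * sph + o[1] * cph, dv = -d[0] * sph + d[1] * cph;
  double ow = o[2] - zc, dw = d[2];
  t0 = -1e300; t1 = 1e300;
  if (!axis_clip(ou, du, G.r_in, G.r_out, t0, t1)) return false;
  if (!axis_clip(ov, dv, -G.half_t, G.half_t, t0, t1)) return false;
  if (!axis_clip(ow, dw, -G.half_a, G.half_a, t0, t1)) return false;
  return t1 > t0;
}

// First slab entered by a ray starting inside the bore (radius < r_in).
// Candidate modules are found from the crossing of the inner-radius
// cylinder: +-1 azimuthal neighbours, rings within reach of the crossing z.
inline Hit intersect_one(const Geom& G, const double* o, const double* d) {
  Hit h{-1, 0.0, 0.0};
  double a = d[0] * d[0] + d[1] * d[1];
  if (a < 1e-14) return h;  // (near-)axial ray escapes through the bore ends
  double b = 2.0 * (o[0] * d[0] + o[1] * d[1]);
  double c = o[0] * o[0] + o[1] * o[1] - G.r_in * G.r_in;
  double disc = b * b - 4.0 * a * c;
  if (disc <= 0.0) return h;
  double tc = (-b + std::sqrt(disc)) / (2.0 * a);
  if (tc < 0.0) return h;
  double qx = o[0] + tc * d[0], qy = o[1] + tc * d[1], qz = o[2] + tc * d[2];
  int k0 = (int)std::lround(std::atan2(qy, qx) / G.dphi);
  // grazing rays drift azimuthally between the inner-radius crossing and the
  // slab entry (which can sit at radius up to sqrt(r_out^2 + half_t^2)):
  // bracket the candidate azimuths with the crossing of that outer radius
  int k1 = k0;
  double qz2 = qz;
  {
    double r2 = G.r_out * G.r_out + G.half_t * G.half_t;
    double c2 = o[0] * o[0] + o[1] * o[1] - r2;
    double disc2 = b * b - 4.0 * a * c2;  // > disc > 0 from inside the bore
    if (disc2 > 0.0) {
      double t2 = (-b + std::sqrt(disc2)) / (2.0 * a);
      double px = o[0] + t2 * d[0], py = o[1] + t2 * d[1];
      k1 = (int)std::lround(std::atan2(py, px) / G.dphi);
      qz2 = o[2] + t2 * d[2];
    }
  }
  int dk1 = k1 - k0;
  dk1 -= (int)std::lround((double)dk1 / G.n_azim) * G.n_azim;  // shortest arc
  int lo = std::min(0, dk1) - 1, hi = std::max(0, dk1) + 1;
  double zlo = std::min(qz, qz2) - G.half_a - 1.0;
  double zhi = std::max(qz, qz2) + G.half_a + 1.0;
  double best_t = 1e300;
  int nr = (int)G.ring_z.size();
  for (int r = 0; r < nr; ++r) {
    if (G.ring_z[r] < zlo || G.ring_z[r] > zhi) continue;
    for (int dk = lo; dk <= hi; ++dk) {
      int k = ((k0 + dk) % G.n_azim + G.n_azim) % G.n_azim;
      double t0, t1;
      if (box_intersect(G, o, d, k * G.dphi, G.ring_z[r], t0, t1)) {
        if (t1 > 1e-9 && t0 >= -1e-9 && t0 < best_t) {
          best_t = t0;
          h.module = r * G.n_azim + k;
          h.t_entry = std::max(t0, 0.0);
          h.chord = t1 - std::max(t0, 0.0);
        }
      }
    }
  }
  return h;
}
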