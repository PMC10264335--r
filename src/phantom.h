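#pragma once
#include <Rcpp.h>
#include <cmath>
#include <vector>

// Phantom = ordered list of homogeneous primitives; the highest-priority
// (last listed) primitive containing a point decides the material there.
// Shape codes: 0 cylinder (cx,cy,cz,r,half_len; axis along z)
//              1 sphere   (cx,cy,cz,r)
//              2 box      (cx,cy,cz,hx,hy,hz)
//              3 torso    (cz,half_len,a,R): two half-circles of radius R
//                centred at (+-a, 0) joined by straight walls |y| <= R.
struct Phantom {
  int n;
  std::vector<int> shape;
  std::vector<std::array<double, 7>> par;
  std::vector<double> mu, cf;
  double mu_max;
  double bb[6];  // xmin,xmax,ymin,ymax,zmin,zmax

  static Phantom from_matrix(const Rcpp::NumericMatrix& m,
                             const Rcpp::NumericVector& aux) {
    Phantom P;
    P.n = m.nrow();
    P.shape.resize(P.n);
    P.par.resize(P.n);
    P.mu.resize(P.n);
    P.cf.resize(P.n);
    for (int i = 0; i < P.n; ++i) {
      P.shape[i] = (int)m(i, 0);
      for (int j = 0; j < 7; ++j) P.par[i][j] = m(i, 1 + j);
      P.mu[i] = m(i, 8);
      P.cf[i] = m(i, 9);
    }
    P.mu_max = aux[0];
    for (int j = 0; j < 6; ++j) P.bb[j] = aux[1 + j];
    return P;
  }

  bool contains(int i, double x, double y, double z) const {
    const std::array<double, 7>& p = par[i];
    switch (shape[i]) {
      case 0: {
        double dx = x - p[0], dy = y - p[1];
        return dx * dx + dy * dy <= p[3] * p[3] && std::fabs(z - p[2]) <= p[4];
      }
      case 1: {
        double dx = x - p[0], dy = y - p[1], dz = z - p[2];
        return dx * dx + dy * dy + dz * dz <= p[3] * p[3];
      }
      case 2:
        return std::fabs(x - p[0]) <= p[3] && std::fabs(y - p[1]) <= p[4] &&
               std::fabs(z - p[2]) <= p[5];
      case 3: {
        if (std::fabs(z - p[0]) > p[1]) return false;
        double a = p[2], R = p[3];
        double xp = std::fabs(x) - a;
        if (xp < 0.0) xp = 0.0;
        return xp * xp + y * y <= R * R;
      }
    }
    return false;
  }

  // index of highest-priority primitive containing the point; -1 if none
  int locate(double x, double y, double z) const {
    for (int i = n - 1; i >= 0; --i)
      if (contains(i, x, y, z)) return i;
    return -1;
  }

  bool in_bbox(double x, double y, double z) const {
    return x >= bb[0] && x <= bb[1] && y >= bb[2] && y <= bb[3] &&
           z >= bb[4] && z <= bb[5];
  }
};
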