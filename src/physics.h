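#pragma once
#include <Rcpp.h>
#include <cmath>

// 511 keV is used as the electron rest energy scale so that the Compton
// closed cases (170.33 keV at 180 deg, 255.5 at 90 deg) are exact.
constexpr double E_REST = 511.0;
constexpr double C_MM_NS = 299.792458;   // speed of light, mm/ns
constexpr double FWHM_TO_SIGMA = 1.0 / 2.3548200450309493;

inline void iso_direction(double* d) {
  double z = 2.0 * unif_rand() - 1.0;
  double ph = 2.0 * M_PI * unif_rand();
  double s = std::sqrt(std::max(0.0, 1.0 - z * z));
  d[0] = s * std::cos(ph);
  d[1] = s * std::sin(ph);
  d[2] = z;
}

// Rotate unit vector d by polar angle theta (cos/sin given) with a uniform
// random azimuth around d.
inline void rotate_direction(double* d, double ct, double st) {
  double e1[3], e2[3];
  if (std::fabs(d[0]) < 0.9) {
    e1[0] = 0.0; e1[1] = -d[2]; e1[2] = d[1];
  } else {
    e1[0] = -d[2]; e1[1] = 0.0; e1[2] = d[0];
  }
  double n = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
  for (int j = 0; j < 3; ++j) e1[j] /= n;
  e2[0] = d[1] * e1[2] - d[2] * e1[1];
  e2[1] = d[2] * e1[0] - d[0] * e1[2];
  e2[2] = d[0] * e1[1] - d[1] * e1[0];
  double ps = 2.0 * M_PI * unif_rand();
  double cp = std::cos(ps), sp = std::sin(ps);
  for (int j = 0; j < 3; ++j)
    d[j] = ct * d[j] + st * (cp * e1[j] + sp * e2[j]);
}

// Klein-Nishina scattering angle by rejection on cos(theta); the envelope
// bound f(cos=1)=2 holds for all photon energies.
inline double sample_kn_costheta(double energy) {
  double alpha = energy / E_REST;
  for (;;) {
    double c = 2.0 * unif_rand() - 1.0;
    double r = 1.0 / (1.0 + alpha * (1.0 - c));  // E'/E
    double f = r * (1.0 + r * r - r * (1.0 - c * c));
    if (unif_rand() * 2.0 < f) return c;
  }
}

inline double compton_scattered_energy(double energy, double costheta) {
  return energy / (1.0 + (energy / E_REST) * (1.0 - costheta));
}

// Energy resolution model: FWHM(E) = res_frac * sqrt(E_REST * E), i.e. the
// fractional resolution scales as sqrt(E_REST/E) from its 511 keV value.
inline double energy_blur_sigma(double edep, double res_frac) {
  return res_frac * std::sqrt(E_REST * edep) * FWHM_TO_SIGMA;
}
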