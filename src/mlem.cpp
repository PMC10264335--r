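#include <Rcpp.h>
#include "grid.h"
#include "physics.h"
using namespace Rcpp;

// List-mode projector: p_ij = intersection length of LOR i with voxel j,
// optionally weighted by a Gaussian TOF kernel centred on the annihilation
// position estimated from the timestamp difference (dt = t1 - t2, ns).

static inline double lor_length(const double* p1, const double* p2) {
  double s = 0.0;
  for (int j = 0; j < 3; ++j) s += (p2[j] - p1[j]) * (p2[j] - p1[j]);
  return std::sqrt(s);
}

// [[Rcpp::export]]
NumericVector forward_project_cpp(NumericVector x, NumericVector origin,
                                  NumericVector spacing, IntegerVector dims,
                                  NumericMatrix p1, NumericMatrix p2,
                                  NumericVector dt_ns, double tof_sigma_mm) {
  Grid g = Grid::make(origin, spacing, dims);
  int n = p1.nrow();
  bool tof = tof_sigma_mm > 0.0 && dt_ns.size() == n;
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double a[3] = {p1(i, 0), p1(i, 1), p1(i, 2)};
    double b[3] = {p2(i, 0), p2(i, 1), p2(i, 2)};
    double L = lor_length(a, b);
    double u0 = tof ? 0.5 * C_MM_NS * dt_ns[i] : 0.0;
    double acc = 0.0;
    trace_segment(g, a, b, [&](long long j, double len, double tm) {
      double w = len;
      if (tof) {
        double u = (tm - 0.5) * L - u0;
        if (std::fabs(u) > 3.5 * tof_sigma_mm) return;
        w *= std::exp(-0.5 * u * u / (tof_sigma_mm * tof_sigma_mm));
      }
      acc += w * x[j];
    });
    y[i] = acc;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector backproject_cpp(NumericVector y, NumericVector origin,
                              NumericVector spacing, IntegerVector dims,
                              NumericMatrix p1, NumericMatrix p2,
                              NumericVector dt_ns, double tof_sigma_mm) {
  Grid g = Grid::make(origin, spacing, dims);
  int n = p1.nrow();
  bool tof = tof_sigma_mm > 0.0 && dt_ns.size() == n;
  NumericVector x((R_xlen_t)g.nvox());
  for (int i = 0; i < n; ++i) {
    if (y[i] == 0.0) continue;
    double a[3] = {p1(i, 0), p1(i, 1), p1(i, 2)};
    double b[3] = {p2(i, 0), p2(i, 1), p2(i, 2)};
    double L = lor_length(a, b);
    double u0 = tof ? 0.5 * C_MM_NS * dt_ns[i] : 0.0;
    trace_segment(g, a, b, [&](long long j, double len, double tm) {
      double w = len;
      if (tof) {
        double u = (tm - 0.5) * L - u0;
        if (std::fabs(u) > 3.5 * tof_sigma_mm) return;
        w *= std::exp(-0.5 * u * u / (tof_sigma_mm * tof_sigma_mm));
      }
      x[j] += w * y[i];
    });
  }
  return x;
}

// [[Rcpp::export]]
NumericVector line_integrals_cpp(NumericVector x, NumericVector origin,
                                 NumericVector spacing, IntegerVector dims,
                                 NumericMatrix p1, NumericMatrix p2) {
  Grid g = Grid::make(origin, spacing, dims);
  int n = p1.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double a[3] = {p1(i, 0), p1(i, 1), p1(i, 2)};
    double b[3] = {p2(i, 0), p2(i, 1), p2(i, 2)};
    double acc = 0.0;
    trace_segment(g, a, b,
                  [&](long long j, double len, double) { acc += len * x[j]; });
    out[i] = acc;
  }
  return out;
}

// [[Rcpp::export]]
List mlem_cpp(NumericMatrix p1, NumericMatrix p2, NumericVector dt_ns,
              double tof_sigma_mm, NumericVector origin, NumericVector spacing,
              IntegerVector dims, NumericVector sens, int n_iter,
              IntegerVector snapshots) {
  Grid g = Grid::make(origin, spacing, dims);
  int n = p1.nrow();
  bool tof = tof_sigma_mm > 0.0 && dt_ns.size() == n;
  R_xlen_t nv = (R_xlen_t)g.nvox();
  if (sens.size() != nv) stop("sensitivity map size mismatch");

  std::vector<double> x(nv), acc(nv);
  bool any_pos = false;
  for (R_xlen_t j = 0; j < nv; ++j) {
    x[j] = sens[j] > 0.0 ? 1.0 : 0.0;
    if (sens[j] > 0.0) any_pos = true;
  }
  if (!any_pos) stop("sensitivity map is identically zero");

  NumericVector loglik(n_iter);
  List images;
  CharacterVector img_names;
  long long skipped = 0;

  for (int it = 0; it < n_iter; ++it) {
    std::fill(acc.begin(), acc.end(), 0.0);
    double ll = 0.0;
    skipped = 0;
    for (int i = 0; i < n; ++i) {
      double a[3] = {p1(i, 0), p1(i, 1), p1(i, 2)};
      double b[3] = {p2(i, 0), p2(i, 1), p2(i, 2)};
      double L = lor_length(a, b);
      double u0 = tof ? 0.5 * C_MM_NS * dt_ns[i] : 0.0;
      double fwd = 0.0;
      trace_segment(g, a, b, [&](long long j, double len, double tm) {
        double w = len;
        if (tof) {
          double u = (tm - 0.5) * L - u0;
          if (std::fabs(u) > 3.5 * tof_sigma_mm) return;
          w *= std::exp(-0.5 * u * u / (tof_sigma_mm * tof_sigma_mm));
        }
        fwd += w * x[j];
      });
      if (fwd <= 0.0) {
        ++skipped;
        continue;
      }
      ll += std::log(fwd);
      double inv = 1.0 / fwd;
      trace_segment(g, a, b, [&](long long j, double len, double tm) {
        double w = len;
        if (tof) {
          double u = (tm - 0.5) * L - u0;
          if (std::fabs(u) > 3.5 * tof_sigma_mm) return;
          w *= std::exp(-0.5 * u * u / (tof_sigma_mm * tof_sigma_mm));
        }
        acc[j] += w * inv;
      });
    }
    // list-mode log-likelihood of the current (pre-update) image
    double sxs = 0.0;
    for (R_xlen_t j = 0; j < nv; ++j) sxs += x[j] * sens[j];
    loglik[it] = ll - sxs;
    for (R_xlen_t j = 0; j < nv; ++j)
      if (sens[j] > 0.0) x[j] = x[j] * acc[j] / sens[j];
    for (int s = 0; s < snapshots.size(); ++s) {
      if (snapshots[s] == it + 1) {
        NumericVector img(nv);
        std::copy(x.begin(), x.end(), img.begin());
        images.push_back(img);
        img_names.push_back(std::to_string(it + 1));
      }
    }
    checkUserInterrupt();
  }
  images.attr("names") = img_names;
  NumericVector xfinal(nv);
  std::copy(x.begin(), x.end(), xfinal.begin());
  return List::create(_["image"] = xfinal, _["snapshots"] = images,
                      _["loglik"] = loglik,
                      _["n_skipped"] = (double)skipped);
}

// Detection probability of back-to-back pairs emitted isotropically from
// given points: chord-based crystal interaction probability on both sides,
// times attenuation survival through an optional mu-map. Used to build the
// MLEM sensitivity map on a coarse lattice.
// [[Rcpp::export]]
NumericVector sens_lattice_cpp(List geom, NumericMatrix points, int n_dirs,
                               double mu_lyso, NumericVector mu,
                               NumericVector origin, NumericVector spacing,
                               IntegerVector dims) {
  Geom G = Geom::from_list(geom);
  bool has_mu = mu.size() > 0;
  Grid g{};
  if (has_mu) g = Grid::make(origin, spacing, dims);
  int np = points.nrow();
  NumericVector out(np);
  for (int ip = 0; ip < np; ++ip) {
    double p[3] = {points(ip, 0), points(ip, 1), points(ip, 2)};
    double acc = 0.0;
    for (int id = 0; id < n_dirs; ++id) {
      double d1[3];
      iso_direction(d1);
      double d2[3] = {-d1[0], -d1[1], -d1[2]};
      Hit h1 = intersect_one(G, p, d1);
      if (h1.module < 0) continue;
      Hit h2 = intersect_one(G, p, d2);
      if (h2.module < 0) continue;
      double pd = (1.0 - std::exp(-mu_lyso * h1.chord)) *
                  (1.0 - std::exp(-mu_lyso * h2.chord));
      if (has_mu) {
        double e1[3], e2[3];
        for (int j = 0; j < 3; ++j) {
          e1[j] = p[j] + h1.t_entry * d1[j];
          e2[j] = p[j] + h2.t_entry * d2[j];
        }
        double li = 0.0;
        trace_segment(g, e1, e2,
                      [&](long long j, double len, double) { li += len * mu[j]; });
        pd *= std::exp(-li);
      }
      acc += pd;
    }
    out[ip] = acc / n_dirs;
    checkUserInterrupt();
  }
  return out;
}
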