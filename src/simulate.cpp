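#include <Rcpp.h>
#include "geom.h"
#include "phantom.h"
#include "physics.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// physics configuration passed once per run
struct Phys {
  double p_full, e_res, t_sigma_ns, mu_lyso, e_cut;
  double acolin_sigma_rad;  // 0 = off
  double prange_w1, prange_m1, prange_m2;  // exponential mixture, mm; m1=m2=0 off
  int mode;                 // 0 back-to-back, 1 F-18
  static Phys from_list(const List& l) {
    Phys p;
    p.p_full = as<double>(l["p_full"]);
    p.e_res = as<double>(l["energy_resolution"]);
    p.t_sigma_ns = as<double>(l["ctr_fwhm_ns"]) * FWHM_TO_SIGMA / std::sqrt(2.0);
    p.mu_lyso = as<double>(l["mu_lyso"]);
    p.e_cut = as<double>(l["energy_cutoff"]);
    p.mode = as<int>(l["mode"]);
    double ac = as<double>(l["acolinearity_fwhm_deg"]);
    p.acolin_sigma_rad = (p.mode == 1) ? ac * M_PI / 180.0 * FWHM_TO_SIGMA : 0.0;
    p.prange_w1 = as<double>(l["prange_w1"]);
    p.prange_m1 = as<double>(l["prange_m1"]);
    p.prange_m2 = as<double>(l["prange_m2"]);
    if (p.mode != 1) { p.prange_m1 = 0.0; p.prange_m2 = 0.0; }
    return p;
  }
};

static bool bbox_entry(const Phantom& P, const double* o, const double* d,
                       double& t0, double& t1) {
  t0 = -1e300; t1 = 1e300;
  if (!axis_clip(o[0], d[0], P.bb[0], P.bb[1], t0, t1)) return false;
  if (!axis_clip(o[1], d[1], P.bb[2], P.bb[3], t0, t1)) return false;
  if (!axis_clip(o[2], d[2], P.bb[4], P.bb[5], t0, t1)) return false;
  return t1 > t0;
}

// Woodcock (delta) tracking through the primitive phantom. Returns true if
// the photon escaped, false if absorbed (photoelectric or below cutoff).
static bool transport_one(const Phantom& P, double* pos, double* dir,
                          double& E, int& nscat, double& path, double e_cut) {
  if (P.n == 0 || P.mu_max <= 0.0) return true;
  for (;;) {
    if (!P.in_bbox(pos[0], pos[1], pos[2])) {
      double t0, t1;
      if (!bbox_entry(P, pos, dir, t0, t1) || t1 <= 1e-9) return true;
      double adv = std::max(t0, 0.0) + 1e-9;
      for (int j = 0; j < 3; ++j) pos[j] += adv * dir[j];
      path += adv;
      continue;
    }
    double t0, t1;
    bbox_entry(P, pos, dir, t0, t1);  // inside the bbox: t0 < 0 < t1
    double s = exp_rand() / P.mu_max;
    if (s >= t1) {
      // escapes: leave the photon just outside the bbox on its line of
      // flight (the free path beyond the phantom is irrelevant)
      double adv = t1 + 1e-9;
      for (int j = 0; j < 3; ++j) pos[j] += adv * dir[j];
      path += adv;
      return true;
    }
    for (int j = 0; j < 3; ++j) pos[j] += s * dir[j];
    path += s;
    int i = P.locate(pos[0], pos[1], pos[2]);
    if (i < 0) continue;
    if (unif_rand() * P.mu_max > P.mu[i]) continue;  // virtual interaction
    if (unif_rand() < P.cf[i]) {
      double ct = sample_kn_costheta(E);
      double enew = compton_scattered_energy(E, ct);
      rotate_direction(dir, ct, std::sqrt(std::max(0.0, 1.0 - ct * ct)));
      E = enew;
      ++nscat;
      if (E < e_cut) return false;
    } else {
      return false;  // photoelectric absorption
    }
  }
}

struct SingleRec {
  int module;
  double ix, iy, iz, edep, emeas, t;
};

// fate: 1 detected, 2 escaped without hitting a module, 3 hit but no interaction
static int detect_one(const Geom& G, const double* pos, const double* dir,
                      double E, double path0, double tdecay_ns, const Phys& ph,
                      SingleRec& out) {
  Hit h = intersect_one(G, pos, dir);
  if (h.module < 0) return 2;
  double pint = 1.0 - std::exp(-ph.mu_lyso * h.chord);
  double u = unif_rand();
  if (u >= pint) return 3;
  double depth = -std::log(1.0 - u) / ph.mu_lyso;  // truncated exp given u < pint
  double travel = h.t_entry + depth;
  double edep;
  if (unif_rand() < ph.p_full) {
    edep = E;  // photopeak: full deposit (photoelectric or recovered multi-site)
  } else {
    double ct = sample_kn_costheta(E);
    edep = E - compton_scattered_energy(E, ct);  // Compton escape
    if (edep < 1e-6) edep = 1e-6;
  }
  double emeas = edep + energy_blur_sigma(edep, ph.e_res) * norm_rand();
  if (emeas < 1e-3) emeas = 1e-3;
  out.module = h.module + 1;  // 1-based for R
  out.ix = pos[0] + travel * dir[0];
  out.iy = pos[1] + travel * dir[1];
  out.iz = pos[2] + travel * dir[2];
  out.edep = edep;
  out.emeas = emeas;
  out.t = tdecay_ns + (path0 + travel) / C_MM_NS + ph.t_sigma_ns * norm_rand();
  return 1;
}

static void emit_pair_dirs(const Phys& ph, double* d1, double* d2) {
  iso_direction(d1);
  for (int j = 0; j < 3; ++j) d2[j] = -d1[j];
  if (ph.acolin_sigma_rad > 0.0) {
    double dev = std::fabs(norm_rand()) * ph.acolin_sigma_rad;
    rotate_direction(d2, std::cos(dev), std::sin(dev));
  }
}

// ---------------------------------------------------------------------------
// source sampling
struct Source {
  int kind;  // 0 line, 1 point, 2 volume
  double p0[3], p1[3];
  std::vector<int> reg_shape, reg_prim;
  std::vector<std::array<double, 7>> reg_par;
  std::vector<double> cumw;
  const Phantom* P;

  static Source from_list(const List& l, const Phantom* P) {
    Source s;
    s.P = P;
    s.kind = as<int>(l["kind"]);
    if (s.kind == 0 || s.kind == 1) {
      NumericVector a = l["p0"];
      for (int j = 0; j < 3; ++j) s.p0[j] = a[j];
      if (s.kind == 0) {
        NumericVector b = l["p1"];
        for (int j = 0; j < 3; ++j) s.p1[j] = b[j];
      }
    } else {
      NumericMatrix reg = l["regions"];  // shape, par1..7, prim_idx (1-based)
      NumericVector w = l["weights"];
      double tot = 0.0;
      for (int i = 0; i < reg.nrow(); ++i) {
        s.reg_shape.push_back((int)reg(i, 0));
        std::array<double, 7> pr;
        for (int j = 0; j < 7; ++j) pr[j] = reg(i, 1 + j);
        s.reg_par.push_back(pr);
        s.reg_prim.push_back((int)reg(i, 8) - 1);
        tot += w[i];
        s.cumw.push_back(tot);
      }
      for (size_t i = 0; i < s.cumw.size(); ++i) s.cumw[i] /= tot;
    }
    return s;
  }

  void sample_in_shape(int i, double* p) const {
    const std::array<double, 7>& q = reg_par[i];
    switch (reg_shape[i]) {
      case 0: {
        double r = q[3] * std::sqrt(unif_rand());
        double th = 2.0 * M_PI * unif_rand();
        p[0] = q[0] + r * std::cos(th);
        p[1] = q[1] + r * std::sin(th);
        p[2] = q[2] + (2.0 * unif_rand() - 1.0) * q[4];
        break;
      }
      case 1: {
        double d[3];
        iso_direction(d);
        double r = q[3] * std::cbrt(unif_rand());
        for (int j = 0; j < 3; ++j) p[j] = q[j] + r * d[j];
        break;
      }
      case 2:
        for (int j = 0; j < 3; ++j)
          p[j] = q[j] + (2.0 * unif_rand() - 1.0) * q[3 + j];
        break;
      case 3: {
        double a = q[2], R = q[3];
        for (;;) {
          double x = (2.0 * unif_rand() - 1.0) * (a + R);
          double y = (2.0 * unif_rand() - 1.0) * R;
          double xp = std::fabs(x) - a;
          if (xp < 0.0) xp = 0.0;
          if (xp * xp + y * y <= R * R) { p[0] = x; p[1] = y; break; }
        }
        p[2] = q[0] + (2.0 * unif_rand() - 1.0) * q[1];
        break;
      }
    }
  }

  void sample(double* pos) const {
    if (kind == 1) {
      for (int j = 0; j < 3; ++j) pos[j] = p0[j];
    } else if (kind == 0) {
      double u = unif_rand();
      for (int j = 0; j < 3; ++j) pos[j] = p0[j] + u * (p1[j] - p0[j]);
    } else {
      double u = unif_rand();
      int i = 0;
      while (i + 1 < (int)cumw.size() && u > cumw[i]) ++i;
      for (int it = 0; it < 10000; ++it) {
        sample_in_shape(i, pos);
        if (P->locate(pos[0], pos[1], pos[2]) == reg_prim[i]) return;
      }
      stop("volume source sampling failed: region unreachable");
    }
  }
};

// ---------------------------------------------------------------------------
// exported operations (unit-level surfaces + fused end-to-end run)

// [[Rcpp::export]]
List intersect_rays_cpp(List geom, NumericMatrix origins, NumericMatrix dirs) {
  Geom G = Geom::from_list(geom);
  int n = origins.nrow();
  IntegerVector module(n);
  NumericMatrix entry(n, 3);
  NumericVector chord(n), tmin(n);
  for (int i = 0; i < n; ++i) {
    double o[3] = {origins(i, 0), origins(i, 1), origins(i, 2)};
    double d[3] = {dirs(i, 0), dirs(i, 1), dirs(i, 2)};
    Hit h = intersect_one(G, o, d);
    module[i] = h.module + 1;  // 0 means none
    if (h.module >= 0) {
      for (int j = 0; j < 3; ++j) entry(i, j) = o[j] + h.t_entry * d[j];
      chord[i] = h.chord;
      tmin[i] = h.t_entry;
    } else {
      entry(i, 0) = entry(i, 1) = entry(i, 2) = NA_REAL;
      chord[i] = NA_REAL;
      tmin[i] = NA_REAL;
    }
  }
  return List::create(_["module"] = module, _["entry"] = entry,
                      _["chord"] = chord, _["t_entry"] = tmin);
}

// [[Rcpp::export]]
List emit_pairs_cpp(int n, List phys) {
  Phys ph = Phys::from_list(phys);
  NumericMatrix d1(n, 3), d2(n, 3);
  for (int i = 0; i < n; ++i) {
    double a[3], b[3];
    emit_pair_dirs(ph, a, b);
    for (int j = 0; j < 3; ++j) { d1(i, j) = a[j]; d2(i, j) = b[j]; }
  }
  return List::create(_["d1"] = d1, _["d2"] = d2);
}

// [[Rcpp::export]]
List transport_photons_cpp(NumericMatrix pos, NumericMatrix dir,
                           NumericVector energy, NumericMatrix phantom,
                           NumericVector phantom_aux, double e_cut) {
  Phantom P = Phantom::from_matrix(phantom, phantom_aux);
  int n = pos.nrow();
  NumericMatrix out_pos(n, 3), out_dir(n, 3);
  NumericVector out_e(n), out_path(n);
  IntegerVector out_nscat(n), escaped(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    double d[3] = {dir(i, 0), dir(i, 1), dir(i, 2)};
    double E = energy[i], path = 0.0;
    int ns = 0;
    bool esc = transport_one(P, p, d, E, ns, path, e_cut);
    for (int j = 0; j < 3; ++j) { out_pos(i, j) = p[j]; out_dir(i, j) = d[j]; }
    out_e[i] = E;
    out_path[i] = path;
    out_nscat[i] = ns;
    escaped[i] = esc ? 1 : 0;
  }
  return List::create(_["pos"] = out_pos, _["dir"] = out_dir,
                      _["energy"] = out_e, _["path"] = out_path,
                      _["n_scatters"] = out_nscat, _["escaped"] = escaped);
}

// [[Rcpp::export]]
List detect_photons_cpp(NumericMatrix pos, NumericMatrix dir,
                        NumericVector energy, NumericVector path0,
                        NumericVector tdecay_ns, List geom, List phys) {
  Geom G = Geom::from_list(geom);
  Phys ph = Phys::from_list(phys);
  int n = pos.nrow();
  IntegerVector module(n), fate(n);
  NumericMatrix ipt(n, 3);
  NumericVector edep(n), emeas(n), tns(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    double d[3] = {dir(i, 0), dir(i, 1), dir(i, 2)};
    SingleRec s;
    int f = detect_one(G, p, d, energy[i], path0[i], tdecay_ns[i], ph, s);
    fate[i] = f;
    if (f == 1) {
      module[i] = s.module;
      ipt(i, 0) = s.ix; ipt(i, 1) = s.iy; ipt(i, 2) = s.iz;
      edep[i] = s.edep; emeas[i] = s.emeas; tns[i] = s.t;
    } else {
      module[i] = 0;
      ipt(i, 0) = ipt(i, 1) = ipt(i, 2) = NA_REAL;
      edep[i] = NA_REAL; emeas[i] = NA_REAL; tns[i] = NA_REAL;
    }
  }
  return List::create(_["module"] = module, _["point"] = ipt,
                      _["energy_dep"] = edep, _["energy_meas"] = emeas,
                      _["t_ns"] = tns, _["fate"] = fate);
}

// [[Rcpp::export]]
List simulate_singles_cpp(List geom, NumericMatrix phantom,
                          NumericVector phantom_aux, List source,
                          double n_decays, double duration_ns, List phys) {
  Geom G = Geom::from_list(geom);
  Phantom P = Phantom::from_matrix(phantom, phantom_aux);
  Phys ph = Phys::from_list(phys);
  Source S = Source::from_list(source, &P);

  long long nd = (long long)n_decays;
  std::vector<double> o_id, o_x, o_y, o_z, o_edep, o_emeas, o_t;
  std::vector<int> o_mod, o_nscat;
  size_t reserve = (size_t)std::min((double)nd / 8.0, 4e6);
  o_id.reserve(reserve);

  long long absorbed = 0, undetected = 0, missed = 0, detected = 0;

  for (long long i = 0; i < nd; ++i) {
    double tdec = unif_rand() * duration_ns;
    double apos[3];
    S.sample(apos);
    if (ph.prange_m1 > 0.0 || ph.prange_m2 > 0.0) {
      double r = (unif_rand() < ph.prange_w1)
                     ? exp_rand() * ph.prange_m1
                     : exp_rand() * ph.prange_m2;
      double d[3];
      iso_direction(d);
      for (int j = 0; j < 3; ++j) apos[j] += r * d[j];
    }
    double d1[3], d2[3];
    emit_pair_dirs(ph, d1, d2);
    double* dd[2] = {d1, d2};
    for (int k = 0; k < 2; ++k) {
      double p[3] = {apos[0], apos[1], apos[2]};
      double dir[3] = {dd[k][0], dd[k][1], dd[k][2]};
      double E = E_REST, path = 0.0;
      int ns = 0;
      if (!transport_one(P, p, dir, E, ns, path, ph.e_cut)) {
        ++absorbed;
        continue;
      }
      SingleRec s;
      int f = detect_one(G, p, dir, E, path, tdec, ph, s);
      if (f == 2) { ++undetected; continue; }
      if (f == 3) { ++missed; continue; }
      ++detected;
      o_id.push_back((double)(i + 1));
      o_mod.push_back(s.module);
      o_x.push_back(s.ix); o_y.push_back(s.iy); o_z.push_back(s.iz);
      o_edep.push_back(s.edep); o_emeas.push_back(s.emeas);
      o_t.push_back(s.t);
      o_nscat.push_back(ns);
    }
    if ((i & 0xFFFFF) == 0) checkUserInterrupt();
  }

  List tallies = List::create(
      _["decays"] = (double)nd, _["photons"] = (double)(2 * nd),
      _["absorbed_phantom"] = (double)absorbed,
      _["escaped_undetected"] = (double)undetected,
      _["missed_crystal"] = (double)missed, _["detected"] = (double)detected);
  // copy one column at a time, releasing each buffer immediately, to keep
  // the peak footprint low on large runs
  List out(10);
  CharacterVector nm = CharacterVector::create(
      "decay_id", "module", "x", "y", "z", "energy_dep", "energy", "t_ns",
      "n_scatters", "tallies");
  auto take_d = [](std::vector<double>& v) {
    NumericVector r(v.begin(), v.end());
    std::vector<double>().swap(v);
    return r;
  };
  auto take_i = [](std::vector<int>& v) {
    IntegerVector r(v.begin(), v.end());
    std::vector<int>().swap(v);
    return r;
  };
  out[0] = take_d(o_id);
  out[1] = take_i(o_mod);
  out[2] = take_d(o_x);
  out[3] = take_d(o_y);
  out[4] = take_d(o_z);
  out[5] = take_d(o_edep);
  out[6] = take_d(o_emeas);
  out[7] = take_d(o_t);
  out[8] = take_i(o_nscat);
  out[9] = tallies;
  out.attr("names") = nm;
  return out;
}

// [[Rcpp::export]]
List pair_coincidences_cpp(NumericVector t, IntegerVector module,
                           double window_ns, int policy) {
  // policy: 0 = killAll (discard multiples), 1 = takeAllGoods
  int n = t.size();
  std::vector<int> ii, jj;
  int k = 0;
  while (k < n) {
    int m = k;
    while (m + 1 < n && t[m + 1] - t[k] <= window_ns) ++m;
    int size = m - k + 1;
    if (size == 2) {
      if (module[k] != module[k + 1]) { ii.push_back(k + 1); jj.push_back(m + 1); }
    } else if (size > 2 && policy == 1) {
      for (int a = k; a <= m; ++a)
        for (int b = a + 1; b <= m; ++b)
          if (module[a] != module[b]) { ii.push_back(a + 1); jj.push_back(b + 1); }
    }
    k = m + 1;
  }
  return List::create(_["i"] = IntegerVector(ii.begin(), ii.end()),
                      _["j"] = IntegerVector(jj.begin(), jj.end()));
}
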