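// Inner loops for the toy samplers: analytic term-sum potentials,
// overdamped Langevin dynamics, grid-accumulated well-tempered
// metadynamics, and 1-D adaptive biasing force.  All randomness comes
// from R's RNG so that set.seed() gives bit-reproducible runs.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

enum TermType {
  T_BUMP = 1, T_HARMONIC, T_DOUBLEWELL, T_SWITCH_HARMONIC,
  T_RADIAL_BUMP, T_RADIAL_SWITCH_HARMONIC, T_RADIAL_HARMONIC,
  T_CYLINDER_WALL, T_LOWER_WALL, T_UPPER_WALL, T_LOG_SIN, T_GAUSSIAN,
  T_FADE_HARMONIC
};

struct Term {
  int type;
  std::vector<int> dims;     // 0-based coordinate indices
  std::vector<double> center;
  std::vector<double> sigma;
  double a, b, c, d, e;      // meaning depends on type
};

static int type_code(const std::string &s) {
  if (s == "bump") return T_BUMP;
  if (s == "harmonic") return T_HARMONIC;
  if (s == "doublewell") return T_DOUBLEWELL;
  if (s == "switch_harmonic") return T_SWITCH_HARMONIC;
  if (s == "radial_bump") return T_RADIAL_BUMP;
  if (s == "radial_switch_harmonic") return T_RADIAL_SWITCH_HARMONIC;
  if (s == "radial_harmonic") return T_RADIAL_HARMONIC;
  if (s == "cylinder_wall") return T_CYLINDER_WALL;
  if (s == "lower_wall") return T_LOWER_WALL;
  if (s == "upper_wall") return T_UPPER_WALL;
  if (s == "log_sin") return T_LOG_SIN;
  if (s == "gaussian") return T_GAUSSIAN;
  if (s == "fade_harmonic") return T_FADE_HARMONIC;
  stop("unknown potential term type: " + s);
  return 0;
}

static std::vector<Term> parse_terms(List terms) {
  std::vector<Term> out;
  for (int i = 0; i < terms.size(); ++i) {
    List tl = terms[i];
    Term t;
    t.type = type_code(as<std::string>(tl["type"]));
    IntegerVector d = tl["dims"];
    for (int k = 0; k < d.size(); ++k) t.dims.push_back(d[k] - 1);
    if (tl.containsElementNamed("center")) {
      NumericVector c = tl["center"];
      for (int k = 0; k < c.size(); ++k) t.center.push_back(c[k]);
    }
    if (tl.containsElementNamed("sigma")) {
      NumericVector s = tl["sigma"];
      for (int k = 0; k < s.size(); ++k) t.sigma.push_back(s[k]);
    }
    t.a = tl.containsElementNamed("a") ? as<double>(tl["a"]) : 0.0;
    t.b = tl.containsElementNamed("b") ? as<double>(tl["b"]) : 0.0;
    t.c = tl.containsElementNamed("c") ? as<double>(tl["c"]) : 0.0;
    t.d = tl.containsElementNamed("d") ? as<double>(tl["d"]) : 0.0;
    t.e = tl.containsElementNamed("e") ? as<double>(tl["e"]) : 0.0;
    out.push_back(t);
  }
  return out;
}

// quintic smoothstep: C^2, S(0)=0, S(1)=1
static inline double sstep(double u, double &dS) {
  if (u <= 0.0) { dS = 0.0; return 0.0; }
  if (u >= 1.0) { dS = 0.0; return 1.0; }
  double u2 = u * u;
  dS = 30.0 * u2 * (u - 1.0) * (u - 1.0);
  return u2 * u * (10.0 + u * (-15.0 + 6.0 * u));
}

static inline double rad_dist(const Term &t, const double *x,
                              std::vector<double> &dx) {
  double s = 0.0;
  for (size_t k = 0; k < t.dims.size(); ++k) {
    double c = k < t.center.size() ? t.center[k] : 0.0;
    dx[k] = x[t.dims[k]] - c;
    s += dx[k] * dx[k];
  }
  return std::sqrt(s);
}

// energy of one term; if grad != NULL accumulate dE/dx into it
static double term_eval(const Term &t, const double *x, double *grad) {
  switch (t.type) {
  case T_BUMP: {
    // a * (1 - u^2)^2 on |u|<1, u = (x-c)/b  (compact support)
    double u = (x[t.dims[0]] - t.c) / t.b;
    if (u <= -1.0 || u >= 1.0) return 0.0;
    double q = 1.0 - u * u;
    if (grad) grad[t.dims[0]] += -4.0 * t.a * u * q / t.b;
    return t.a * q * q;
  }
  case T_HARMONIC: {
    double d = x[t.dims[0]] - t.c;
    if (grad) grad[t.dims[0]] += t.a * d;
    return 0.5 * t.a * d * d;
  }
  case T_DOUBLEWELL: {
    // a * (u^2 - 1)^2, u = (x-c)/b : minima at c +/- b, barrier a
    double u = (x[t.dims[0]] - t.c) / t.b;
    double q = u * u - 1.0;
    if (grad) grad[t.dims[0]] += 4.0 * t.a * u * q / t.b;
    return t.a * q * q;
  }
  case T_SWITCH_HARMONIC: {
    // (a/2) * (x_i - cref(x_j))^2, cref = b + (c-b)*S((x_j-d)/(e-d))
    double u = (x[t.dims[1]] - t.d) / (t.e - t.d);
    double dS;
    double S = sstep(u, dS);
    double cref = t.b + (t.c - t.b) * S;
    double del = x[t.dims[0]] - cref;
    if (grad) {
      grad[t.dims[0]] += t.a * del;
      grad[t.dims[1]] += -t.a * del * (t.c - t.b) * dS / (t.e - t.d);
    }
    return 0.5 * t.a * del * del;
  }
  case T_RADIAL_BUMP: {
    std::vector<double> dx(t.dims.size());
    double r = rad_dist(t, x, dx);
    double u = (r - t.c) / t.b;
    if (u <= -1.0 || u >= 1.0) return 0.0;
    double q = 1.0 - u * u;
    if (grad) {
      double dEdr = -4.0 * t.a * u * q / t.b;
      // dEdr/r finite as r->0 when c==0 (u = r/b); for an off-centre
      // bump the gradient at the symmetric point r=0 is zero
      double f = (r > 1e-12) ? dEdr / r
                             : (t.c == 0.0 ? -4.0 * t.a / (t.b * t.b) : 0.0);
      for (size_t k = 0; k < t.dims.size(); ++k)
        grad[t.dims[k]] += f * dx[k];
    }
    return t.a * q * q;
  }
  case T_RADIAL_SWITCH_HARMONIC: {
    // (a/2)*(x_i - cref(r))^2 with r over dims[1..]
    Term rt = t;
    rt.dims.assign(t.dims.begin() + 1, t.dims.end());
    std::vector<double> dx(rt.dims.size());
    double r = rad_dist(rt, x, dx);
    double u = (r - t.d) / (t.e - t.d);
    double dS;
    double S = sstep(u, dS);
    double cref = t.b + (t.c - t.b) * S;
    double del = x[t.dims[0]] - cref;
    if (grad) {
      grad[t.dims[0]] += t.a * del;
      double dEdr = -t.a * del * (t.c - t.b) * dS / (t.e - t.d);
      if (r > 1e-12) {
        for (size_t k = 0; k < rt.dims.size(); ++k)
          grad[rt.dims[k]] += dEdr * dx[k] / r;
      }
    }
    return 0.5 * t.a * del * del;
  }
  case T_RADIAL_HARMONIC: {
    std::vector<double> dx(t.dims.size());
    double r = rad_dist(t, x, dx);
    double del = r - t.c;
    if (grad && r > 1e-12) {
      for (size_t k = 0; k < t.dims.size(); ++k)
        grad[t.dims[k]] += t.a * del * dx[k] / r;
    }
    return 0.5 * t.a * del * del;
  }
  case T_CYLINDER_WALL: {
    // one-sided wall at rho = b (radius), k = a, over two perp dims
    std::vector<double> dx(t.dims.size());
    double rho = rad_dist(t, x, dx);
    if (rho <= t.b) return 0.0;
    double del = rho - t.b;
    if (grad && rho > 1e-12) {
      for (size_t k = 0; k < t.dims.size(); ++k)
        grad[t.dims[k]] += t.a * del * dx[k] / rho;
    }
    return 0.5 * t.a * del * del;
  }
  case T_LOWER_WALL: {
    double d = x[t.dims[0]] - t.c;
    if (d >= 0.0) return 0.0;
    if (grad) grad[t.dims[0]] += t.a * d;
    return 0.5 * t.a * d * d;
  }
  case T_UPPER_WALL: {
    double d = x[t.dims[0]] - t.c;
    if (d <= 0.0) return 0.0;
    if (grad) grad[t.dims[0]] += t.a * d;
    return 0.5 * t.a * d * d;
  }
  case T_LOG_SIN: {
    // -a * log(sin(scale * x)), scale = b (e.g. pi/180 for degrees);
    // clamped flat (zero gradient) once sin drops below the floor
    double th = t.b * x[t.dims[0]];
    double s = std::sin(th);
    if (s < 1e-10) return -t.a * std::log(1e-10);
    if (grad) grad[t.dims[0]] += -t.a * t.b * std::cos(th) / s;
    return -t.a * std::log(s);
  }
  case T_FADE_HARMONIC: {
    // (a/2)(x_i - b)^2 * (1 - S(u)), u = (x_j - d)/(e - d): a harmonic
    // confinement that fades out as the switch coordinate crosses [d, e]
    double u = (x[t.dims[1]] - t.d) / (t.e - t.d);
    double dS;
    double S = sstep(u, dS);
    double del = x[t.dims[0]] - t.b;
    if (grad) {
      grad[t.dims[0]] += t.a * del * (1.0 - S);
      grad[t.dims[1]] += -0.5 * t.a * del * del * dS / (t.e - t.d);
    }
    return 0.5 * t.a * del * del * (1.0 - S);
  }
  case T_GAUSSIAN: {
    double ex = 0.0;
    for (size_t k = 0; k < t.dims.size(); ++k) {
      double d = x[t.dims[k]] - t.center[k];
      ex += d * d / (2.0 * t.sigma[k] * t.sigma[k]);
    }
    double E = t.a * std::exp(-ex);
    if (grad) {
      for (size_t k = 0; k < t.dims.size(); ++k) {
        double d = x[t.dims[k]] - t.center[k];
        grad[t.dims[k]] += -E * d / (t.sigma[k] * t.sigma[k]);
      }
    }
    return E;
  }
  }
  return 0.0;
}

static double pot_eval(const std::vector<Term> &ts, const double *x,
                       double *grad, int ndim) {
  if (grad) for (int k = 0; k < ndim; ++k) grad[k] = 0.0;
  double E = 0.0;
  for (size_t i = 0; i < ts.size(); ++i) E += term_eval(ts[i], x, grad);
  return E;
}

// [[Rcpp::export]]
NumericVector cpp_pot_energy(List terms, NumericMatrix X) {
  std::vector<Term> ts = parse_terms(terms);
  int n = X.nrow(), nd = X.ncol();
  NumericVector out(n);
  std::vector<double> x(nd);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < nd; ++k) x[k] = X(i, k);
    out[i] = pot_eval(ts, x.data(), NULL, nd);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_pot_grad(List terms, NumericVector x) {
  std::vector<Term> ts = parse_terms(terms);
  int nd = x.size();
  NumericVector g(nd);
  std::vector<double> xx(nd), gg(nd);
  for (int k = 0; k < nd; ++k) xx[k] = x[k];
  pot_eval(ts, xx.data(), gg.data(), nd);
  for (int k = 0; k < nd; ++k) g[k] = gg[k];
  return g;
}

struct Wrap {
  std::vector<int> dims;
  std::vector<double> lo, hi;
};

static Wrap parse_wrap(List wrap) {
  Wrap w;
  if (wrap.size() == 0) return w;
  IntegerVector d = wrap["dims"];
  NumericVector lo = wrap["lo"], hi = wrap["hi"];
  for (int k = 0; k < d.size(); ++k) {
    w.dims.push_back(d[k] - 1);
    w.lo.push_back(lo[k]);
    w.hi.push_back(hi[k]);
  }
  return w;
}

static inline void apply_wrap(const Wrap &w, double *x) {
  for (size_t k = 0; k < w.dims.size(); ++k) {
    double L = w.hi[k] - w.lo[k];
    double u = (x[w.dims[k]] - w.lo[k]) / L;
    x[w.dims[k]] = w.lo[k] + (u - std::floor(u)) * L;
  }
}

static void check_domain(const double *x, int nd, const double *lo,
                         const double *hi, double margin, double time) {
  for (int k = 0; k < nd; ++k) {
    if (R_finite(lo[k]) && x[k] < lo[k] - margin)
      stop("Langevin dynamics diverged: coordinate %d left the domain at t = %g ps", k + 1, time);
    if (R_finite(hi[k]) && x[k] > hi[k] + margin)
      stop("Langevin dynamics diverged: coordinate %d left the domain at t = %g ps", k + 1, time);
  }
}

// Overdamped Euler-Maruyama: dx = -grad(U) dt / gamma + N(0, 2 kT dt / gamma)
// [[Rcpp::export]]
List cpp_langevin(List terms, NumericVector x0, double dt, double friction,
                  int n_steps, int save_stride, double kT,
                  NumericVector lower, NumericVector upper, double margin,
                  List wrap) {
  std::vector<Term> ts = parse_terms(terms);
  Wrap wr = parse_wrap(wrap);
  int nd = x0.size();
  int nf = n_steps / save_stride + 1;
  NumericMatrix coords(nf, nd);
  NumericVector times(nf);
  std::vector<double> x(nd), g(nd);
  for (int k = 0; k < nd; ++k) { x[k] = x0[k]; coords(0, k) = x0[k]; }
  times[0] = 0.0;
  double mob = dt / friction;
  double nsd = std::sqrt(2.0 * kT * dt / friction);
  int fi = 1;
  for (int s = 1; s <= n_steps; ++s) {
    pot_eval(ts, x.data(), g.data(), nd);
    for (int k = 0; k < nd; ++k)
      x[k] += -g[k] * mob + (nsd > 0.0 ? nsd * norm_rand() : 0.0);
    apply_wrap(wr, x.data());
    if (s % 1000 == 0)
      check_domain(x.data(), nd, REAL(lower), REAL(upper), margin, s * dt);
    if (s % save_stride == 0 && fi < nf) {
      for (int k = 0; k < nd; ++k) coords(fi, k) = x[k];
      times[fi] = s * dt;
      ++fi;
    }
  }
  check_domain(x.data(), nd, REAL(lower), REAL(upper), margin, n_steps * dt);
  return List::create(_["times"] = times, _["coords"] = coords);
}

struct BiasGrid {
  int ncv;
  int nb[2];
  double lo[2], dx[2];
  std::vector<double> V, d1, d2, Vsum;
  long navg;
  BiasGrid(int ncv_, const double *lo_, const double *hi_, const int *nb_)
      : ncv(ncv_), navg(0) {
    long tot = 1;
    for (int k = 0; k < ncv; ++k) {
      nb[k] = nb_[k];
      lo[k] = lo_[k];
      dx[k] = (hi_[k] - lo_[k]) / nb_[k];
      tot *= nb_[k];
    }
    if (ncv == 1) nb[1] = 1;
    V.assign(tot, 0.0);
    d1.assign(tot, 0.0);
    d2.assign(ncv == 2 ? tot : 0, 0.0);
    Vsum.assign(tot, 0.0);
  }
  inline double center(int k, int i) const { return lo[k] + (i + 0.5) * dx[k]; }
  inline long idx(int i, int j) const { return (long)j * nb[0] + i; }
  // linear interpolation between bin centers, clamped at edges
  void interp(const double *s, double &V_out, double *g_out) const {
    double u0 = (s[0] - center(0, 0)) / dx[0];
    int i0 = (int)std::floor(u0);
    if (i0 < 0) i0 = 0;
    if (i0 > nb[0] - 2) i0 = nb[0] - 2;
    double f0 = u0 - i0;
    if (f0 < 0) f0 = 0;
    if (f0 > 1) f0 = 1;
    if (ncv == 1) {
      V_out = (1 - f0) * V[i0] + f0 * V[i0 + 1];
      g_out[0] = (1 - f0) * d1[i0] + f0 * d1[i0 + 1];
      return;
    }
    double u1 = (s[1] - center(1, 0)) / dx[1];
    int j0 = (int)std::floor(u1);
    if (j0 < 0) j0 = 0;
    if (j0 > nb[1] - 2) j0 = nb[1] - 2;
    double f1 = u1 - j0;
    if (f1 < 0) f1 = 0;
    if (f1 > 1) f1 = 1;
    double w00 = (1 - f0) * (1 - f1), w10 = f0 * (1 - f1);
    double w01 = (1 - f0) * f1, w11 = f0 * f1;
    long a = idx(i0, j0), b = idx(i0 + 1, j0), c = idx(i0, j0 + 1),
         d = idx(i0 + 1, j0 + 1);
    V_out = w00 * V[a] + w10 * V[b] + w01 * V[c] + w11 * V[d];
    g_out[0] = w00 * d1[a] + w10 * d1[b] + w01 * d1[c] + w11 * d1[d];
    g_out[1] = w00 * d2[a] + w10 * d2[b] + w01 * d2[c] + w11 * d2[d];
  }
  void add_hill(const double *c, const double *sig, double h, double cutoff) {
    int lo0 = (int)std::floor((c[0] - cutoff * sig[0] - center(0, 0)) / dx[0]);
    int hi0 = (int)std::ceil((c[0] + cutoff * sig[0] - center(0, 0)) / dx[0]);
    if (lo0 < 0) lo0 = 0;
    if (hi0 > nb[0] - 1) hi0 = nb[0] - 1;
    if (ncv == 1) {
      for (int i = lo0; i <= hi0; ++i) {
        double d0 = center(0, i) - c[0];
        double e = h * std::exp(-d0 * d0 / (2 * sig[0] * sig[0]));
        V[i] += e;
        d1[i] += -e * d0 / (sig[0] * sig[0]);
      }
      return;
    }
    int lo1 = (int)std::floor((c[1] - cutoff * sig[1] - center(1, 0)) / dx[1]);
    int hi1 = (int)std::ceil((c[1] + cutoff * sig[1] - center(1, 0)) / dx[1]);
    if (lo1 < 0) lo1 = 0;
    if (hi1 > nb[1] - 1) hi1 = nb[1] - 1;
    for (int j = lo1; j <= hi1; ++j) {
      double e1 = center(1, j) - c[1];
      double g1 = std::exp(-e1 * e1 / (2 * sig[1] * sig[1]));
      for (int i = lo0; i <= hi0; ++i) {
        double d0 = center(0, i) - c[0];
        double e = h * g1 * std::exp(-d0 * d0 / (2 * sig[0] * sig[0]));
        long id = idx(i, j);
        V[id] += e;
        d1[id] += -e * d0 / (sig[0] * sig[0]);
        d2[id] += -e * e1 / (sig[1] * sig[1]);
      }
    }
  }
};

// Well-tempered metadynamics with grid-accumulated bias.  CVs are
// coordinate projections (cv_dims).  The funnel/extra walls are part of
// `terms`.  Hills outside the grid range are deposited at the clamped
// grid position and counted.
// [[Rcpp::export]]
List cpp_metad(List terms, NumericVector x0, double dt, double friction,
               int n_steps, int save_stride, double kT,
               IntegerVector cv_dims, NumericVector grid_min,
               NumericVector grid_max, IntegerVector nbins,
               NumericVector sigma, double omega, int tau_steps,
               double kb_deltaT, double avg_start_frac,
               NumericVector lower, NumericVector upper, double margin,
               List wrap) {
  std::vector<Term> ts = parse_terms(terms);
  Wrap wr = parse_wrap(wrap);
  int nd = x0.size();
  int ncv = cv_dims.size();
  if (ncv < 1 || ncv > 2) stop("only 1 or 2 collective variables supported");
  double glo[2], ghi[2];
  int gnb[2];
  for (int k = 0; k < ncv; ++k) {
    glo[k] = grid_min[k];
    ghi[k] = grid_max[k];
    gnb[k] = nbins[k];
  }
  BiasGrid grid(ncv, glo, ghi, gnb);
  int n_hills_max = n_steps / tau_steps;
  long avg_from = (long)std::floor(avg_start_frac * n_hills_max);
  NumericMatrix hills(n_hills_max, 2 + 2 * ncv); // time, centers, sigmas, height
  int nf = n_steps / save_stride + 1;
  NumericMatrix cvtraj(nf, ncv);
  NumericMatrix coords(nf, nd);
  NumericVector times(nf);
  std::vector<double> x(nd), g(nd);
  double s[2], bg[2] = {0, 0}, Vh;
  for (int k = 0; k < nd; ++k) { x[k] = x0[k]; coords(0, k) = x0[k]; }
  for (int k = 0; k < ncv; ++k) cvtraj(0, k) = x[cv_dims[k] - 1];
  int fi = 1, nh = 0, clamped = 0;
  double mob = dt / friction;
  double nsd = std::sqrt(2.0 * kT * dt / friction);
  for (int stp = 1; stp <= n_steps; ++stp) {
    pot_eval(ts, x.data(), g.data(), nd);
    for (int k = 0; k < ncv; ++k) s[k] = x[cv_dims[k] - 1];
    grid.interp(s, Vh, bg);
    for (int k = 0; k < ncv; ++k) g[cv_dims[k] - 1] += bg[k];
    for (int k = 0; k < nd; ++k)
      x[k] += -g[k] * mob + (nsd > 0.0 ? nsd * norm_rand() : 0.0);
    apply_wrap(wr, x.data());
    if (stp % tau_steps == 0 && nh < n_hills_max) {
      for (int k = 0; k < ncv; ++k) s[k] = x[cv_dims[k] - 1];
      bool cl = false;
      double sc[2];
      for (int k = 0; k < ncv; ++k) {
        sc[k] = s[k];
        if (sc[k] < glo[k]) { sc[k] = glo[k]; cl = true; }
        if (sc[k] > ghi[k]) { sc[k] = ghi[k]; cl = true; }
      }
      if (cl) ++clamped;
      grid.interp(sc, Vh, bg);
      double h = omega * std::exp(-std::max(Vh, 0.0) / kb_deltaT);
      grid.add_hill(sc, REAL(sigma), h, 6.0);
      hills(nh, 0) = stp * dt;
      for (int k = 0; k < ncv; ++k) {
        hills(nh, 1 + k) = sc[k];
        hills(nh, 1 + ncv + k) = sigma[k];
      }
      hills(nh, 1 + 2 * ncv) = h;
      ++nh;
      if (nh > avg_from) {
        for (size_t q = 0; q < grid.V.size(); ++q) grid.Vsum[q] += grid.V[q];
        ++grid.navg;
      }
    }
    if (stp % 1000 == 0)
      check_domain(x.data(), nd, REAL(lower), REAL(upper), margin, stp * dt);
    if (stp % save_stride == 0 && fi < nf) {
      for (int k = 0; k < ncv; ++k) cvtraj(fi, k) = x[cv_dims[k] - 1];
      for (int k = 0; k < nd; ++k) coords(fi, k) = x[k];
      times[fi] = stp * dt;
      ++fi;
    }
  }
  NumericVector Vfin(grid.V.size()), Vavg(grid.V.size());
  for (size_t q = 0; q < grid.V.size(); ++q) {
    Vfin[q] = grid.V[q];
    Vavg[q] = grid.navg > 0 ? grid.Vsum[q] / grid.navg : grid.V[q];
  }
  return List::create(
      _["hills"] = hills(Range(0, std::max(nh - 1, 0)), _),
      _["n_hills"] = nh, _["times"] = times, _["cv_traj"] = cvtraj,
      _["coords"] = coords, _["bias_final"] = Vfin, _["bias_avg"] = Vavg,
      _["n_avg"] = (double)grid.navg, _["n_clamped"] = clamped);
}

// 1-D adaptive biasing force with direct force projection on a
// coordinate CV.  The instantaneous collective force -dU/dxi is
// accumulated per bin; the applied bias is minus the ramped running
// mean, which cancels the mean force once counts pass `ramp`.
// [[Rcpp::export]]
List cpp_abf(List terms, NumericVector x0, double dt, double friction,
             int n_steps, int save_stride, double kT, int cv_dim,
             double lo, double hi, int nbins, double ramp,
             NumericVector lower, NumericVector upper, double margin,
             List wrap) {
  std::vector<Term> ts = parse_terms(terms);
  Wrap wr = parse_wrap(wrap);
  int nd = x0.size();
  int cd = cv_dim - 1;
  double w = (hi - lo) / nbins;
  std::vector<double> sums(nbins, 0.0);
  std::vector<double> counts(nbins, 0.0);
  long n_out = 0;
  int nf = n_steps / save_stride + 1;
  NumericVector cvser(nf);
  NumericVector times(nf);
  std::vector<double> x(nd), g(nd);
  for (int k = 0; k < nd; ++k) x[k] = x0[k];
  cvser[0] = x[cd];
  times[0] = 0.0;
  int fi = 1;
  double mob = dt / friction;
  double nsd = std::sqrt(2.0 * kT * dt / friction);
  for (int stp = 1; stp <= n_steps; ++stp) {
    pot_eval(ts, x.data(), g.data(), nd);
    int b = (int)std::floor((x[cd] - lo) / w);
    if (b >= 0 && b < nbins) {
      double f_inst = -g[cd];
      sums[b] += f_inst;
      counts[b] += 1.0;
      double mean = sums[b] / counts[b];
      double scale = counts[b] < ramp ? counts[b] / ramp : 1.0;
      // applied bias force = -(mean collective force) * ramp
      g[cd] += mean * scale; // adds -(-mean*scale) to force
    } else {
      ++n_out;
    }
    for (int k = 0; k < nd; ++k)
      x[k] += -g[k] * mob + (nsd > 0.0 ? nsd * norm_rand() : 0.0);
    apply_wrap(wr, x.data());
    if (stp % 1000 == 0)
      check_domain(x.data(), nd, REAL(lower), REAL(upper), margin, stp * dt);
    if (stp % save_stride == 0 && fi < nf) {
      cvser[fi] = x[cd];
      times[fi] = stp * dt;
      ++fi;
    }
  }
  return List::create(_["force_sums"] = NumericVector(sums.begin(), sums.end()),
                      _["counts"] = NumericVector(counts.begin(), counts.end()),
                      _["cv_series"] = cvser, _["times"] = times,
                      _["n_out_of_range"] = (double)n_out);
}

// Evaluate a sum of Gaussian hills (and its well-tempered FES scale)
// on grid points; used to rebuild a FES from a HILLS file.
// [[Rcpp::export]]
NumericVector cpp_eval_hills(NumericMatrix centers, NumericMatrix sigmas,
                             NumericVector heights, NumericMatrix points) {
  int nh = centers.nrow(), np = points.nrow(), ncv = centers.ncol();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double v = 0.0;
    for (int h = 0; h < nh; ++h) {
      double ex = 0.0;
      for (int k = 0; k < ncv; ++k) {
        double d = points(p, k) - centers(h, k);
        ex += d * d / (2.0 * sigmas(h, k) * sigmas(h, k));
      }
      if (ex < 30.0) v += heights[h] * std::exp(-ex);
    }
    out[p] = v;
  }
  return out;
}
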