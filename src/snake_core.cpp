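// Fast evaluation of the planar friction-modulation equations of motion.
//
// The state vector is y = (x, y, vx, vy, alpha_bar, alpha_bar_t): centre of
// mass position/velocity plus mean orientation and its rate, all in
// nondimensional units (body lengths, undulation periods, radians).  The
// body shape is reconstructed from the prescribed lateral curvature wave at
// every evaluation; friction forces use the anisotropic Coulomb model with
// a lifting (weight-redistribution) wave and an optional heterogeneous
// friction-scale landscape.  This mirrors the reference R implementation in
// R/dynamics.R (acceleration()); the two are cross-checked in the tests.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Primitive {
  int type;        // 1 disk, 2 strip, 3 radial gradient, 4 raster
  double par[6];
  std::vector<double> vals;  // raster values, vals[ix + nx*iy]
  int nx, ny;
};

struct SimCore {
  // gait
  double eps, k, A, phi, lam;
  int lift;        // 0 none, 1 cosine, 2 exp(-kappa)
  // environment (friction ratios scaled by mu_f)
  double mu_t, mu_b, fr, delta;
  std::vector<Primitive> prims;
  // arclength grid (trapezoidal quadrature, weights sum to 1)
  int n;
  std::vector<double> s, w, ds;
  // work arrays
  std::vector<double> kap, kap_t, kap_tt, ca, sa, Ikap, Itx, Ity,
      alphat, vx, vy, Nh, t1, t2, Ia, Ib, Iktt, cum;
};

// running trapezoidal integral of f from s = 0, minus its quadrature mean
void mean_zero(const SimCore& sc, const std::vector<double>& f,
               std::vector<double>& out, std::vector<double>& cum) {
  const int n = sc.n;
  cum[0] = 0.0;
  for (int i = 1; i < n; ++i)
    cum[i] = cum[i - 1] + 0.5 * (f[i] + f[i - 1]) * sc.ds[i];
  double m = 0.0;
  for (int i = 0; i < n; ++i) m += sc.w[i] * cum[i];
  for (int i = 0; i < n; ++i) out[i] = cum[i] - m;
}

// local friction scale at a lab-frame point; later-listed primitive wins
double lookup_scale(const SimCore& sc, double px, double py) {
  double out = 1.0;
  for (size_t j = 0; j < sc.prims.size(); ++j) {
    const Primitive& p = sc.prims[j];
    switch (p.type) {
      case 1: {  // disk: cx, cy, diameter, scale
        double dx = px - p.par[0], dy = py - p.par[1], r = 0.5 * p.par[2];
        if (dx * dx + dy * dy <= r * r) out = p.par[3];
        break;
      }
      case 2: {  // strip: ax, ay, direction angle, width, scale
        double nx = -std::sin(p.par[2]), ny = std::cos(p.par[2]);
        double d = std::fabs((px - p.par[0]) * nx + (py - p.par[1]) * ny);
        if (d <= 0.5 * p.par[3]) out = p.par[4];
        break;
      }
      case 3: {  // radial gradient: cx, cy, diameter, centre scale (linear)
        double dx = px - p.par[0], dy = py - p.par[1], r = 0.5 * p.par[2];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d <= r) out = p.par[3] + (1.0 - p.par[3]) * (d / r);
        break;
      }
      case 4: {  // raster: ox, oy, hx, hy (origin = centre of cell [0,0])
        double ix = std::floor((px - p.par[0]) / p.par[2] + 0.5);
        double iy = std::floor((py - p.par[1]) / p.par[3] + 0.5);
        if (ix >= 0 && ix < p.nx && iy >= 0 && iy < p.ny)
          out = p.vals[(int)ix + p.nx * (int)iy];
        break;
      }
    }
  }
  return out;
}

void core_rhs(SimCore& sc, double t, const double* y, double* ydot) {
  const double TWOPI = 6.283185307179586476925286766559;
  const int n = sc.n;
  const double twopik = TWOPI * sc.k;

  for (int i = 0; i < n; ++i) {
    double ph = twopik * (sc.s[i] + t);
    double c = std::cos(ph), si = std::sin(ph);
    sc.kap[i] = sc.eps * c;
    sc.kap_t[i] = -twopik * sc.eps * si;
    sc.kap_tt[i] = -twopik * twopik * sc.kap[i];
  }
  mean_zero(sc, sc.kap, sc.Ikap, sc.cum);
  for (int i = 0; i < n; ++i) {
    double a = y[4] + sc.Ikap[i];
    sc.ca[i] = std::cos(a);
    sc.sa[i] = std::sin(a);
  }
  mean_zero(sc, sc.ca, sc.Itx, sc.cum);  // I[t], also x - xbar
  mean_zero(sc, sc.sa, sc.Ity, sc.cum);
  mean_zero(sc, sc.kap_t, sc.t1, sc.cum);
  for (int i = 0; i < n; ++i) sc.alphat[i] = y[5] + sc.t1[i];
  for (int i = 0; i < n; ++i) {
    sc.t1[i] = -sc.alphat[i] * sc.sa[i];  // alpha_t * n
    sc.t2[i] = sc.alphat[i] * sc.ca[i];
  }
  mean_zero(sc, sc.t1, sc.Ia, sc.cum);
  mean_zero(sc, sc.t2, sc.Ib, sc.cum);
  for (int i = 0; i < n; ++i) {
    sc.vx[i] = y[2] + sc.Ia[i];
    sc.vy[i] = y[3] + sc.Ib[i];
  }

  // lifting modulation and weight normalization
  double intN = 0.0;
  if (sc.lift == 0) {
    for (int i = 0; i < n; ++i) sc.Nh[i] = 1.0;
  } else if (sc.lift == 1) {
    double twopikl = TWOPI * sc.lam * sc.k;
    for (int i = 0; i < n; ++i) {
      double v = sc.A * std::cos(twopikl * (sc.s[i] + t + sc.phi)) + 1.0;
      sc.Nh[i] = v > 0.0 ? v : 0.0;
    }
  } else {
    for (int i = 0; i < n; ++i) sc.Nh[i] = std::exp(-sc.kap[i]);
  }
  for (int i = 0; i < n; ++i) intN += sc.w[i] * sc.Nh[i];
  if (!(intN > 1e-12))
    stop("degenerate lifting wave: weight integral is zero at t = %g", t);

  // friction force density, net force, torque, moment of inertia
  const bool hetero = !sc.prims.empty();
  const double d2 = sc.delta * sc.delta;
  double Fx = 0.0, Fy = 0.0, Tq = 0.0, J = 0.0;
  for (int i = 0; i < n; ++i) {
    double pscale = 1.0;
    if (hetero) pscale = lookup_scale(sc, y[0] + sc.Itx[i], y[1] + sc.Ity[i]);
    double sp = std::sqrt(sc.vx[i] * sc.vx[i] + sc.vy[i] * sc.vy[i] + d2);
    double ux = sc.vx[i] / sp, uy = sc.vy[i] / sp;
    double ut = ux * sc.ca[i] + uy * sc.sa[i];
    double un = -ux * sc.sa[i] + uy * sc.ca[i];
    // Heaviside split of tangential friction; H(0) = 1/2
    double coef = ut > 0.0 ? 1.0 : (ut < 0.0 ? sc.mu_b : 0.5 * (1.0 + sc.mu_b));
    double mux = sc.mu_t * un * (-sc.sa[i]) + coef * ut * sc.ca[i];
    double muy = sc.mu_t * un * (sc.ca[i]) + coef * ut * sc.sa[i];
    double fx = -(sc.Nh[i] / intN) * pscale * mux;
    double fy = -(sc.Nh[i] / intN) * pscale * muy;
    Fx += sc.w[i] * fx;
    Fy += sc.w[i] * fy;
    Tq += sc.w[i] * (sc.Itx[i] * fy - sc.Ity[i] * fx);
    J += sc.w[i] * (sc.Itx[i] * sc.Itx[i] + sc.Ity[i] * sc.Ity[i]);
  }

  // inertial correction: I[n].I[t alpha_t^2] - I[t].I[t I[kappa_tt]],
  // with I[n] = (-I[sin alpha], I[cos alpha])
  for (int i = 0; i < n; ++i) {
    double g = sc.alphat[i] * sc.alphat[i];
    sc.t1[i] = sc.ca[i] * g;
    sc.t2[i] = sc.sa[i] * g;
  }
  mean_zero(sc, sc.t1, sc.Ia, sc.cum);
  mean_zero(sc, sc.t2, sc.Ib, sc.cum);
  double corr = 0.0;
  for (int i = 0; i < n; ++i)
    corr += sc.w[i] * (-sc.Ity[i] * sc.Ia[i] + sc.Itx[i] * sc.Ib[i]);
  mean_zero(sc, sc.kap_tt, sc.Iktt, sc.cum);
  for (int i = 0; i < n; ++i) {
    sc.t1[i] = sc.ca[i] * sc.Iktt[i];
    sc.t2[i] = sc.sa[i] * sc.Iktt[i];
  }
  mean_zero(sc, sc.t1, sc.Ia, sc.cum);
  mean_zero(sc, sc.t2, sc.Ib, sc.cum);
  for (int i = 0; i < n; ++i)
    corr -= sc.w[i] * (sc.Itx[i] * sc.Ia[i] + sc.Ity[i] * sc.Ib[i]);

  ydot[0] = y[2];
  ydot[1] = y[3];
  ydot[2] = Fx / sc.fr;
  ydot[3] = Fy / sc.fr;
  ydot[4] = y[5];
  ydot[5] = Tq / (J * sc.fr) + corr / J;
}

}  // namespace

// [[Rcpp::export]]
SEXP sim_core_create(List gait, List env, NumericVector s, NumericVector w,
                     List prims) {
  SimCore* sc = new SimCore();
  sc->eps = as<double>(gait["epsilon"]);
  sc->k = as<double>(gait["k"]);
  sc->A = as<double>(gait["A"]);
  sc->phi = as<double>(gait["phi"]);
  sc->lam = as<double>(gait["lam"]);
  std::string lm = as<std::string>(gait["lifting_model"]);
  sc->lift = (lm == "none") ? 0 : (lm == "cosine" ? 1 : 2);
  sc->mu_t = as<double>(env["mu_t_ratio"]);
  sc->mu_b = as<double>(env["mu_b_ratio"]);
  sc->fr = as<double>(env["froude"]);
  sc->delta = as<double>(env["velocity_reg"]);

  sc->n = s.size();
  sc->s.assign(s.begin(), s.end());
  sc->w.assign(w.begin(), w.end());
  sc->ds.resize(sc->n);
  sc->ds[0] = 0.0;
  for (int i = 1; i < sc->n; ++i) sc->ds[i] = sc->s[i] - sc->s[i - 1];
  for (std::vector<double>* v :
       {&sc->kap, &sc->kap_t, &sc->kap_tt, &sc->ca, &sc->sa, &sc->Ikap,
        &sc->Itx, &sc->Ity, &sc->alphat, &sc->vx, &sc->vy, &sc->Nh, &sc->t1,
        &sc->t2, &sc->Ia, &sc->Ib, &sc->Iktt, &sc->cum})
    v->assign(sc->n, 0.0);

  for (int j = 0; j < prims.size(); ++j) {
    List pr = prims[j];
    Primitive p;
    p.type = as<int>(pr["type"]);
    NumericVector par = pr["par"];
    for (int q = 0; q < 6; ++q) p.par[q] = q < par.size() ? par[q] : 0.0;
    p.nx = p.ny = 0;
    if (p.type == 4) {
      NumericMatrix vals = pr["values"];
      p.nx = vals.nrow();
      p.ny = vals.ncol();
      p.vals.assign(vals.begin(), vals.end());
      p.par[4] = p.nx;
      p.par[5] = p.ny;
    }
    sc->prims.push_back(p);
  }

  XPtr<SimCore> ptr(sc, true);
  return ptr;
}

// [[Rcpp::export]]
NumericVector sim_core_rhs(SEXP ptr, double t, NumericVector y) {
  XPtr<SimCore> sc(ptr);
  NumericVector ydot(6);
  core_rhs(*sc, t, REAL(y), REAL(ydot));
  return ydot;
}

// [[Rcpp::export]]
NumericVector sim_core_scale(SEXP ptr, NumericMatrix pts) {
  XPtr<SimCore> sc(ptr);
  NumericVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i)
    out[i] = lookup_scale(*sc, pts(i, 0), pts(i, 1));
  return out;
}
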