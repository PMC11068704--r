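#include <Rcpp.h>
using namespace Rcpp;

// Hard-coded explicit-Euler integrators for the four neuron models.
// The per-step loop (up to ~10^7 steps) with optional per-step multiplicative
// parameter noise is inherently sequential, hence compiled.
//
// Parameter noise: each eligible parameter kappa is replaced at every step by
// kappa * (1 + xi), xi ~ Uniform(-xi_bar, xi_bar), freshly drawn per step via
// the R RNG (so set.seed() on the R side gives bit-reproducible trajectories).

static inline void check_state(const double *x, int nstate, double bound,
                               R_xlen_t step) {
  for (int j = 0; j < nstate; ++j) {
    if (!R_finite(x[j]) || fabs(x[j]) > bound)
      stop("state diverged (|x| > %g) at step %d", bound, (int)(step));
  }
}

// [[Rcpp::export(name = ".euler_morris_lecar")]]
NumericMatrix euler_morris_lecar(NumericVector x0, NumericVector i_app,
                                 double dt, List pars, double xi_bar,
                                 double bound) {
  const double C = pars["C"], gL = pars["g_L"], gK = pars["g_K"],
               gCa = pars["g_Ca"], EL = pars["E_L"], EK = pars["E_K"],
               ECa = pars["E_Ca"], V1 = pars["V1"], V2 = pars["V2"],
               V3 = pars["V3"], V4 = pars["V4"], phi = pars["phi"];
  const R_xlen_t n = i_app.size();
  NumericMatrix out(n, 2);
  double v = x0[0], w = x0[1];
  out(0, 0) = v; out(0, 1) = w;
  for (R_xlen_t m = 1; m < n; ++m) {
    double gLs = gL, gKs = gK;
    if (xi_bar > 0) {
      gLs *= 1.0 + R::runif(-xi_bar, xi_bar);
      gKs *= 1.0 + R::runif(-xi_bar, xi_bar);
    }
    const double minf = 0.5 * (1.0 + tanh((v - V1) / V2));
    const double winf = 0.5 * (1.0 + tanh((v - V3) / V4));
    const double lamw = phi * cosh((v - V3) / (2.0 * V4));
    const double dv = (i_app[m - 1] - gLs * (v - EL) - gKs * w * (v - EK) -
                       gCa * minf * (v - ECa)) / C;
    const double dw = lamw * (winf - w);
    v += dt * dv; w += dt * dw;
    out(m, 0) = v; out(m, 1) = w;
    double x[2] = {v, w};
    check_state(x, 2, bound, m);
  }
  return out;
}

// [[Rcpp::export(name = ".euler_fhn")]]
NumericMatrix euler_fhn(NumericVector x0, NumericVector i_app, double dt,
                        List pars, double xi_bar, double bound) {
  const double a = pars["a"], gamma = pars["gamma"], eps = pars["eps"];
  const R_xlen_t n = i_app.size();
  NumericMatrix out(n, 2);
  double v = x0[0], w = x0[1];
  out(0, 0) = v; out(0, 1) = w;
  for (R_xlen_t m = 1; m < n; ++m) {
    double as = a, gs = gamma;
    if (xi_bar > 0) {
      as *= 1.0 + R::runif(-xi_bar, xi_bar);
      gs *= 1.0 + R::runif(-xi_bar, xi_bar);
    }
    const double dv = v * (v - as) * (1.0 - v) - w + i_app[m - 1];
    const double dw = eps * (v - gs * w);
    v += dt * dv; w += dt * dw;
    out(m, 0) = v; out(m, 1) = w;
    double x[2] = {v, w};
    check_state(x, 2, bound, m);
  }
  return out;
}

// [[Rcpp::export(name = ".euler_fhn3d")]]
NumericMatrix euler_fhn3d(NumericVector x0, NumericVector i_app, double dt,
                          List pars, double xi_bar, double bound) {
  const double a = pars["a"], gamma = pars["gamma"], eps = pars["eps"],
               epsy = pars["eps_y"], c = pars["c"];
  const R_xlen_t n = i_app.size();
  NumericMatrix out(n, 3);
  double v = x0[0], w = x0[1], y = x0[2];
  out(0, 0) = v; out(0, 1) = w; out(0, 2) = y;
  for (R_xlen_t m = 1; m < n; ++m) {
    double as = a, gs = gamma;
    if (xi_bar > 0) {
      as *= 1.0 + R::runif(-xi_bar, xi_bar);
      gs *= 1.0 + R::runif(-xi_bar, xi_bar);
    }
    const double dv = v * (v - as) * (1.0 - v) - w + y + i_app[m - 1];
    const double dw = eps * (v - gs * w);
    const double dy = epsy * (c - v - y);
    v += dt * dv; w += dt * dw; y += dt * dy;
    out(m, 0) = v; out(m, 1) = w; out(m, 2) = y;
    double x[3] = {v, w, y};
    check_state(x, 3, bound, m);
  }
  return out;
}

static inline double safe_exprel(double u) {
  // u / (1 - exp(-u)), finite at u = 0
  if (fabs(u) < 1e-7) return 1.0 + u / 2.0;
  return u / (1.0 - exp(-u));
}

// [[Rcpp::export(name = ".euler_wang")]]
NumericMatrix euler_wang(NumericVector x0, NumericVector i_app, double dt,
                         List pars, double xi_bar, double bound) {
  const double C = pars["C"], gNa = pars["g_Na"], gK = pars["g_K"],
               gL = pars["g_L"], ENa = pars["E_Na"], EK = pars["E_K"],
               EL = pars["E_L"], phi = pars["phi"];
  const R_xlen_t n = i_app.size();
  NumericMatrix out(n, 3);
  double v = x0[0], h = x0[1], nn = x0[2];
  out(0, 0) = v; out(0, 1) = h; out(0, 2) = nn;
  for (R_xlen_t m = 1; m < n; ++m) {
    double gLs = gL, gKs = gK;
    if (xi_bar > 0) {
      gLs *= 1.0 + R::runif(-xi_bar, xi_bar);
      gKs *= 1.0 + R::runif(-xi_bar, xi_bar);
    }
    const double am = safe_exprel(0.1 * (v + 35.0));
    const double bm = 4.0 * exp(-(v + 60.0) / 18.0);
    const double minf = am / (am + bm);
    const double ah = 0.07 * exp(-(v + 58.0) / 20.0);
    const double bh = 1.0 / (1.0 + exp(-0.1 * (v + 28.0)));
    const double an = 0.1 * safe_exprel(0.1 * (v + 34.0));
    const double bn = 0.125 * exp(-(v + 44.0) / 80.0);
    const double m3 = minf * minf * minf;
    const double n4 = nn * nn * nn * nn;
    const double dv = (i_app[m - 1] - gNa * m3 * h * (v - ENa) -
                       gKs * n4 * (v - EK) - gLs * (v - EL)) / C;
    const double dh = phi * (ah * (1.0 - h) - bh * h);
    const double dn = phi * (an * (1.0 - nn) - bn * nn);
    v += dt * dv; h += dt * dh; nn += dt * dn;
    out(m, 0) = v; out(m, 1) = h; out(m, 2) = nn;
    double x[3] = {v, h, nn};
    check_state(x, 3, bound, m);
  }
  return out;
}
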