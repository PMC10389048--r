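#include <Rcpp.h>
#include <cmath>

// Scalar ODE for intracellular glucose in the fermentation glucose subsystem:
//   dGlci/dt = (Vin - Vhk) / cytoplasm
//   Vin  = cytoplasm * (Vm1 - KilG6P * G6P)
//   Vhk  = cytoplasm * Vm2 / (1 + Km2Glc/Glci + Km2ATP/ATP
//                               + Ks2Glc*Km2ATP/(Glci*ATP))
// G6P and ATP are held constant, so Vin is state-independent and Vhk is a
// saturating function of Glci alone. Integrated with an adaptive
// Dormand-Prince 5(4) pair; output instants are hit exactly by step
// truncation (no dense output needed for a scalar state).

namespace {

struct GlciModel {
  double vm1, kilg6p, vm2, km2glc, km2atp, ks2glc;
  double vol, g6p, atp;

  double vin() const { return vol * (vm1 - kilg6p * g6p); }

  double vhk(double glci) const {
    // Limit Glci -> 0+: the saturable terms send the denominator to
    // infinity, so the flux vanishes; used when the clamped state sits at 0.
    if (glci <= 0.0) {
      if (km2glc > 0.0 || (ks2glc > 0.0 && km2atp > 0.0)) return 0.0;
      double denom = 1.0;
      if (km2atp > 0.0) denom += km2atp / atp;
      return vol * vm2 / denom;
    }
    double denom = 1.0 + km2glc / glci;
    if (km2atp > 0.0 || ks2glc > 0.0) {
      denom += km2atp / atp + ks2glc * km2atp / (glci * atp);
    }
    return vol * vm2 / denom;
  }

  double dglci(double t, double glci) const {
    (void)t;
    return (vin() - vhk(glci)) / vol;
  }
};

}  // namespace

// [[Rcpp::export(name = ".glci_integrate")]]
Rcpp::NumericVector glci_integrate(Rcpp::NumericVector params,
                                   Rcpp::NumericVector env,
                                   Rcpp::NumericVector times,
                                   double rtol, double atol) {
  if (params.size() != 6) Rcpp::stop("expected 6 kinetic parameters");
  if (env.size() != 4) Rcpp::stop("expected 4 environment values");
  const int n = times.size();
  if (n < 2) Rcpp::stop("need at least two output times");

  GlciModel m;
  m.vm1 = params[0]; m.kilg6p = params[1]; m.vm2 = params[2];
  m.km2glc = params[3]; m.km2atp = params[4]; m.ks2glc = params[5];
  m.vol = env[0]; m.g6p = env[1]; m.atp = env[2];
  const double glci0 = env[3];

  for (int i = 0; i < 6; ++i)
    if (!std::isfinite(params[i])) Rcpp::stop("non-finite kinetic parameter");
  if (!(m.vol > 0.0)) Rcpp::stop("cytoplasm volume must be positive");
  if (m.atp <= 0.0 && (m.km2atp > 0.0 || m.ks2glc > 0.0))
    Rcpp::stop("singular rate: ATP = 0 with nonzero saturation coefficient");

  // Dormand-Prince 5(4) tableau.
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                      c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                      e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                      e6 = 187.0 / 2100, e7 = 1.0 / 40;

  Rcpp::NumericVector out(n);
  double t = times[0];
  double y = glci0;
  bool clamped = false;
  if (y < 0.0) { y = 0.0; clamped = true; }
  out[0] = y;

  const double tend = times[n - 1];
  double h = (tend - t) / 100.0;
  if (h <= 0.0) Rcpp::stop("times must be strictly increasing");

  int next = 1;
  long iter = 0;
  const long max_iter = 10000000L;

  while (next < n) {
    if (++iter > max_iter)
      Rcpp::stop("integration failure near t = %g (step budget exhausted)", t);
    double tout = times[next];
    if (tout <= t) Rcpp::stop("times must be strictly increasing");
    bool hit = false;
    double hs = h;
    if (t + hs >= tout) { hs = tout - t; hit = true; }
    if (hs < 1e-14 * std::max(1.0, std::fabs(t)))
      Rcpp::stop("integration failure near t = %g (step size collapsed)", t);

    const double k1 = m.dglci(t, y);
    const double k2 = m.dglci(t + c2 * hs, y + hs * a21 * k1);
    const double k3 = m.dglci(t + c3 * hs, y + hs * (a31 * k1 + a32 * k2));
    const double k4 =
        m.dglci(t + c4 * hs, y + hs * (a41 * k1 + a42 * k2 + a43 * k3));
    const double k5 = m.dglci(
        t + c5 * hs, y + hs * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4));
    const double k6 = m.dglci(
        t + hs,
        y + hs * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5));
    const double y5 =
        y + hs * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6);
    const double k7 = m.dglci(t + hs, y5);
    const double y4 = y + hs * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 +
                                e6 * k6 + e7 * k7);

    if (!std::isfinite(y5))
      Rcpp::stop("integration failure near t = %g (non-finite state)", t);

    const double sc =
        atol + rtol * std::max(std::fabs(y), std::fabs(y5));
    const double err = std::fabs(y5 - y4) / sc;

    if (err <= 1.0) {
      t += hs;
      y = y5;
      if (y < 0.0) { y = 0.0; clamped = true; }
      if (hit && std::fabs(t - tout) <= 1e-12 * std::max(1.0, std::fabs(tout))) {
        out[next] = y;
        ++next;
      }
    }
    double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 5.0;
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h = (err <= 1.0 ? hs : h) * fac;
  }

  out.attr("clamped") = clamped;
  return out;
}
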