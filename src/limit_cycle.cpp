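// Adaptive Dormand-Prince 5(4) integration of the forced tumor-immune ODE
//
//   dx/dt = a x (1 - b x) - beta x^2 / (eps + x^2) - c(t)
//
// with c(t) = h(t) (additive) or h(t) x (multiplicative).  The cycle is
// integrated sample-to-sample on a uniform grid so the waveform
// discontinuity at t = T0 never falls inside a solver step, and cycles are
// repeated until two consecutive cycles agree pointwise (periodicity) or
// max_cycles is exhausted.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

namespace {

struct Model {
  double a, b, beta, eps;
  int coupling;  // 0 = additive, 1 = multiplicative
};

struct Wave {
  int kind;  // 0 = none, 1 = rectangular, 2 = halfsine
  double h0, T, d;
};

inline double wave_value(const Wave &w, double t) {
  if (w.kind == 0 || w.h0 == 0.0) return 0.0;
  double tm = t - w.T * std::floor(t / w.T);  // t mod T, in [0, T)
  if (tm >= w.T) tm = 0.0;                    // guard rounding at the seam
  const double T0 = w.d * w.T;
  if (tm >= T0) return 0.0;
  if (w.kind == 1) return w.h0;
  return w.h0 * std::sin(M_PI * tm / T0);
}

inline double rhs(const Model &m, const Wave &w, double t, double x) {
  const double hv = wave_value(w, t);
  const double kill = (m.coupling == 0) ? hv : hv * x;
  return m.a * x * (1.0 - m.b * x) - m.beta * x * x / (m.eps + x * x) - kill;
}

// Dormand-Prince 5(4) tableau
const double c2 = 1.0 / 5.0, c3 = 3.0 / 10.0, c4 = 4.0 / 5.0, c5 = 8.0 / 9.0;
const double a21 = 1.0 / 5.0;
const double a31 = 3.0 / 40.0, a32 = 9.0 / 40.0;
const double a41 = 44.0 / 45.0, a42 = -56.0 / 15.0, a43 = 32.0 / 9.0;
const double a51 = 19372.0 / 6561.0, a52 = -25360.0 / 2187.0,
             a53 = 64448.0 / 6561.0, a54 = -212.0 / 729.0;
const double a61 = 9017.0 / 3168.0, a62 = -355.0 / 33.0,
             a63 = 46732.0 / 5247.0, a64 = 49.0 / 176.0,
             a65 = -5103.0 / 18656.0;
const double b1 = 35.0 / 384.0, b3 = 500.0 / 1113.0, b4 = 125.0 / 192.0,
             b5 = -2187.0 / 6784.0, b6 = 11.0 / 84.0;
// (5th order) - (embedded 4th order) weights, for the error estimate
const double e1 = 71.0 / 57600.0, e3 = -71.0 / 16695.0, e4 = 71.0 / 1920.0,
             e5 = -17253.0 / 339200.0, e6 = 22.0 / 525.0, e7 = -1.0 / 40.0;

// Integrate x from t0 to t1; hstep persists across calls. Returns false on
// a non-finite state.
bool integrate_span(const Model &m, const Wave &w, double t0, double t1,
                    double &x, double &hstep, double rtol, double atol) {
  double t = t0;
  const double span = t1 - t0;
  if (span <= 0) return true;
  const double hmin = span * 1e-14;
  if (hstep <= 0 || !std::isfinite(hstep)) hstep = span;
  int guard = 0;
  while (t < t1) {
    if (++guard > 1000000) return false;
    double h = std::min(hstep, t1 - t);
    const double k1 = rhs(m, w, t, x);
    const double k2 = rhs(m, w, t + c2 * h, x + h * a21 * k1);
    const double k3 = rhs(m, w, t + c3 * h, x + h * (a31 * k1 + a32 * k2));
    const double k4 =
        rhs(m, w, t + c4 * h, x + h * (a41 * k1 + a42 * k2 + a43 * k3));
    const double k5 = rhs(m, w, t + c5 * h,
                          x + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4));
    const double k6 =
        rhs(m, w, t + h,
            x + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5));
    const double x5 =
        x + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6);
    const double k7 = rhs(m, w, t + h, x5);
    const double err = h * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 +
                            e7 * k7);
    if (!std::isfinite(x5)) return false;
    const double sc = atol + rtol * std::max(std::fabs(x), std::fabs(x5));
    const double en = std::fabs(err) / sc;
    if (en <= 1.0) {
      t += h;
      x = x5;
      const double fac =
          (en == 0.0) ? 5.0 : std::min(5.0, std::max(0.2, 0.9 * std::pow(en, -0.2)));
      hstep = h * fac;
    } else {
      hstep = h * std::max(0.2, 0.9 * std::pow(en, -0.2));
      if (hstep < hmin) return false;
    }
  }
  return true;
}

}  // namespace

// [[Rcpp::export]]
List cpp_limit_cycle(double a, double b, double beta, double eps, int coupling,
                     int waveform, double h0, double T, double d, double x0,
                     double rtol, double atol, int n_samples, int max_cycles,
                     double periodicity_tol, int min_transient_cycles,
                     double x_floor) {
  Model mdl{a, b, beta, eps, coupling};
  Wave wv{waveform, h0, T, d};

  const int n = n_samples;
  NumericVector tt(n + 1), hh(n + 1);
  for (int i = 0; i <= n; ++i) {
    tt[i] = T * double(i) / double(n);
    hh[i] = wave_value(wv, (i == n) ? 0.0 : tt[i]);  // periodic wrap at t = T
  }
  const double T0 = d * T;

  std::vector<double> cur(n + 1), prev(n + 1);
  double x = x0, hstep = T / double(n);
  double min_x = x0, maxdiff = R_PosInf;
  bool converged = false, dead = (x0 <= x_floor);
  if (dead) x = 0.0;
  int cycle = 0;

  for (cycle = 0; cycle < max_cycles; ++cycle) {
    cur[0] = x;
    for (int i = 0; i < n; ++i) {
      double ta = tt[i], tb = tt[i + 1];
      if (!dead) {
        // split the interval at the waveform discontinuity if it is interior
        bool ok = true;
        if (ta < T0 && T0 < tb) {
          ok = integrate_span(mdl, wv, ta, T0, x, hstep, rtol, atol) &&
               integrate_span(mdl, wv, T0, tb, x, hstep, rtol, atol);
        } else {
          ok = integrate_span(mdl, wv, ta, tb, x, hstep, rtol, atol);
        }
        if (!ok) stop("integration failed (non-finite state or step underflow)");
        if (x <= x_floor) {  // eradication: clamp and hold at zero
          x = 0.0;
          dead = true;
        }
      }
      cur[i + 1] = x;
      if (x < min_x) min_x = x;
    }
    // periodicity test against the previous cycle
    if (cycle >= 1) {
      maxdiff = 0.0;
      for (int i = 0; i <= n; ++i)
        maxdiff = std::max(maxdiff, std::fabs(cur[i] - prev[i]));
      if (cycle >= min_transient_cycles && maxdiff < periodicity_tol) {
        converged = true;
        break;
      }
    }
    prev = cur;
  }

  NumericVector xx(n + 1);
  for (int i = 0; i <= n; ++i) xx[i] = cur[i];
  const int n_transient = converged ? cycle : max_cycles;

  return List::create(
      _["t"] = tt, _["x"] = xx, _["h"] = hh, _["converged"] = converged,
      _["n_transient_cycles"] = n_transient, _["min_x"] = min_x,
      _["periodicity_gap"] = maxdiff);
}
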