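#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Classical fixed-step RK4 integration of the underdamped bistable system
//   x' = v
//   v' = a*x - b*x^3 - beta*v + u
// with one step of size h per input sample and the drive u held constant
// across the four stages of a step (zero-order hold). `u` must already
// contain any additive noise term. Signals an R error when |x| exceeds
// `guard` (numeric blow-up), reporting the offending sample index (1-based).
// [[Rcpp::export]]
List rk4_bistable(NumericVector u, double a, double b, double beta,
                  double h, double x0, double v0, double guard) {
  const int n = u.size();
  NumericVector x(n), v(n);
  double xx = x0, vv = v0;
  for (int i = 0; i < n; ++i) {
    const double ui = u[i];
    const double k1x = vv;
    const double k1v = a * xx - b * xx * xx * xx - beta * vv + ui;
    double x2 = xx + 0.5 * h * k1x, v2 = vv + 0.5 * h * k1v;
    const double k2x = v2;
    const double k2v = a * x2 - b * x2 * x2 * x2 - beta * v2 + ui;
    double x3 = xx + 0.5 * h * k2x, v3 = vv + 0.5 * h * k2v;
    const double k3x = v3;
    const double k3v = a * x3 - b * x3 * x3 * x3 - beta * v3 + ui;
    double x4 = xx + h * k3x, v4 = vv + h * k3v;
    const double k4x = v4;
    const double k4v = a * x4 - b * x4 * x4 * x4 - beta * v4 + ui;
    xx += h / 6.0 * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
    vv += h / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
    if (!std::isfinite(xx) || std::fabs(xx) > guard)
      stop("bistable integration diverged at sample %d (|x| > %g)", i + 1, guard);
    x[i] = xx;
    v[i] = vv;
  }
  return List::create(_["x"] = x, _["v"] = v);
}
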