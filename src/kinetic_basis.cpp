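#include <Rcpp.h>
using namespace Rcpp;

// Causal convolution with a unit-mass exponential kernel rate*exp(-rate*t),
// evaluated by the exact O(n) recursion
//   y_i = a y_{i-1} + (1 - a)(x_i + x_{i-1})/2,  a = exp(-rate*dt),
// with y_1 = 0 (the integral over an empty interval). DC gain is exactly 1
// for any rate, so tracer mass is conserved.
// [[Rcpp::export(name = ".kexp_conv_cpp")]]
NumericVector kexp_conv_cpp(NumericVector x, double rate, double dt) {
  int n = x.size();
  NumericVector y(n);
  double a = std::exp(-rate * dt);
  double c = (1.0 - a) * 0.5;
  y[0] = 0.0;
  for (int i = 1; i < n; ++i) y[i] = a * y[i - 1] + c * (x[i] + x[i - 1]);
  return y;
}

// Shift a uniformly sampled curve to later times by delay_s seconds
// (linear interpolation between samples, zero-filled before the start).
// [[Rcpp::export(name = ".shift_later_cpp")]]
NumericVector shift_later_cpp(NumericVector x, double delay_s, double dt) {
  int n = x.size();
  NumericVector y(n);
  double off = delay_s / dt;
  for (int i = 0; i < n; ++i) {
    double pos = i - off;
    if (pos < 0.0) { y[i] = 0.0; continue; }
    int k = (int)std::floor(pos);
    double w = pos - k;
    if (k >= n - 1) { y[i] = x[n - 1]; continue; }
    y[i] = (1.0 - w) * x[k] + w * x[k + 1];
  }
  return y;
}

// Unit-flow compartment basis: the arterial curve shifted by the bolus
// delay, dispersed by the exponential vascular transport kernel
// (1/disp_s) exp(-t/disp_s), and convolved with the exponential residue
// function exp(-t/mtt) (integral mtt). Flow multiplies this curve.
// [[Rcpp::export(name = ".comp_basis_cpp")]]
NumericVector comp_basis_cpp(NumericVector aif, double dt, double mtt,
                             double delay_s, double disp_s) {
  NumericVector x = (delay_s > 0.0) ? shift_later_cpp(aif, delay_s, dt)
                                    : clone(aif);
  if (disp_s > 0.0) x = kexp_conv_cpp(x, 1.0 / disp_s, dt);
  NumericVector y = kexp_conv_cpp(x, 1.0 / mtt, dt);
  int n = y.size();
  for (int i = 0; i < n; ++i) y[i] *= mtt;
  return y;
}
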