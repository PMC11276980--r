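#include <Rcpp.h>
using namespace Rcpp;

// One biquad pass (direct form II transposed), state initialized to the
// steady state of the first sample so a constant signal passes unchanged.
static void biquad_forward(std::vector<double>& x, double b0, double b1,
                           double b2, double a1, double a2) {
  const double g = (b0 + b1 + b2) / (1.0 + a1 + a2);
  const double x0 = x[0], y0 = g * x0;
  double w2 = b2 * x0 - a2 * y0;
  double w1 = b1 * x0 - a1 * y0 + w2;
  const size_t n = x.size();
  for (size_t i = 0; i < n; ++i) {
    const double xn = x[i];
    const double yn = b0 * xn + w1;
    w1 = b1 * xn - a1 * yn + w2;
    w2 = b2 * xn - a2 * yn;
    x[i] = yn;
  }
}

// Zero-phase (forward-backward) cascade of second-order sections.
// sos: one row per section, columns b0 b1 b2 a1 a2 (a0 = 1).
// pad: odd-reflection padding length at each end to suppress edge
// transients, clamped to n - 1.
// [[Rcpp::export]]
NumericVector sos_filtfilt_cpp(NumericVector x, NumericMatrix sos, int pad) {
  const int n = x.size();
  if (pad > n - 1) pad = n - 1;
  if (pad < 0) pad = 0;
  std::vector<double> xp(n + 2 * pad);
  for (int i = 0; i < pad; ++i) xp[i] = 2.0 * x[0] - x[pad - i];
  for (int i = 0; i < n; ++i) xp[pad + i] = x[i];
  for (int i = 0; i < pad; ++i) xp[pad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];

  const int ns = sos.nrow();
  for (int s = 0; s < ns; ++s)
    biquad_forward(xp, sos(s, 0), sos(s, 1), sos(s, 2), sos(s, 3), sos(s, 4));
  std::reverse(xp.begin(), xp.end());
  for (int s = 0; s < ns; ++s)
    biquad_forward(xp, sos(s, 0), sos(s, 1), sos(s, 2), sos(s, 3), sos(s, 4));
  std::reverse(xp.begin(), xp.end());

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = xp[pad + i];
  return out;
}
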