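#include <Rcpp.h>
using namespace Rcpp;

// Leaky integrate-and-fire membrane with spike-triggered adaptation,
// integrated sample-exactly (exponential update per sample). The membrane
// relaxes toward rmp + (I - w) * R, where w is an adaptation current that
// jumps at each spike and decays with tau_w. When V crosses `theta` during
// the step, a spike is emitted: `n_wave` samples are reserved (NA, filled
// with the stereotyped waveform by the caller) and V resumes from
// `v_resume`. Above the depolarizing-block current the caller sets
// `blocked`: spike emission stops `block_t` seconds into the step and the
// trajectory is clamped at `v_plateau`.
// [[Rcpp::export]]
List iaf_integrate_cpp(int n, double dt, double rmp, double amp_pa,
                       double r_mohm, double tau_ms, double tau_w_ms,
                       double theta, int i_on, int i_off, double w_jump,
                       int n_wave, double v_resume, bool blocked,
                       double block_t, double v_plateau) {
  NumericVector v(n);
  std::vector<int> spikes;
  double V = rmp, w = 0.0;
  const double ad = std::exp(-dt * 1000.0 / tau_ms);
  const double aw = std::exp(-dt * 1000.0 / tau_w_ms);
  const bool may_spike = R_finite(theta);
  int i = 0;
  while (i < n) {
    const bool instep = (i >= i_on && i < i_off);
    const double I = instep ? amp_pa : 0.0;
    const double vinf = rmp + (I - w) * r_mohm * 1e-3;
    V = vinf + (V - vinf) * ad;
    w *= aw;
    bool can_spike = instep && may_spike;
    if (blocked && instep && (i - i_on) * dt >= block_t) {
      can_spike = false;
      if (V > v_plateau) V = v_plateau;
    }
    if (can_spike && V >= theta) {
      spikes.push_back(i);
      const int iend = std::min(n, i + n_wave);
      for (int j = i; j < iend; ++j) v[j] = NA_REAL;
      i = iend;
      V = v_resume;
      w = (w + w_jump) * std::pow(aw, (double)n_wave);
      continue;
    }
    v[i] = V;
    ++i;
  }
  return List::create(_["v"] = v, _["spike_idx"] = wrap(spikes));
}
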