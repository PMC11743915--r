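#include <Rcpp.h>
using namespace Rcpp;

// Per-tick trigger state machine over a whole trace.  Times in microseconds.
// Semantics (mirrors trigger_step() in R):
//   supra       := sample > threshold (strict, raw ADC counts)
//   in pulse    : supra refreshes last_supra; terminate when both
//                 t - start >= min_dur and t - last_supra >= increment.
//                 Termination is evaluated before new-onset logic, and a
//                 terminated tick never re-triggers within the same tick.
//   idle        : supra starts a pulse unless t - last_onset < refractory
//                 (silent suppression).
// EPS guards >= comparisons against accumulated floating-point error in
// t = t0 + i * dt (1e-6 us, i.e. 1 ps).
// [[Rcpp::export]]
List trigger_scan_cpp(NumericVector samples, double t0, double dt,
                      double threshold, double min_dur, double increment,
                      double refractory) {
  const double EPS = 1e-6;
  std::vector<double> rise, fall;
  bool in_pulse = false, has_onset = false;
  double last_onset = 0.0, last_supra = 0.0, start = 0.0;
  const R_xlen_t n = samples.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double t = t0 + (double)i * dt;
    const bool supra = samples[i] > threshold;
    if (in_pulse) {
      if (supra) last_supra = t;
      if (t - start >= min_dur - EPS && t - last_supra >= increment - EPS) {
        fall.push_back(t);
        in_pulse = false;
      }
    } else if (supra &&
               (!has_onset || t - last_onset >= refractory - EPS)) {
      rise.push_back(t);
      start = t;
      last_supra = t;
      last_onset = t;
      has_onset = true;
      in_pulse = true;
    }
  }
  return List::create(_["rise"] = rise, _["fall"] = fall,
                      _["open"] = in_pulse);
}
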