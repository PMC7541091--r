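#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sum of sinusoidal components with an optional per-component, time-varying
// log-amplitude (dB) gain surface
//   G(t, x_k) = depth_db * sin(2*pi*(tm_rate*t + sm_sign*sm_density*x_k) + phi)
// where x_k is the component's spectral coordinate in octaves above the band
// edge. With depth_db = 0 this reduces to a plain tone-complex sum, used for
// the notched-noise masker (10k components) where an FFT grid would not
// respect the exact log-uniform component frequencies.
// [[Rcpp::export]]
NumericVector component_sum(NumericVector freqs, NumericVector amps,
                            NumericVector phases, int n, double fs,
                            double depth_db, double tm_rate, double sm_sign,
                            double sm_density, NumericVector x_oct,
                            double mod_phase) {
  const int k = freqs.size();
  NumericVector out(n);
  const double two_pi = 2.0 * M_PI;
  const double c = depth_db * std::log(10.0) / 20.0;  // dB -> natural log gain
  const bool modulated = depth_db != 0.0;
  for (int j = 0; j < k; ++j) {
    const double w = two_pi * freqs[j] / fs;
    const double ph = phases[j];
    const double a = amps[j];
    if (!modulated) {
      for (int i = 0; i < n; ++i) out[i] += a * std::cos(w * i + ph);
    } else {
      const double b = two_pi * sm_sign * sm_density * x_oct[j] + mod_phase;
      const double wm = two_pi * tm_rate / fs;
      for (int i = 0; i < n; ++i) {
        const double g = std::exp(c * std::sin(wm * i + b));
        out[i] += a * g * std::cos(w * i + ph);
      }
    }
  }
  return out;
}
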