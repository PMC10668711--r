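#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Delay-and-sum beamforming of one analysis window.
//
// x:     samples-by-channels buffer (band-filtered), 0-based indexing
// dly:   grid-points-by-channels integer delay table (samples, >= 0)
// start: 0-based offset of the analysis window in *source time*: for grid
//        point g and channel m the summed samples are
//        x[start + t + dly(g, m), m], t = 0..win-1
// win:   window length (samples)
//
// Returns, per grid point, the maximum absolute amplitude of the
// channel-averaged aligned sum — the classic delay-and-sum map value.
// Delays are given in (fractional) samples. With subsample = false each
// delay is rounded to the nearest sample; with subsample = true channels
// are shifted with linear-interpolation fractional delays.
// [[Rcpp::export]]
NumericVector das_map_core(NumericMatrix x, NumericMatrix dly,
                           int start, int win, bool subsample = false) {
  const int G = dly.nrow(), M = dly.ncol(), n = x.nrow();
  if (M != x.ncol()) stop("delay table and buffer disagree on channel count");
  if (start < 0 || win <= 0) stop("invalid window");
  double max_d = 0.0;
  for (int i = 0; i < G * M; ++i) if (dly[i] > max_d) max_d = dly[i];
  if (start + win + (int)std::ceil(max_d) + 1 > n)
    stop("frame shorter than delay span plus analysis window");

  NumericVector out(G);
  std::vector<double> acc(win);
  for (int g = 0; g < G; ++g) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int m = 0; m < M; ++m) {
      const double* col = &x(0, m);
      const double d = dly(g, m);
      if (subsample) {
        const int d0 = (int)std::floor(d);
        const double f = d - d0;
        const int off = start + d0;
        for (int t = 0; t < win; ++t)
          acc[t] += (1.0 - f) * col[off + t] + f * col[off + t + 1];
      } else {
        const int off = start + (int)std::lround(d);
        for (int t = 0; t < win; ++t) acc[t] += col[off + t];
      }
    }
    double mx = 0.0;
    for (int t = 0; t < win; ++t) {
      const double a = std::fabs(acc[t]);
      if (a > mx) mx = a;
    }
    out[g] = mx / M;
  }
  return out;
}

// Frequency-domain delay-and-sum beam power.
//
// Xre, Xim: real/imag parts of the channel spectra at the selected in-band
//           bins (bins-by-channels); f0 the frequency (Hz) of the first
//           bin, df the bin spacing (Hz); dly the grid-by-channels delay
//           table in seconds (exact, not sample-rounded).
// For grid point g, channel spectra are phase-aligned with the steering
// factor e^{+2*pi*i*f*d} (time advance by the propagation delay) and
// summed; the map value is the RMS of the channel-averaged in-band beam
// spectrum. Phase factors across bins are generated by complex rotation.
// [[Rcpp::export]]
NumericVector das_power_core(NumericMatrix Xre, NumericMatrix Xim,
                             double f0, double df, NumericMatrix dly) {
  const int K = Xre.nrow(), M = Xre.ncol(), G = dly.nrow();
  if (Xim.nrow() != K || Xim.ncol() != M || dly.ncol() != M)
    stop("spectra and delay table disagree in shape");
  NumericVector out(G);
  std::vector<double> yre(K), yim(K);
  const double twopi = 2.0 * M_PI;
  for (int g = 0; g < G; ++g) {
    std::fill(yre.begin(), yre.end(), 0.0);
    std::fill(yim.begin(), yim.end(), 0.0);
    for (int m = 0; m < M; ++m) {
      const double d = dly(g, m);
      double c = std::cos(twopi * f0 * d), s = std::sin(twopi * f0 * d);
      const double cr = std::cos(twopi * df * d),
                   sr = std::sin(twopi * df * d);
      const double* xr = &Xre(0, m);
      const double* xi = &Xim(0, m);
      for (int k = 0; k < K; ++k) {
        yre[k] += xr[k] * c - xi[k] * s;
        yim[k] += xr[k] * s + xi[k] * c;
        const double cn = c * cr - s * sr;
        s = c * sr + s * cr;
        c = cn;
      }
    }
    double acc = 0.0;
    for (int k = 0; k < K; ++k) acc += yre[k] * yre[k] + yim[k] * yim[k];
    out[g] = std::sqrt(acc / K) / M;
  }
  return out;
}

// Frame RMS of a vector: root mean square over consecutive frames of
// `frame` samples with hop `hop` (both in samples). Used by the streaming
// energy gate.
// [[Rcpp::export]]
NumericVector frame_rms_core(NumericVector x, int frame, int hop) {
  if (frame <= 0 || hop <= 0) stop("invalid framing");
  const int n = x.size();
  const int nf = (n >= frame) ? (1 + (n - frame) / hop) : 0;
  NumericVector out(nf);
  for (int k = 0; k < nf; ++k) {
    const int s0 = k * hop;
    double acc = 0.0;
    for (int t = 0; t < frame; ++t) acc += x[s0 + t] * x[s0 + t];
    out[k] = std::sqrt(acc / frame);
  }
  return out;
}
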