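#' Band-pass filter a signal to the analysis band
#'
#' Zero-phase Butterworth band-pass (order 4, applied forward and backward),
#' the denoising step that restricts the camera to its tuned ultrasonic
#' band. Out-of-band tones a few kHz beyond the edges are attenuated by more
#' than 40 dB while the passband is preserved.
#'
#' @param x numeric vector or samples-by-channels matrix
#' @param band a [band_config()]
#' @param fs sample rate (Hz); must exceed `2 * band$f_hi`
#' @return filtered signal, same shape as `x`
#' @export
band_filter <- function(x, band = band_config(), fs = 192000) {
  if (!inherits(band, "fc_band")) stop("band must be a band_config()")
  if (fs <= 2 * band$f_hi)
    stop("fs must exceed twice the upper band edge")
  bf <- signal::butter(4, c(band$f_lo, band$f_hi) / (fs / 2), type = "pass")
  if (is.matrix(x)) {
    if (nrow(x) == 0) return(x)
    apply(x, 2, function(col) signal::filtfilt(bf, col))
  } else {
    if (!length(x)) return(x)
    signal::filtfilt(bf, x)
  }
}

# Raised-cosine on/off ramps over the first and last `frac` of a burst.
raised_cosine_ramp <- function(n, frac = 0.1) {
  w <- rep(1, n)
  nr <- max(1L, floor(n * frac))
  up <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
  w[seq_len(nr)] <- up
  w[n + 1 - seq_len(nr)] <- up
  w
}

# Deterministic band-limited noise burst for one simulated source.
# Reproducible given (cfg$seed, event id) regardless of which synthesis
# window requests it.
source_waveform <- function(event, cfg) {
  n <- max(8L, round(event$duration_s * cfg$fs))
  pad <- 512L
  ev_seed <- (cfg$seed + 7919 * event$id) %% 2147483647
  w <- with_seed(ev_seed, rnorm(n + 2L * pad))
  bf <- signal::butter(4, c(event$center_freq - event$bandwidth / 2,
                            event$center_freq + event$bandwidth / 2) /
                         (cfg$fs / 2), type = "pass")
  w <- signal::filtfilt(bf, w)[pad + seq_len(n)]
  w <- w * raised_cosine_ramp(n)
  r <- sqrt(mean(w^2))
  if (r > 0) w <- w * (event$amplitude / r)
  w
}
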