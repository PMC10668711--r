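#' Synthesise microphone-array signals for a scene window
#'
#' Free-field, direct-path rendering: each event's band-limited noise burst
#' reaches every microphone delayed by distance / c (fractional delays via
#' linear interpolation) and attenuated spherically (1/r), on top of white
#' background noise at the level implied by `cfg$snr_db`. Event waveforms
#' are reproducible per event id, so overlapping windows render identical
#' signals.
#'
#' @param events a [generate_sound_events()] result (or any data frame with
#'   its columns)
#' @param array a [mic_array()]
#' @param geometry a [pen_geometry()]
#' @param cfg a [sim_config()]
#' @param t0 window start (s, scene time)
#' @param duration_s window length (s)
#' @param noise add background noise (default `TRUE`)
#' @param noise_seed RNG seed for the noise (derived from `cfg$seed` and
#'   `t0` when `NULL`, so a given window always renders identically)
#' @return samples-by-channels matrix (`duration_s * cfg$fs` rows)
#' @export
synthesize_mic_signals <- function(events, array = mic_array(),
                                   geometry = pen_geometry(),
                                   cfg = sim_config(), t0 = 0,
                                   duration_s = NULL, noise = TRUE,
                                   noise_seed = NULL) {
  if (is.null(duration_s)) {
    duration_s <- if (nrow(events))
      max(events$t + events$duration_s) + 0.02 - t0 else 1
  }
  fs <- cfg$fs
  n <- round(duration_s * fs)
  M <- array$n_mics
  if (nrow(events)) {
    fmax <- max(events$center_freq + events$bandwidth / 2)
    if (fs <= 2 * fmax)
      stop(sprintf("aliasing: fs = %g must exceed twice the highest event frequency (%g Hz)",
                   fs, fmax))
  }
  if (noise && noise_rms(cfg) > 0) {
    if (is.null(noise_seed))
      noise_seed <- (cfg$seed + 5e6 + round(abs(t0) * 1000)) %% 2147483647
    x <- with_seed(noise_seed,
                   matrix(rnorm(n * M, sd = noise_rms(cfg)), n, M))
  } else {
    x <- matrix(0, n, M)
  }
  if (!nrow(events)) return(x)
  if (!"id" %in% names(events)) events$id <- seq_len(nrow(events))

  # events whose direct-path arrival can intersect the window (50 ms covers
  # the largest propagation delay across the pen)
  keep <- events$t + events$duration_s + 0.05 >= t0 &
    events$t <= t0 + duration_s
  ev <- events[keep, , drop = FALSE]
  for (k in seq_len(nrow(ev))) {
    e <- ev[k, ]
    w <- source_waveform(e, cfg)
    d <- sqrt((array$positions[, 1] - e$x_m)^2 +
                (array$positions[, 2] - e$y_m)^2 +
                array$positions[, 3]^2)
    for (m in seq_len(M)) {
      off <- (e$t + d[m] / cfg$c_sound - t0) * fs
      i0 <- floor(off); frac <- off - i0
      idx <- i0 + seq_along(w)             # 0-based start of each sample
      contrib <- w * (1 / d[m])            # spherical 1/r attenuation
      in1 <- idx >= 0 & idx < n
      if (any(in1))
        x[idx[in1] + 1L, m] <- x[idx[in1] + 1L, m] +
          (1 - frac) * contrib[in1]
      idx2 <- idx + 1L
      in2 <- idx2 >= 0 & idx2 < n
      if (any(in2))
        x[idx2[in2] + 1L, m] <- x[idx2[in2] + 1L, m] + frac * contrib[in2]
    }
  }
  x
}
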