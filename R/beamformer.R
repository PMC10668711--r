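#' Detector configuration for the spot pipeline
#'
#' @param frame_len_s analysis frame length (s)
#' @param hop_s frame hop (s), at most `frame_len_s`
#' @param threshold_db_above_floor a frame yields a spot only when the map
#'   maximum exceeds the per-frame noise floor (the map median) by this many
#'   dB — the "no clear source, no spot" denoising rule
#' @param lag_correction_s seconds added to recorded spot times to undo the
#'   acquisition lag of the recording chain
#' @param spatial_region rectangle `c(x0, x1, y0, y1)` (m) outside which
#'   sources are never displayed (the built-in spatial filter); defaults to
#'   the pen
#' @param grid_spacing_m acoustic-map grid spacing (m)
#' @param search_margin_m how far beyond `spatial_region` the localisation
#'   grid extends, so that out-of-region sources are localised (and then
#'   discarded) rather than leaking sidelobes into the region
#' @param win_s delay-and-sum analysis window inside each frame (s)
#' @param gate_db streaming energy gate: frames whose in-band reference
#'   energy is below this margin over the floor are skipped entirely
#' @return object of class `fc_detector`
#' @export
detector_config <- function(frame_len_s = 0.05, hop_s = frame_len_s,
                            threshold_db_above_floor = 6,
                            lag_correction_s = 1.5,
                            spatial_region = NULL,
                            grid_spacing_m = 0.05,
                            search_margin_m = 0.5,
                            win_s = 0.01, gate_db = 3) {
  if (frame_len_s <= 0) stop("frame_len_s must be > 0")
  if (hop_s <= 0 || hop_s > frame_len_s)
    stop("hop_s must be in (0, frame_len_s]")
  if (win_s > frame_len_s) stop("win_s must not exceed frame_len_s")
  structure(list(frame_len_s = frame_len_s, hop_s = hop_s,
                 threshold_db_above_floor = threshold_db_above_floor,
                 lag_correction_s = lag_correction_s,
                 spatial_region = spatial_region,
                 grid_spacing_m = grid_spacing_m,
                 search_margin_m = search_margin_m,
                 win_s = win_s, gate_db = gate_db),
            class = "fc_detector")
}

region_or_pen <- function(det, geometry) {
  if (!is.null(det$spatial_region)) det$spatial_region
  else rect_region(0, geometry$pen_length_m, 0, geometry$pen_width_m)
}

#' Build a pen-plane focus grid
#'
#' Regular grid of candidate source positions at floor height covering a
#' rectangle.
#'
#' @param region rectangle `c(x0, x1, y0, y1)` (m)
#' @param spacing_m grid spacing (m)
#' @return data frame with `x`, `y` plus attributes `nx`, `ny`, `spacing`
#' @export
focus_grid <- function(region, spacing_m = 0.05) {
  gx <- seq(region["x0"], region["x1"], by = spacing_m)
  gy <- seq(region["y0"], region["y1"], by = spacing_m)
  g <- expand.grid(x = gx, y = gy)
  attr(g, "nx") <- length(gx); attr(g, "ny") <- length(gy)
  attr(g, "spacing") <- spacing_m
  g
}

#' Propagation-delay table
#'
#' Delay from every grid point (floor height, z = 0) to every microphone:
#' exactly distance / c.
#'
#' @param array a [mic_array()]
#' @param grid a [focus_grid()] (or data frame with `x`, `y` in the same
#'   frame as the microphone positions)
#' @param c_sound speed of sound (m/s)
#' @return grid-points-by-microphones matrix of delays (s), with the grid as
#'   attribute `grid`
#' @export
compute_delays <- function(array, grid, c_sound = 343) {
  if (c_sound <= 0) stop("speed of sound must be positive")
  px <- array$positions[, 1]; py <- array$positions[, 2]
  pz <- array$positions[, 3]
  d <- outer(grid$x, px, function(gx, mx) (gx - mx)^2) +
    outer(grid$y, py, function(gy, my) (gy - my)^2)
  d <- sqrt(sweep(d, 2, pz^2, "+"))
  delays <- d / c_sound
  attr(delays, "grid") <- grid
  delays
}

#' Delay-and-sum beamform one frame onto an acoustic map
#'
#' For every grid point, each channel is shifted back by its propagation
#' delay (nearest sample), the channels are averaged, and the maximum
#' absolute amplitude of the aligned sum is the map value: in-phase
#' (positive) interference peaks at true source positions, destructive
#' interference suppresses empty ones.
#'
#' @param frame samples-by-channels matrix (band-filtered); must be at least
#'   as long as the delay span plus the analysis window
#' @param delays a [compute_delays()] table (seconds)
#' @param fs sample rate (Hz)
#' @param frame_time scene time of the start of the analysis window (s)
#' @param win_s analysis window (s); defaults to the usable length
#' @param start_s offset of the analysis window within the frame, in source
#'   time (s)
#' @param subsample shift channels with linear-interpolation fractional
#'   delays instead of nearest-sample shifts; nearest-sample rounding
#'   costs up to half a sample of alignment (enough to let a strong
#'   sidelobe out-vote the main lobe for far off-axis sources), so the
#'   detection pipelines enable this
#' @return object of class `fc_map`: list with `values` (grid-length
#'   vector), `grid`, `frame_time`, `grid_spacing_m`
#' @export
das_beamform <- function(frame, delays, fs, frame_time = 0, win_s = NULL,
                         start_s = 0, subsample = FALSE) {
  grid <- attr(delays, "grid")
  dly <- matrix(delays * fs, nrow(delays), ncol(delays))
  start <- as.integer(round(start_s * fs))
  max_d <- ceiling(max(dly)) + 1
  if (is.null(win_s)) {
    win <- nrow(frame) - max_d - start
    if (win <= 0) stop("frame shorter than delay span plus analysis window")
  } else {
    win <- as.integer(round(win_s * fs))
  }
  vals <- das_map_core(frame, dly, start, win, subsample)
  structure(list(values = vals, grid = grid, frame_time = frame_time,
                 grid_spacing_m = attr(grid, "spacing")),
            class = "fc_map")
}

#' Frequency-domain delay-and-sum map of one frame
#'
#' Equivalent steering to [das_beamform()] carried out on the in-band FFT
#' bins: each channel spectrum is phase-shifted by `exp(2i * pi * f * delay)`
#' (exact delays, no sample rounding), channels are averaged, and the map
#' value is the RMS of the in-band beam spectrum. Selecting bins inside the
#' analysis band makes a separate band-pass filter unnecessary, and the
#' per-frame cost is far lower than the time-domain sum, which is what makes
#' streaming analysis of long scenes practical. Peak positions agree with
#' the time-domain map; only the value scale differs (RMS vs peak
#' amplitude).
#'
#' @param frame samples-by-channels matrix (unfiltered is fine)
#' @param delays a [compute_delays()] table (seconds)
#' @param fs sample rate (Hz)
#' @param band a [band_config()]
#' @param frame_time scene time of the start of the analysis window (s)
#' @param n_fft analysis window / FFT length (samples)
#' @param start_s offset of the analysis window within the frame (source
#'   time, s)
#' @return an `fc_map`, as [das_beamform()]
#' @export
das_power_map <- function(frame, delays, fs, band = band_config(),
                          frame_time = 0, n_fft = 2048, start_s = 0) {
  grid <- attr(delays, "grid")
  start <- round(start_s * fs)
  max_d <- max(delays)
  need <- start + n_fft + ceiling(max_d * fs)
  if (need > nrow(frame))
    stop("frame shorter than delay span plus analysis window")
  # spectra over a window long enough to cover every steering delay
  n_win <- min(nrow(frame) - start, n_fft + ceiling(max_d * fs))
  X <- stats::mvfft(frame[start + seq_len(n_win), , drop = FALSE])
  f_bin <- (seq_len(n_win) - 1) * fs / n_win
  kk <- which(f_bin >= band$f_lo & f_bin <= band$f_hi)
  if (!length(kk)) stop("no FFT bins inside the analysis band")
  vals <- das_power_core(Re(X[kk, , drop = FALSE]), Im(X[kk, , drop = FALSE]),
                         f_bin[kk[1]], fs / n_win, unclass(delays)) / n_win
  structure(list(values = vals, grid = grid, frame_time = frame_time,
                 grid_spacing_m = attr(grid, "spacing")),
            class = "fc_map")
}

#' @export
print.fc_map <- function(x, ...) {
  cat(sprintf("Acoustic map at t = %.3f s: %d grid points, max %.3g at (%.2f, %.2f) m\n",
              x$frame_time, length(x$values), max(x$values),
              x$grid$x[which.max(x$values)], x$grid$y[which.max(x$values)]))
  invisible(x)
}

#' @export
plot.fc_map <- function(x, ...) {
  nx <- attr(x$grid, "nx"); ny <- attr(x$grid, "ny")
  z <- matrix(x$values, nx, ny)
  graphics::image(unique(x$grid$x), unique(x$grid$y), z,
                  xlab = "x (m)", ylab = "y (m)",
                  main = sprintf("Acoustic map, t = %.2f s", x$frame_time),
                  useRaster = TRUE, ...)
  invisible(x)
}

map_peak <- function(map) {
  i <- which.max(map$values)
  c(x = map$grid$x[i], y = map$grid$y[i], value = map$values[i])
}

#' Extract sound spots from a sequence of acoustic maps
#'
#' One spot at most per frame: the global map maximum, kept only when it
#' exceeds the per-frame noise floor (map median) by the configured margin
#' ("no clear source, no spot") and lies inside the spatial-filter region.
#' Spot times are the frame times plus the lag correction.
#'
#' @param maps list of [das_beamform()] maps, time-ordered
#' @param det a [detector_config()]
#' @param geometry a [pen_geometry()] (defines the default region)
#' @return a spot [event_log]
#' @export
detect_spots <- function(maps, det = detector_config(),
                         geometry = pen_geometry()) {
  if (length(maps) > 1) {
    tt <- vapply(maps, function(m) m$frame_time, numeric(1))
    if (is.unsorted(tt)) stop("maps must be time-ordered")
  }
  region <- region_or_pen(det, geometry)
  rows <- lapply(maps, function(m) {
    if (!length(m$values) || max(m$values) < 1e-12) return(NULL)
    floor_v <- stats::median(m$values)
    pk <- map_peak(m)
    if (floor_v > 0 &&
        pk["value"] < floor_v * 10^(det$threshold_db_above_floor / 20))
      return(NULL)
    if (!in_rect(pk["x"], pk["y"], region)) return(NULL)
    data.frame(time_s = m$frame_time + det$lag_correction_s,
               x_m = pk[["x"]], y_m = pk[["y"]], magnitude = pk[["value"]])
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(event_log())
  df <- do.call(rbind, rows)
  log <- event_log(time_s = df$time_s, duration_s = 0, stream = "spot",
                   label = "spot",
                   zone = zone_of(df$x_m, df$y_m, geometry),
                   x_m = df$x_m, y_m = df$y_m, audible = NA)
  log
}
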