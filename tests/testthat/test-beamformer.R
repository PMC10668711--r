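test_that("delay tables are exact distance over speed of sound", {
  arr <- structure(list(positions = rbind(c(0, 0, 0), c(3.43, 0, 0)),
                        n_mics = 2L), class = "fc_array")
  grid <- data.frame(x = c(0, 6.86), y = c(0, 0))
  attr(grid, "spacing") <- 1
  d <- compute_delays(arr, grid, c_sound = 343)
  expect_equal(d[1, 1], 0)            # mic at the grid point
  expect_equal(d[1, 2], 0.01)         # 3.43 m at 343 m/s -> 10 ms
  expect_equal(d[2, 2], d[1, 2])      # symmetric distances
  expect_equal(d[2, 1], 2 * d[1, 2])  # doubling distance doubles delay
  expect_error(compute_delays(arr, grid, c_sound = -1), "positive")
})

test_that("delay-and-sum localises a noiseless burst and matches the oracle", {
  cfg <- sim_config(seed = 6, snr_db = Inf)
  geom <- pen_geometry(); arr <- mic_array(geom)
  src <- c(1.00, 0.50)
  ev <- burst_event(t = 0.02, duration_s = 0.1, x = src[1], y = src[2])
  x <- synthesize_mic_signals(ev, arr, geom, cfg, t0 = 0, duration_s = 0.2,
                              noise = FALSE)
  xf <- band_filter(x, band_config(), cfg$fs)
  grid <- focus_grid(c(x0 = 0, x1 = geom$pen_length_m,
                       y0 = 0, y1 = geom$pen_width_m), 0.05)
  delays <- compute_delays(arr, grid)
  m <- das_beamform(xf, delays, cfg$fs, win_s = 0.01, start_s = 0.04)
  i <- which.max(m$values)
  expect_lt(abs(m$grid$x[i] - src[1]), 0.05 + 1e-9)
  expect_lt(abs(m$grid$y[i] - src[2]), 0.05 + 1e-9)
  # independent brute-force delay-sum on a dense 0.01 m grid near the source
  dense <- expand.grid(x = seq(src[1] - 0.07, src[1] + 0.07, by = 0.01),
                       y = seq(src[2] - 0.07, src[2] + 0.07, by = 0.01))
  ov <- oracle_das_values(xf, cfg$fs, arr$positions, dense$x, dense$y,
                          start = round(0.04 * cfg$fs), win = round(0.01 * cfg$fs))
  j <- which.max(ov)
  expect_lt(abs(dense$x[j] - src[1]), 0.02 + 1e-9)
  expect_lt(abs(dense$y[j] - src[2]), 0.02 + 1e-9)
  # implementation agrees with the oracle where both are evaluated
  dg <- compute_delays(arr, {
    g <- dense; attr(g, "spacing") <- 0.01; g
  })
  mi <- das_beamform(xf, dg, cfg$fs, win_s = 0.01, start_s = 0.04)
  expect_equal(mi$values, ov, tolerance = 1e-10)

  # all-zero frames give an all-zero map
  z <- das_beamform(matrix(0, 8000, 64), delays, cfg$fs, win_s = 0.01)
  expect_true(all(z$values == 0))
  # frames shorter than the delay span are rejected
  expect_error(das_beamform(xf[1:500, ], delays, cfg$fs, win_s = 0.01),
               "delay span")
})

test_that("beamformed amplitude at the focus is invariant to array size", {
  cfg <- sim_config(seed = 8, snr_db = Inf)
  geom <- pen_geometry()
  src <- c(1.40, 0.875)
  ev <- burst_event(t = 0.02, duration_s = 0.08, x = src[1], y = src[2])
  vals <- vapply(c(4, 8), function(n_side) {
    arr <- mic_array(geom, n_side = n_side, pitch_m = 0.04)
    x <- synthesize_mic_signals(ev, arr, geom, cfg, t0 = 0,
                                duration_s = 0.15, noise = FALSE)
    xf <- band_filter(x, band_config(), cfg$fs)
    g <- data.frame(x = src[1], y = src[2]); attr(g, "spacing") <- 0.05
    das_beamform(xf, compute_delays(arr, g), cfg$fs, win_s = 0.01,
                 start_s = 0.03)$values
  }, numeric(1))
  # 1/N normalisation: focus amplitude does not grow with the mic count
  expect_equal(vals[1], vals[2], tolerance = 0.05)
})

test_that("spot extraction applies the noise-floor and spatial-filter rules", {
  cfg <- sim_config(seed = 10, snr_db = Inf)
  geom <- pen_geometry(); arr <- mic_array(geom)
  det <- detector_config(lag_correction_s = 0)
  # silent recording: no spots
  silent <- beamform_audio(matrix(0, 30000, 64), cfg$fs, arr, geom,
                           det = det, record_lag_s = 0)
  expect_equal(nrow(silent$spots), 0)
  # a source outside the spatial-filter region is suppressed entirely
  ev_out <- burst_event(t = 0.05, duration_s = 0.15, x = -0.35, y = 0.9,
                        label = "neighbour")
  x <- synthesize_mic_signals(ev_out, arr, geom, cfg, t0 = 0,
                              duration_s = 0.3, noise = FALSE)
  res <- beamform_audio(x, cfg$fs, arr, geom, det = det, record_lag_s = 0)
  expect_equal(nrow(res$spots), 0)
  # the same source inside the region yields spots at its position
  ev_in <- burst_event(t = 0.05, duration_s = 0.15, x = 0.60, y = 0.90)
  xi <- synthesize_mic_signals(ev_in, arr, geom, cfg, t0 = 0,
                               duration_s = 0.3, noise = FALSE)
  resi <- beamform_audio(xi, cfg$fs, arr, geom, det = det, record_lag_s = 0)
  expect_gt(nrow(resi$spots), 0)
  expect_true(all(abs(resi$spots$x_m - 0.60) <= 0.05 &
                    abs(resi$spots$y_m - 0.90) <= 0.05))
  # detect_spots wants time-ordered maps
  maps <- beamform_audio(xi, cfg$fs, arr, geom, det = det, record_lag_s = 0,
                         keep_maps = TRUE)$maps
  expect_error(detect_spots(rev(maps), det, geom), "time-ordered")
})

test_that("delaying all channels shifts spot times by the same amount", {
  cfg <- sim_config(seed = 13, snr_db = Inf)
  geom <- pen_geometry(); arr <- mic_array(geom)
  det <- detector_config(lag_correction_s = 0)
  ev <- burst_event(t = 0.06, duration_s = 0.12, x = 1.2, y = 0.7)
  x <- synthesize_mic_signals(ev, arr, geom, cfg, t0 = 0, duration_s = 0.35,
                              noise = FALSE)
  shift <- round(0.10 * cfg$fs)
  x2 <- rbind(matrix(0, shift, ncol(x)), x)
  r1 <- beamform_audio(x, cfg$fs, arr, geom, det = det, record_lag_s = 0)
  r2 <- beamform_audio(x2, cfg$fs, arr, geom, det = det, record_lag_s = 0)
  t1 <- min(r1$spots$time_s); t2 <- min(r2$spots$time_s)
  expect_equal(t2 - t1, 0.10, tolerance = 0.051)  # within one frame hop
})
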