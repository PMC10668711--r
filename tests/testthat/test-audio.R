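test_that("propagation synthesis delays and attenuates per microphone", {
  cfg <- sim_config(seed = 3, snr_db = Inf)
  geom <- pen_geometry()
  # two microphones: one 0.343 m closer to the source than the other
  src <- c(1.0, 0.875)
  arr <- structure(list(positions = rbind(c(src[1], src[2], 1.000),
                                          c(src[1], src[2], 1.343)),
                        n_mics = 2L, pitch_m = NA, n_side = NA),
                   class = "fc_array")
  ev <- burst_event(t = 0.02, duration_s = 0.05, x = src[1], y = src[2])
  x <- synthesize_mic_signals(ev, arr, geom, cfg, t0 = 0, duration_s = 0.12,
                              noise = FALSE)
  cc <- stats::ccf(x[, 2], x[, 1], lag.max = 400, plot = FALSE)
  lag <- cc$lag[which.max(cc$acf)]
  expect_equal(lag / cfg$fs, 0.343 / 343, tolerance = 0.05)  # 1.0 ms lead
  # spherical attenuation: RMS ratio ~ r1/r2
  expect_equal(sqrt(mean(x[, 1]^2)) / sqrt(mean(x[, 2]^2)), 1.343 / 1.000,
               tolerance = 0.02)

  # equidistant microphones receive identical noiseless channels
  arr_eq <- structure(list(positions = rbind(c(src[1] - 0.2, src[2], 2),
                                             c(src[1] + 0.2, src[2], 2)),
                           n_mics = 2L, pitch_m = NA, n_side = NA),
                      class = "fc_array")
  xe <- synthesize_mic_signals(ev, arr_eq, geom, cfg, t0 = 0,
                               duration_s = 0.12, noise = FALSE)
  expect_equal(xe[, 1], xe[, 2], tolerance = 1e-8)
})

test_that("empty scenes and aliasing are handled", {
  cfg <- sim_config(seed = 1, snr_db = Inf)
  empty <- sim_config(seed = 1)
  x <- synthesize_mic_signals(burst_event()[0, ], mic_array(), pen_geometry(),
                              cfg, t0 = 0, duration_s = 0.05, noise = FALSE)
  expect_true(all(x == 0))
  ev_hi <- burst_event(cf = 100000)
  expect_error(synthesize_mic_signals(ev_hi, mic_array(), pen_geometry(), cfg,
                                      duration_s = 0.1),
               "aliasing")
  expect_error(sim_config(fs = 48000), "twice the highest")
})

test_that("band filter attenuates out-of-band tones and preserves the passband", {
  fs <- 192000
  t <- seq_len(fs / 10) / fs
  band <- band_config(39570, 41570)
  tone44 <- sin(2 * pi * 44000 * t)
  out <- band_filter(tone44, band, fs)
  expect_lt(sqrt(mean(out^2)) / sqrt(mean(tone44^2)), 0.01)
  centre <- sin(2 * pi * 40570 * t)
  outc <- band_filter(centre, band, fs)
  expect_equal(sqrt(mean(outc^2)) / sqrt(mean(centre^2)), 1, tolerance = 0.11)
  expect_equal(band_filter(numeric(0), band, fs), numeric(0))
  expect_true(all(band_filter(rep(0, 1000), band, fs) == 0))
  expect_error(band_filter(tone44, band, fs = 60000), "twice the upper")
})
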