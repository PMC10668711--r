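make_spot_log <- function(head_t = numeric(), rear_t = numeric()) {
  event_log(time_s = c(head_t, rear_t), duration_s = 0, stream = "spot",
            label = "spot",
            zone = c(rep("head", length(head_t)), rep("rump", length(rear_t))),
            x_m = c(rep(0.6, length(head_t)), rep(2.2, length(rear_t))),
            y_m = 0.9)
}

test_that("onset needs prior rooting activity and a rear confirmation", {
  cfg <- onset_config()
  # no head-zone activity at any time: cessation precondition unmet
  r0 <- detect_onset(make_spot_log(rear_t = seq(3000, 4000, by = 30)), cfg)
  expect_true(is.na(r0$t_onset_est))
  # rooting continues throughout: no onset
  busy <- make_spot_log(head_t = seq(0, 7200, by = 15))
  expect_true(is.na(detect_onset(busy, cfg)$t_onset_est))
  # rooting that ceases, followed by rear clusters: onset near the cessation
  head_t <- seq(0, 3600, by = 15)
  rear_t <- rep(seq(3900, 5400, by = 300), each = 6) + seq(0, 50, by = 10)
  r <- detect_onset(make_spot_log(head_t, rear_t), cfg)
  expect_false(is.na(r$t_onset_est))
  expect_lt(abs(r$t_onset_est - 3600), cfg$window_s)
  # cessation without any rear-zone clusters stays unconfirmed
  r2 <- detect_onset(make_spot_log(head_t), cfg)
  expect_true(is.na(r2$t_onset_est))
})

test_that("raising the rear-cluster requirement never makes onset earlier", {
  head_t <- seq(0, 3600, by = 15)
  rear_t <- c(rep(seq(3700, 4200, by = 100), each = 3) + c(0, 10, 20),
              rep(seq(4800, 6000, by = 150), each = 6) + seq(0, 50, 10))
  log <- make_spot_log(head_t, sort(rear_t))
  prev <- -Inf
  for (k in c(3, 5, 6)) {
    r <- detect_onset(log, onset_config(rear_cluster_min = k))
    if (is.na(r$t_onset_est)) break
    expect_gte(r$t_onset_est, prev - 1e-9)
    prev <- r$t_onset_est
  }
})

test_that("progress tracking flags stalls and the end of farrowing", {
  cfg <- onset_config(rear_cluster_min = 3)  # sparse-but-steady rear spots
  head_t <- seq(0, 3600, by = 15)
  # rear spots every 60 s for two hours: one progress interval, no stalls
  rear_t <- seq(3660, 3660 + 7200, by = 60)
  log <- make_spot_log(head_t, rear_t)
  r <- detect_onset(log, cfg)
  expect_false(is.na(r$t_onset_est))
  r <- monitor_progress(log, r, cfg)
  expect_equal(nrow(r$progress_intervals), 1)
  expect_false(any(r$alerts$kind == "stalled"))
  expect_equal(r$t_end_est, max(rear_t) + cfg$progress_timeout_s)
  # a 45-minute gap with a 30-minute timeout raises one stall alert
  rear_gap <- c(seq(3660, 5400, by = 60), seq(5400 + 2700, 9000, by = 60))
  log2 <- make_spot_log(head_t, rear_gap)
  r2 <- monitor_progress(log2, detect_onset(log2, cfg), cfg)
  expect_equal(sum(r2$alerts$kind == "stalled"), 1)
  expect_equal(nrow(r2$progress_intervals), 2)
  # calling the tracker before onset is an error
  r_none <- detect_onset(make_spot_log(head_t), cfg)
  expect_error(monitor_progress(log, r_none, cfg), "requires a detected onset")
})

test_that("onset and end are recovered on simulated study scenes", {
  for (s in c(21, 22)) {
    cfg <- sim_config(seed = s)
    tl <- generate_timeline(cfg)
    script <- generate_behaviour(tl, cfg)
    ev <- generate_sound_events(tl, script, cfg)
    spots <- events_to_spots(ev, cfg)
    r <- detect_onset(spots)
    expect_false(is.na(r$t_onset_est))
    expect_lt(abs(r$t_onset_est - tl$t_onset), 900)
    r <- monitor_progress(spots, r)
    expect_lt(abs(r$t_end_est - tl$t_end_farrowing), 1800)
    expect_true(r$t_onset_est <= r$t_end_est)
    expect_false(is.unsorted(r$alerts$t))
  }
})
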