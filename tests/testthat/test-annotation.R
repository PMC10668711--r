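test_that("location correspondence follows the packaged tables", {
  t1 <- correspondence_table("study1_sound")
  expect_true(is_location_correct("trough", "trough", t1))
  expect_true(is_location_correct("outside_pen", "neighbour_sow", t1))
  expect_true(is_location_correct("head", "sow_in_crate", t1))
  expect_true(is_location_correct("cloud", "neighbour_sow", t1))
  expect_false(is_location_correct("trough", "metal_fence", t1))
  expect_error(is_location_correct("trough", "jackhammer", t1),
               "unknown reference label")
  expect_error(is_location_correct("attic", "trough", t1), "unknown zone")
  # behaviour table: simulator state names map onto ethogram labels
  tb <- correspondence_table("study2_behaviour")
  expect_true(is_location_correct("head", "jute_rooting", tb))
  expect_true(is_location_correct("rump", "sitting_standing", tb))
  expect_true(is_location_correct("none", "lying", tb))
  expect_false(is_location_correct("rump", "jute_rooting", tb))
})

test_that("time budgets are additive, normalised, and validated", {
  tl <- structure(list(t_start = 0, t_onset = 14400, birth_times = numeric(),
                       t_end_farrowing = 14400, t_stop = 14400),
                  class = "fc_timeline")
  # single 4 h lying interval -> 100% lying
  one <- event_log(0, 14400, "behaviour", "lying")
  b <- time_budget(one, tl)
  expect_equal(b$proportion[b$state == "lying"], 1)
  # constructed 71.7 / 3.3 / 25 split reproduces its proportions exactly
  mix <- event_log(c(0, 10324.8, 10800), c(10324.8, 475.2, 3600),
                   "behaviour", c("lying", "sitting_standing", "jute_rooting"))
  bm <- time_budget(mix, tl)
  expect_equal(bm$proportion[bm$state == "lying"], 0.717, tolerance = 1e-9)
  expect_equal(bm$proportion[bm$state == "sitting_standing"], 0.033,
               tolerance = 1e-9)
  expect_equal(bm$proportion[bm$state == "jute_rooting"], 0.25,
               tolerance = 1e-9)
  expect_equal(sum(bm$proportion), 1)
  # splitting an interval leaves budgets unchanged
  split <- event_log(c(0, 5000, 10324.8, 10800),
                     c(5000, 5324.8, 475.2, 3600), "behaviour",
                     c("lying", "lying", "sitting_standing", "jute_rooting"))
  expect_equal(time_budget(split, tl), bm)
  # gaps are rejected
  gap <- event_log(c(0, 7300), c(7200, 7100), "behaviour", "lying")
  expect_error(time_budget(gap, tl), "tile")
})

test_that("spot clouds are identified from clustering", {
  cloud_t <- 10 + seq(0, 0.8, length.out = 6)
  log <- event_log(time_s = c(cloud_t, 20), duration_s = 0, stream = "spot",
                   zone = "head", x_m = c(rep(0.6, 6), 0.6),
                   y_m = c(rep(0.8, 6), 0.8))
  out <- annotate_clouds(log)
  expect_equal(sum(out$zone == "cloud"), 6)   # the lone spot stays "head"
  expect_equal(out$zone[out$time_s == 20], "head")
})
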