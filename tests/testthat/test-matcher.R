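sound_cfg <- function(...) match_config(reference_mode = "sound", ...)

test_that("pairing follows the tolerance-window rules", {
  # spot at the head 0.4 s from a sow sound: correct positive
  m <- match_events(event_log(1.0, 0, "spot", "spot", "head", 0.5, 0.8),
                    event_log(1.4, 0, "audible", "sow_in_crate"),
                    cfg = sound_cfg(), t_range = c(0, 3))
  expect_equal(c(m$counts$CP, m$counts$FP, m$counts$FN), c(1, 0, 0))
  # 1.5 s apart exceeds the +/-1 s tolerance: one FP and one FN
  m2 <- match_events(event_log(5.0, 0, "spot", "spot", "trough", 0.25, 0.9),
                     event_log(6.5, 0, "audible", "trough"),
                     cfg = sound_cfg(), t_range = c(4, 8))
  expect_equal(c(m2$counts$CP, m2$counts$FP, m2$counts$FN), c(0, 1, 1))
  # silent 10 s timeline: five 2 s correct negatives
  m3 <- match_events(event_log(),
                     event_log(numeric(0), stream = "audible"),
                     cfg = sound_cfg(), t_range = c(0, 10))
  expect_equal(m3$counts$CN, 5)
  # paired at the right time but in the wrong zone: FN under the default
  # policy, CP under the lenient one; FP and CN unchanged
  mw <- match_events(event_log(2.0, 0, "spot", "spot", "trough", 0.25, 0.9),
                     event_log(2.2, 0, "audible", "metal_fence"),
                     cfg = sound_cfg(), t_range = c(0, 10))
  expect_equal(c(mw$counts$CP, mw$counts$FN), c(0, 1))
  expect_equal(mw$n_wrong_location, 1)
  lenient <- apply_location_policy(mw, "wrong_as_CP")
  expect_equal(c(lenient$CP, lenient$FN), c(1, 0))
  expect_equal(lenient$FP, mw$counts$FP)
  expect_equal(lenient$CN, mw$counts$CN)
  # unsorted input is rejected
  bad <- as.data.frame(event_log(c(1, 5), 0, "spot", "spot", "head", 1, 1))
  bad <- bad[2:1, ]
  expect_error(match_events(bad, event_log(numeric(0), stream = "audible"),
                            cfg = sound_cfg(), t_range = c(0, 6)),
               "time-sorted")
})

test_that("policy switch on the field counts reproduces the published columns", {
  fc <- field_counts()
  sw <- apply_location_policy(fc$wrong_as_FN, "wrong_as_CP",
                              n_wrong_location = 1747)
  expect_equal(c(sw$FP, sw$FN, sw$CP, sw$CN), c(10751, 76, 3256, 1582))
  # identity switch and zero-wrong-pair invariance
  id <- apply_location_policy(fc$wrong_as_FN, "wrong_as_FN",
                              n_wrong_location = 1747)
  expect_equal(unlist(id[1:4]), unlist(fc$wrong_as_FN[1:4]))
  nz <- apply_location_policy(fc$wrong_as_FN, "wrong_as_CP",
                              n_wrong_location = 0)
  expect_equal(unlist(nz[1:4]), unlist(fc$wrong_as_FN[1:4]))
})

test_that("correct negatives accumulate per silent stretch", {
  # two silent recordings joined by a boundary event
  spots <- event_log(300, 0, "spot", "spot", "head", 0.5, 0.8)
  refs <- event_log(numeric(0), stream = "audible")
  m <- match_events(spots, refs, cfg = sound_cfg(), t_range = c(0, 500))
  expect_equal(m$counts$CN, floor(300 / 2) + floor(200 / 2))
  # per-stretch mode counts each qualifying stretch once
  m2 <- match_events(spots, refs, cfg = sound_cfg(cn_mode = "per_stretch"),
                     t_range = c(0, 500))
  expect_equal(m2$counts$CN, 2)
})

test_that("counts are invariant to shifting every stream in time", {
  set.seed(42)
  spots <- event_log(sort(runif(20, 0, 100)), 0, "spot", "spot",
                     sample(c("head", "trough", "rump"), 20, TRUE), 1, 1)
  refs <- event_log(sort(runif(15, 0, 100)), 0.2, "audible",
                    sample(c("sow_in_crate", "trough"), 15, TRUE))
  a <- match_events(spots, refs, cfg = sound_cfg(), t_range = c(0, 100))
  spots2 <- spots; spots2$time_s <- spots2$time_s + 55.5
  refs2 <- refs; refs2$time_s <- refs2$time_s + 55.5
  b <- match_events(spots2, refs2, cfg = sound_cfg(),
                    t_range = c(55.5, 155.5))
  expect_equal(unlist(a$counts[1:4]), unlist(b$counts[1:4]))
})

test_that("greedy-plus-augmentation pairing equals brute-force maximum matching", {
  # includes the classic greedy trap: spots {0, 1}, refs {1.0, 1.1}
  trap <- farrowcam:::pair_streams(c(0, 1), c(1.0, 1.1), c(1.0, 1.1), 1)
  expect_equal(sum(!is.na(trap)), 2)
  set.seed(7)
  for (rep in 1:200) {
    ns <- sample(0:6, 1); nr <- sample(0:6, 1)
    st <- sort(runif(ns, 0, 10))
    rt <- sort(runif(nr, 0, 10))
    got <- sum(!is.na(farrowcam:::pair_streams(st, rt, rt, 1)))
    want <- oracle_max_matching(st, rt, rt, 1)
    expect_equal(got, want)
  }
})

test_that("clouds collapse to their first spot before matching", {
  cloud_t <- 5 + seq(0, 0.5, length.out = 6)
  spots <- event_log(c(cloud_t, 20), 0, "spot", "spot", "head",
                     c(rep(0.6, 6), 0.7), c(rep(0.8, 6), 0.8))
  refs <- event_log(c(5.2, 20.3), 0, "audible", "sow_in_crate")
  m <- match_events(spots, refs, cfg = sound_cfg(), t_range = c(0, 25))
  # 6-spot cloud becomes one spot: 2 CP, no FP from the cloud residue
  expect_equal(m$counts$CP, 2)
  expect_equal(m$counts$FP, 0)
  m_raw <- match_events(spots, refs, cfg = sound_cfg(collapse_clouds = FALSE),
                        t_range = c(0, 25))
  expect_equal(m_raw$counts$FP, 5)   # 6-spot cloud leaves 5 unpaired spots
})

test_that("behaviour and combined reference modes validate spots", {
  beh <- event_log(c(0, 100), c(100, 100), "behaviour",
                   c("jute_rooting", "lying"))
  spots <- event_log(c(50, 150), 0, "spot", "spot", c("head", "head"),
                     0.6, 0.8)
  mb <- match_events(spots, behaviour = beh,
                     cfg = match_config(reference_mode = "behaviour"),
                     t_range = c(0, 200))
  # head spot during rooting is correct; head spot while lying is not
  expect_equal(mb$counts$CP, 1)
  expect_equal(mb$counts$FP, 1)
  # combined mode: an inaudible behaviour validates what sound cannot
  aud <- event_log(numeric(0), stream = "audible")
  mc <- match_events(spots, aud, beh,
                     cfg = match_config(reference_mode = "sound_or_behaviour"),
                     t_range = c(0, 200))
  expect_equal(mc$counts$CP, 1)
})
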