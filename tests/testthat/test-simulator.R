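test_that("timelines are ordered, reproducible, and handle degenerate litters", {
  cfg <- sim_config(seed = 7, litter_size = 12)
  tl <- generate_timeline(cfg)
  expect_length(tl$birth_times, 12)
  expect_true(all(diff(tl$birth_times) > 0))
  expect_true(tl$t_onset <= tl$birth_times[1])
  expect_true(tl$birth_times[12] <= tl$t_end_farrowing)
  expect_true(tl$t_end_farrowing <= tl$t_stop)
  expect_identical(tl, generate_timeline(cfg))

  empty <- generate_timeline(sim_config(seed = 1, litter_size = 0,
                                        pre_farrowing_s = 600))
  expect_length(empty$birth_times, 0)
  expect_equal(empty$t_onset, empty$t_end_farrowing)

  expect_error(sim_config(litter_size = -1), "non-negative")
  expect_error(sim_config(pre_farrowing_s = -5), "non-negative")
})

test_that("behaviour scripts tile the timeline and respect phase structure", {
  cfg <- sim_config(seed = 2)
  tl <- generate_timeline(cfg)
  script <- generate_behaviour(tl, cfg)
  expect_equal(script$start_s[1], tl$t_start)
  expect_equal(script$end_s[nrow(script)], tl$t_stop)
  expect_true(all(abs(script$start_s[-1] -
                        script$end_s[-nrow(script)]) < 1e-9))
  # after farrowing the sow only lies
  after <- script[script$start_s >= tl$t_end_farrowing - 1e-9, ]
  expect_true(all(after$state == "lying"))
  # rooting occurs before onset except the configured residual
  rooting <- script[script$state == "jute_rooting", ]
  during <- pmin(rooting$end_s, tl$t_end_farrowing) -
    pmax(rooting$start_s, tl$t_onset)
  expect_lt(sum(pmax(during, 0)) / (tl$t_end_farrowing - tl$t_onset), 0.02)
  # zero-length timeline -> empty script
  tl0 <- generate_timeline(sim_config(seed = 1, litter_size = 0,
                                      pre_farrowing_s = 0,
                                      post_farrowing_s = 0))
  expect_equal(nrow(generate_behaviour(tl0, cfg)), 0)
  bad <- default_budgets(); bad[1, 1] <- 0.9
  expect_error(sim_config(behaviour_budgets = bad), "sum to 1")
})

test_that("pre-farrowing budgets converge to their targets (4 h and 40 h)", {
  cfg4 <- sim_config(seed = 1)       # 4 h pre-farrowing phase
  tl4 <- generate_timeline(cfg4)
  b4 <- time_budget(generate_behaviour(tl4, cfg4), tl4)
  root4 <- b4$proportion[b4$phase == "before" & b4$state == "jute_rooting"]
  expect_lt(abs(root4 - 0.25), 0.05)

  cfg40 <- sim_config(seed = 5, pre_farrowing_s = 144000, litter_size = 0,
                      post_farrowing_s = 0)   # 10x the default duration
  tl40 <- generate_timeline(cfg40)
  b40 <- time_budget(generate_behaviour(tl40, cfg40), tl40)
  before <- b40[b40$phase == "before", ]
  target <- default_budgets()["before", ]
  for (s in names(target)) {
    got <- before$proportion[before$state == s]
    if (!length(got)) got <- 0
    expect_lt(abs(got - target[[s]]), 0.02)
  }
})

test_that("sound events respect their behavioural and spatial structure", {
  cfg <- sim_config(seed = 9, profile = "demo")
  geom <- pen_geometry()
  tl <- generate_timeline(cfg)
  script <- generate_behaviour(tl, cfg)
  ev <- generate_sound_events(tl, script, cfg, geom)
  expect_identical(as.data.frame(ev),
                   as.data.frame(generate_sound_events(tl, script, cfg, geom)))

  births <- ev[ev$label == "piglet_birth", ]
  expect_equal(births$t, tl$birth_times)
  expect_true(all(!births$audible))
  moves <- ev[ev$label == "piglet_move", ]
  expect_true(all(moves$t >= tl$birth_times[1]))
  rear <- rbind(births, moves)
  expect_true(all(zone_of(rear$x_m, rear$y_m, geom) == "rump"))
  rooting <- ev[ev$label == "jute_rooting", ]
  expect_true(all(zone_of(rooting$x_m, rooting$y_m, geom) == "head"))
  # rooting sounds only inside rooting bouts
  iv <- script[script$state == "jute_rooting", ]
  inside <- vapply(rooting$t, function(t)
    any(t >= iv$start_s & t <= iv$end_s), logical(1))
  expect_true(all(inside))
  nb <- ev[ev$label == "neighbour", ]
  expect_true(all(zone_of(nb$x_m, nb$y_m, geom) == "outside_pen"))
  others <- ev[!ev$label %in% "neighbour", ]
  expect_true(all(others$x_m >= 0 & others$x_m <= geom$pen_length_m &
                    others$y_m >= 0 & others$y_m <= geom$pen_width_m))

  # no births -> no piglet events at all
  cfg0 <- sim_config(seed = 9, profile = "demo", litter_size = 0)
  tl0 <- generate_timeline(cfg0)
  ev0 <- generate_sound_events(tl0, generate_behaviour(tl0, cfg0), cfg0, geom)
  expect_equal(sum(ev0$label %in% c("piglet_birth", "piglet_move")), 0)
})

test_that("reference logs partition events by audibility", {
  cfg <- sim_config(seed = 12, profile = "demo")
  tl <- generate_timeline(cfg)
  script <- generate_behaviour(tl, cfg)
  ev <- generate_sound_events(tl, script, cfg)
  refs <- render_reference_logs(ev, script, cfg)
  expect_equal(nrow(refs$audible), sum(ev$audible))
  expect_false(any(refs$audible$label %in% c("piglet_birth", "piglet_move")))
  # behaviour log reproduces the script and conserves total duration
  expect_equal(sum(refs$behaviour$duration_s), tl$t_stop - tl$t_start)
  # a threshold above every amplitude silences the audible log
  cfg_hi <- cfg; cfg_hi$audibility_threshold <- max(ev$amplitude) + 1
  expect_equal(nrow(render_reference_logs(ev, script, cfg_hi)$audible), 0)
})
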