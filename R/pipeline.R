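#' Aggregate run configuration
#'
#' Bundles the per-stage configurations for [run_pipeline()]. `spot_source`
#' chooses how spots are produced: `"ideal"` emulates the camera at log
#' level (fast, suitable for long scenes), `"audio"` synthesises microphone
#' signals and runs the full beamforming chain (use with the `"demo"`
#' simulation profile).
#'
#' @param seed integer seed propagated to all stochastic stages
#' @param sim a [sim_config()] (its seed is overridden by `seed`)
#' @param geometry a [pen_geometry()]
#' @param array a [mic_array()]
#' @param band a [band_config()]
#' @param det a [detector_config()]
#' @param match a [match_config()]
#' @param onset a [onset_config()]
#' @param spot_source `"ideal"` or `"audio"`
#' @return object of class `fc_run_config`
#' @export
run_config <- function(seed = 1, sim = sim_config(seed = seed),
                       geometry = pen_geometry(), array = mic_array(geometry),
                       band = band_config(), det = detector_config(),
                       match = match_config(reference_mode = "sound_or_behaviour"),
                       onset = onset_config(),
                       spot_source = c("ideal", "audio")) {
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim, geometry = geometry,
                 array = array, band = band, det = det, match = match,
                 onset = onset, spot_source = match.arg(spot_source)),
            class = "fc_run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' simulate -> spots -> match -> metrics -> monitor, writing all artefacts
#' to a directory: `events.csv`, `audible.csv`, `behaviour.csv`,
#' `spots.csv`, `counts.json`, `metrics.csv`, `report.json`, and `run.log`
#' (package version, seed and configuration echo). Identical seeds give
#' byte-identical outputs.
#'
#' @param cfg a [run_config()]
#' @param out_dir output directory (created if needed)
#' @return (invisibly) list with the in-memory artefacts
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = tempfile("fc_run_")) {
  stopifnot(inherits(cfg, "fc_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tl <- run_stage("simulate", generate_timeline(cfg$sim))
  script <- run_stage("simulate", generate_behaviour(tl, cfg$sim))
  events <- run_stage("simulate",
                      generate_sound_events(tl, script, cfg$sim, cfg$geometry))
  refs <- run_stage("simulate", render_reference_logs(events, script, cfg$sim))

  spots <- run_stage("beamform", {
    if (cfg$spot_source == "audio") {
      beamform_scene(events, cfg$sim, cfg$array, cfg$geometry, cfg$band,
                     cfg$det)$spots
    } else {
      events_to_spots(events, cfg$sim, cfg$geometry, cfg$band,
                      lag_correction_s = cfg$det$lag_correction_s)
    }
  })

  mt <- run_stage("match",
                  match_events(spots, refs$audible, refs$behaviour,
                               cfg$match, t_range = c(tl$t_start, tl$t_stop)))
  metrics_tab <- run_stage("metrics", metrics_report(list(run = mt$counts)))
  report <- run_stage("monitor", {
    r <- detect_onset(spots, cfg$onset)
    if (!is.na(r$t_onset_est)) r <- monitor_progress(spots, r, cfg$onset)
    r
  })

  ev_log <- event_log(time_s = events$t, duration_s = events$duration_s,
                      stream = "spot", label = events$label,
                      zone = zone_of(events$x_m, events$y_m, cfg$geometry),
                      x_m = events$x_m, y_m = events$y_m,
                      audible = events$audible)
  write_log(ev_log, file.path(out_dir, "events.csv"))
  write_log(refs$audible, file.path(out_dir, "audible.csv"))
  write_log(refs$behaviour, file.path(out_dir, "behaviour.csv"))
  write_log(spots, file.path(out_dir, "spots.csv"))
  jsonlite::write_json(
    list(CP = mt$counts$CP, FP = mt$counts$FP, FN = mt$counts$FN,
         CN = mt$counts$CN, n_wrong_location = mt$n_wrong_location),
    file.path(out_dir, "counts.json"), auto_unbox = TRUE, digits = NA)
  write.csv(metrics_tab, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(t_onset_est = report$t_onset_est, t_end_est = report$t_end_est,
         progress_intervals = report$progress_intervals,
         alerts = report$alerts),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  writeLines(c(
    sprintf("farrowcam %s", as.character(utils::packageVersion("farrowcam"))),
    sprintf("seed: %d", cfg$seed),
    sprintf("profile: %s", cfg$sim$profile),
    sprintf("spot_source: %s", cfg$spot_source),
    sprintf("reference_mode: %s", cfg$match$reference_mode),
    sprintf("location_policy: %s", cfg$match$location_policy),
    sprintf("band: %g-%g Hz", cfg$band$f_lo, cfg$band$f_hi)),
    file.path(out_dir, "run.log"))

  invisible(list(timeline = tl, script = script, events = events,
                 refs = refs, spots = spots, match = mt,
                 metrics = metrics_tab, report = report, out_dir = out_dir))
}

#' Write packaged fixtures to a directory
#'
#' Copies the correspondence tables, writes the field-validation confusion
#' counts as JSON, and renders a small seeded demo scene (event log,
#' reference logs, and one second of 64-channel audio as float WAV).
#' Regeneration is deterministic.
#'
#' @param out_dir output directory
#' @param audio_s seconds of demo audio to render
#' @return (invisibly) character vector of written files
#' @export
make_fixtures <- function(out_dir = tempfile("fc_fixtures_"), audio_s = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  for (f in c("correspondence_study1_sound.csv",
              "correspondence_study2_sound.csv",
              "correspondence_study2_behaviour.csv",
              "field_validation_counts.csv", "behaviour_budgets.csv")) {
    src <- system.file("extdata", f, package = "farrowcam", mustWork = TRUE)
    file.copy(src, file.path(out_dir, f), overwrite = TRUE)
    written <- c(written, file.path(out_dir, f))
  }
  counts <- field_counts()
  jf <- file.path(out_dir, "field_validation_counts.json")
  jsonlite::write_json(
    lapply(counts, function(cc) list(CP = cc$CP, FP = cc$FP, FN = cc$FN,
                                     CN = cc$CN)),
    jf, auto_unbox = TRUE, digits = NA)
  written <- c(written, jf)

  cfg <- sim_config(seed = 20231116 %% 2147483647, profile = "demo")
  tl <- generate_timeline(cfg)
  script <- generate_behaviour(tl, cfg)
  events <- generate_sound_events(tl, script, cfg)
  refs <- render_reference_logs(events, script, cfg)
  ev_log <- event_log(time_s = events$t, duration_s = events$duration_s,
                      stream = "spot", label = events$label,
                      zone = zone_of(events$x_m, events$y_m),
                      x_m = events$x_m, y_m = events$y_m,
                      audible = events$audible)
  write_log(ev_log, file.path(out_dir, "demo_events.csv"))
  write_log(refs$audible, file.path(out_dir, "demo_audible.csv"))
  write_log(refs$behaviour, file.path(out_dir, "demo_behaviour.csv"))
  arr <- mic_array()
  t0 <- if (length(tl$birth_times)) tl$birth_times[1] - audio_s / 2 else 0
  x <- synthesize_mic_signals(events, arr, pen_geometry(), cfg, t0 = t0,
                              duration_s = audio_s)
  wf <- file.path(out_dir, "demo_scene.wav")
  write_wav(x, cfg$fs, wf)
  written <- c(written, file.path(out_dir, c("demo_events.csv",
                                             "demo_audible.csv",
                                             "demo_behaviour.csv")), wf)
  invisible(written)
}

#' Field-validation confusion counts shipped with the package
#'
#' The confusion counts from the first field validation of the sound camera
#' (four sows, 177 minutes of pre-farrowing video): one count set per
#' location policy.
#'
#' @return named list of [confusion_counts()] (`wrong_as_FN`,
#'   `wrong_as_CP`)
#' @export
field_counts <- function() {
  path <- system.file("extdata", "field_validation_counts.csv",
                      package = "farrowcam", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    confusion_counts(CP = df$CP[i], FP = df$FP[i], FN = df$FN[i],
                     CN = df$CN[i]))
  names(out) <- df$policy
  out
}
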