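# Per-label event properties: typical duration (s), amplitude multiplier on
# the configured median, whether the source can be audible to the observer,
# and the label the human observer writes in the audible-sound log.
label_props <- function() {
  data.frame(
    label = c("sow_vocal", "jute_rooting", "trough", "fence",
              "piglet_birth", "piglet_move", "neighbour"),
    duration_s = c(0.40, 0.50, 0.30, 0.15, 0.50, 0.20, 0.40),
    amp_mult = c(1.0, 0.8, 1.2, 1.0, 0.6, 0.5, 1.5),
    can_be_audible = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    audible_label = c("sow_in_crate", "sow_in_crate", "trough", "metal_fence",
                      NA, NA, "neighbour_sow"),
    stringsAsFactors = FALSE
  )
}

#' Generate timed, located sound events for a farrowing scene
#'
#' Draws the acoustic events of one scene from Poisson processes tied to the
#' timeline and behaviour script: sow vocalisations at the head of the sow
#' throughout; jute-sack/rooting sounds in the head zone during rooting
#' bouts; trough and fence sounds while the sow sits or stands; one birth
#' event per piglet in the area behind the sow (visible to the camera but
#' inaudible to the observer); piglet-movement sounds behind the sow for a
#' window after each birth; and neighbour-sow sounds located outside the pen.
#'
#' @param timeline a [generate_timeline()] result
#' @param script a [generate_behaviour()] script covering the timeline
#' @param cfg a [sim_config()]
#' @param geometry a [pen_geometry()]
#' @return object of class `fc_events`: data frame with one row per event
#'   (`t`, `duration_s`, `x_m`, `y_m`, `center_freq`, `bandwidth`,
#'   `amplitude`, `audible`, `label`, `id`), time-sorted
#' @export
generate_sound_events <- function(timeline, script, cfg = sim_config(),
                                  geometry = pen_geometry()) {
  stopifnot(inherits(timeline, "fc_timeline"))
  props <- label_props()
  with_seed(cfg$seed + 303L, {
    parts <- list()
    span <- c(timeline$t_start, timeline$t_stop)

    # state-conditional windows
    iv <- behaviour_intervals(script)
    rooting <- iv[iv$state == "jute_rooting", , drop = FALSE]
    sitting <- iv[iv$state == "sitting_standing", , drop = FALSE]

    parts$sow_vocal <- poisson_events(span[1], span[2],
                                      cfg$rates[["sow_vocal"]])
    parts$jute_rooting <- windowed_events(rooting, cfg$rates[["jute_rooting"]])
    parts$trough <- windowed_events(sitting, cfg$rates[["trough"]])
    parts$fence <- windowed_events(sitting, cfg$rates[["fence"]])
    parts$piglet_birth <- timeline$birth_times
    move_windows <- data.frame(start_s = timeline$birth_times,
                               end_s = pmin(timeline$birth_times +
                                              cfg$piglet_move_window_s,
                                            timeline$t_stop))
    parts$piglet_move <- windowed_events(move_windows,
                                         cfg$rates[["piglet_move"]])
    parts$neighbour <- poisson_events(span[1], span[2],
                                      cfg$rates[["neighbour"]])

    rows <- lapply(names(parts), function(lab) {
      t <- parts[[lab]]
      if (!length(t)) return(NULL)
      p <- props[props$label == lab, ]
      pos <- sample_positions(lab, length(t), geometry)
      amp <- rlnorm(length(t), log(cfg$amp_median * p$amp_mult), cfg$amp_sdlog)
      data.frame(
        t = t,
        duration_s = p$duration_s * runif(length(t), 0.7, 1.3),
        x_m = pos$x, y_m = pos$y,
        center_freq = runif(length(t), cfg$cf_range[1], cfg$cf_range[2]),
        bandwidth = cfg$bandwidth_hz,
        amplitude = amp,
        audible = p$can_be_audible & amp >= cfg$audibility_threshold,
        label = lab,
        stringsAsFactors = FALSE
      )
    })
    ev <- do.call(rbind, rows)
    if (is.null(ev)) {
      ev <- data.frame(t = numeric(), duration_s = numeric(),
                       x_m = numeric(), y_m = numeric(),
                       center_freq = numeric(), bandwidth = numeric(),
                       amplitude = numeric(), audible = logical(),
                       label = character(), stringsAsFactors = FALSE)
    }
    ev <- ev[order(ev$t), , drop = FALSE]
    ev$id <- seq_len(nrow(ev))
    rownames(ev) <- NULL
    structure(ev, class = c("fc_events", "data.frame"))
  })
}

poisson_events <- function(t0, t1, rate_per_min) {
  len <- t1 - t0
  if (len <= 0 || rate_per_min <= 0) return(numeric())
  n <- rpois(1, rate_per_min / 60 * len)
  sort(runif(n, t0, t1))
}

windowed_events <- function(windows, rate_per_min) {
  if (is.null(windows) || nrow(windows) == 0 || rate_per_min <= 0)
    return(numeric())
  out <- lapply(seq_len(nrow(windows)), function(i)
    poisson_events(windows$start_s[i], windows$end_s[i], rate_per_min))
  sort(unlist(out))
}

# Uniform positions within the characteristic area of each source type.
sample_positions <- function(label, n, geometry) {
  hx <- geometry$sow_head_x
  third <- geometry$crate_length_m / 3
  W <- geometry$pen_width_m; L <- geometry$pen_length_m
  cy0 <- geometry$crate_y0; cw <- geometry$crate_width_m
  box <- switch(label,
    sow_vocal = rect_region(hx + 0.10, hx + third - 0.10,
                            cy0 + 0.15, cy0 + cw - 0.15),
    jute_rooting = rect_region(hx + 0.05, hx + third - 0.05, 0.30, W - 0.30),
    trough = {
      tb <- trough_box(geometry)
      rect_region(tb["x0"] + 0.02, tb["x1"] - 0.02,
                  tb["y0"] + 0.05, tb["y1"] - 0.05)
    },
    piglet_birth = rear_zone_box(geometry),
    piglet_move = rear_zone_box(geometry),
    NULL)
  if (label == "fence") {
    # points on the boundary strip, one of the four sides
    side <- sample.int(4, n, replace = TRUE)
    u <- runif(n); d <- runif(n, 0.03, 0.12)
    x <- ifelse(side == 1, d, ifelse(side == 2, L - d, u * L))
    y <- ifelse(side <= 2, u * W, ifelse(side == 3, d, W - d))
    return(list(x = x, y = y))
  }
  if (label == "neighbour") {
    side <- sample(c(-1, 1), n, replace = TRUE)
    x <- ifelse(side < 0, runif(n, -0.5, -0.15), runif(n, L + 0.15, L + 0.5))
    return(list(x = x, y = runif(n, 0, W)))
  }
  list(x = runif(n, box["x0"], box["x1"]), y = runif(n, box["y0"], box["y1"]))
}

#' @export
print.fc_events <- function(x, ...) {
  cat(sprintf("Sound events: %d", nrow(x)))
  if (nrow(x)) {
    tab <- table(x$label)
    cat(" (", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Render reference annotation logs from a simulated scene
#'
#' Builds the two observer-style reference streams: the audible-sound log
#' (exactly the events the human observer can hear, i.e. audible sources at
#' or above the audibility threshold — piglet births and movement never
#' appear) and the behaviour log (the behaviour script verbatim).
#'
#' @param events a [generate_sound_events()] result
#' @param script a [generate_behaviour()] script
#' @param cfg a [sim_config()]
#' @return list with `audible` and `behaviour` event logs
#' @export
render_reference_logs <- function(events, script, cfg = sim_config()) {
  props <- label_props()
  aud <- events[events$audible & events$amplitude >= cfg$audibility_threshold,
                , drop = FALSE]
  lab <- props$audible_label[match(aud$label, props$label)]
  audible_log <- event_log(
    time_s = aud$t, duration_s = aud$duration_s, stream = "audible",
    label = lab, zone = NA_character_, x_m = NA_real_, y_m = NA_real_,
    audible = TRUE)
  iv <- behaviour_intervals(script)
  behaviour_log <- event_log(
    time_s = iv$start_s, duration_s = iv$end_s - iv$start_s,
    stream = "behaviour", label = iv$state, zone = NA_character_,
    x_m = NA_real_, y_m = NA_real_, audible = NA)
  list(audible = audible_log, behaviour = behaviour_log)
}

#' Which events rise above the camera's detection floor?
#'
#' An event is detectable when its in-band signal-to-noise ratio at the
#' array (source level attenuated over the slant distance to the array
#' centre, restricted to the analysis band) reaches `min_snr_db`, and its
#' position lies inside the camera's spatial-filter region.
#'
#' @param events a [generate_sound_events()] result
#' @param cfg a [sim_config()]
#' @param geometry a [pen_geometry()]
#' @param band a [band_config()]
#' @param min_snr_db detection floor margin (dB)
#' @param region spatial-filter rectangle (`c(x0, x1, y0, y1)`), default the
#'   pen
#' @return logical vector along the rows of `events`
#' @export
event_detectable <- function(events, cfg = sim_config(),
                             geometry = pen_geometry(),
                             band = band_config(), min_snr_db = 6,
                             region = NULL) {
  if (is.null(region))
    region <- rect_region(0, geometry$pen_length_m, 0, geometry$pen_width_m)
  if (!nrow(events)) return(logical())
  f1 <- events$center_freq - events$bandwidth / 2
  f2 <- events$center_freq + events$bandwidth / 2
  overlap <- pmax(0, pmin(f2, band$f_hi) - pmax(f1, band$f_lo)) /
    (f2 - f1)
  d <- sqrt((events$x_m - geometry$pen_length_m / 2)^2 +
              (events$y_m - geometry$pen_width_m / 2)^2 +
              geometry$camera_height_m^2)
  sig <- events$amplitude * sqrt(overlap) / d
  nz <- noise_rms(sim_cfg_or(cfg)) *
    sqrt((band$f_hi - band$f_lo) / (cfg$fs / 2))
  snr_ok <- if (nz > 0) 20 * log10(pmax(sig, 1e-300) / nz) >= min_snr_db
  else sig > 0
  snr_ok & in_rect(events$x_m, events$y_m, region)
}

sim_cfg_or <- function(cfg) {
  if (!inherits(cfg, "fc_sim_config")) stop("cfg must be a sim_config()")
  cfg
}

#' Emulate the camera at log level: events to sound spots
#'
#' Produces the spot stream an ideal acoustic camera would record, without
#' synthesising audio: one spot per detectable event (small time and
#' position jitter), plus spurious "clutter" spots at the configured rate,
#' all zone-annotated. The acquisition lag (`cfg$record_lag_s`) is applied
#' to the recorded times and then corrected by `lag_correction_s`, matching
#' the audio pipeline's behaviour.
#'
#' @param events a [generate_sound_events()] result
#' @param cfg a [sim_config()]
#' @param geometry a [pen_geometry()]
#' @param band a [band_config()]
#' @param min_snr_db detection floor margin (dB)
#' @param lag_correction_s correction added to recorded spot times
#' @param region_margin_m how far beyond the pen the displayed region
#'   extends (lets neighbour-sow sounds appear as `outside_pen` spots)
#' @return a spot [event_log]
#' @export
events_to_spots <- function(events, cfg = sim_config(),
                            geometry = pen_geometry(), band = band_config(),
                            min_snr_db = 6, lag_correction_s = cfg$record_lag_s,
                            region_margin_m = 0.6) {
  region <- rect_region(-region_margin_m,
                        geometry$pen_length_m + region_margin_m,
                        -region_margin_m,
                        geometry$pen_width_m + region_margin_m)
  det <- event_detectable(events, cfg, geometry, band, min_snr_db, region)
  ev <- events[det, , drop = FALSE]
  with_seed(cfg$seed + 404L, {
    t <- ev$t + rnorm(nrow(ev), 0, 0.10)
    x <- ev$x_m + rnorm(nrow(ev), 0, 0.02)
    y <- ev$y_m + rnorm(nrow(ev), 0, 0.02)
    span <- if (nrow(events)) range(events$t) else c(0, 0)
    n_cl <- rpois(1, cfg$rates[["clutter"]] / 60 * max(0, diff(span)))
    ct <- runif(n_cl, span[1], span[2])
    cx <- runif(n_cl, 0, geometry$pen_length_m)
    cy <- runif(n_cl, 0, geometry$pen_width_m)
    spots <- event_log(
      time_s = c(t, ct) - cfg$record_lag_s + lag_correction_s,
      duration_s = 0, stream = "spot", label = "spot",
      zone = zone_of(c(x, cx), c(y, cy), geometry),
      x_m = c(x, cx), y_m = c(y, cy), audible = NA)
    spots
  })
}
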