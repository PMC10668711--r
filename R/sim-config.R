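# Seed-scoped evaluation: runs code under a fixed RNG state and restores the
# caller's state afterwards, so simulator stages are reproducible without
# clobbering the session RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

#' Default per-phase behaviour time budgets
#'
#' Target proportions of time the sow spends lying, sitting/standing, and
#' playing with the jute sack / rooting the floor, for the three farrowing
#' phases (the values observed in the field: rooting drops from 25% before
#' farrowing to a 0.3% residual during farrowing and to zero afterwards).
#'
#' @return a 3 x 3 matrix, rows `before`/`during`/`after`, columns
#'   `lying`/`sitting_standing`/`jute_rooting`; each row sums to 1
#' @export
default_budgets <- function() {
  m <- rbind(before = c(0.717, 0.033, 0.250),
             during = c(0.935, 0.062, 0.003),
             after  = c(1.000, 0.000, 0.000))
  colnames(m) <- c("lying", "sitting_standing", "jute_rooting")
  m
}

#' Simulation configuration
#'
#' All knobs of the synthetic farrowing-scene generator. Defaults describe a
#' full study scene: four hours of pre-farrowing observation, a litter of 12
#' piglets born at a mean interval of 15 min, and four hours post farrowing.
#' `profile = "demo"` shrinks the scene to roughly half an hour spanning
#' farrowing onset and three births, sized for end-to-end audio runs.
#'
#' Amplitudes are linear source levels (RMS at 1 m); `snr_db` sets the
#' background-noise level as the in-band signal-to-noise ratio, at 1 m, of a
#' median-amplitude event whose spectrum fully overlaps a 2000 Hz analysis
#' band. Event rates are events per minute, most of them conditional on the
#' behaviour state (rooting sounds occur during rooting bouts, trough and
#' fence sounds while sitting/standing, piglet movement in a window after
#' each birth).
#'
#' @param seed integer seed controlling every stochastic stage
#' @param profile `"study"` (default) or `"demo"`
#' @param fs sample rate (Hz); must exceed twice the highest simulated
#'   frequency
#' @param litter_size number of piglets born
#' @param pre_farrowing_s,post_farrowing_s phase durations (s)
#' @param onset_to_first_birth_s mean delay from onset to the first birth (s)
#' @param birth_interval_mean_s mean between consecutive births (s)
#' @param end_buffer_s time from last birth to end of farrowing (s)
#' @param behaviour_budgets 3 x 3 per-phase budget matrix, rows summing to 1
#'   (see [default_budgets()])
#' @param dwell_mean_s named mean behaviour-bout durations (s)
#' @param dwell_shape gamma shape of bout durations
#' @param rates named event rates (events/min), see Details
#' @param audibility_threshold amplitude below which a sound is inaudible to
#'   the human observer
#' @param snr_db background-noise level, see above (`Inf` disables noise)
#' @param amp_median,amp_sdlog log-normal source-amplitude parameters
#' @param record_lag_s recording-chain lag: the acquisition timestamps spots
#'   this many seconds early (corrected downstream by the detector's lag
#'   correction)
#' @return object of class `fc_sim_config`
#' @export
sim_config <- function(seed = 1, profile = c("study", "demo"), fs = 192000,
                       litter_size = NULL,
                       pre_farrowing_s = NULL, onset_to_first_birth_s = NULL,
                       birth_interval_mean_s = NULL, end_buffer_s = NULL,
                       post_farrowing_s = NULL,
                       behaviour_budgets = default_budgets(),
                       dwell_mean_s = c(lying = 60, sitting_standing = 25,
                                        jute_rooting = 30),
                       dwell_shape = 4,
                       rates = NULL,
                       audibility_threshold = 0.02,
                       snr_db = 30, amp_median = 0.05, amp_sdlog = 0.6,
                       record_lag_s = 1.5) {
  profile <- match.arg(profile)
  defaults <- if (profile == "study") {
    list(litter_size = 12, pre_farrowing_s = 14400,
         onset_to_first_birth_s = 600, birth_interval_mean_s = 900,
         end_buffer_s = 900, post_farrowing_s = 14400)
  } else {
    list(litter_size = 3, pre_farrowing_s = 360,
         onset_to_first_birth_s = 180, birth_interval_mean_s = 240,
         end_buffer_s = 300, post_farrowing_s = 240)
  }
  pick <- function(arg, name) if (is.null(arg)) defaults[[name]] else arg
  litter_size <- pick(litter_size, "litter_size")
  pre_farrowing_s <- pick(pre_farrowing_s, "pre_farrowing_s")
  onset_to_first_birth_s <- pick(onset_to_first_birth_s, "onset_to_first_birth_s")
  birth_interval_mean_s <- pick(birth_interval_mean_s, "birth_interval_mean_s")
  end_buffer_s <- pick(end_buffer_s, "end_buffer_s")
  post_farrowing_s <- pick(post_farrowing_s, "post_farrowing_s")

  if (litter_size < 0 || litter_size != round(litter_size))
    stop("litter_size must be a non-negative integer")
  durs <- c(pre_farrowing_s, onset_to_first_birth_s, birth_interval_mean_s,
            end_buffer_s, post_farrowing_s)
  if (any(durs < 0)) stop("phase durations must be non-negative")

  bb <- as.matrix(behaviour_budgets)
  if (!all(dim(bb) == c(3, 3))) stop("behaviour_budgets must be 3 x 3")
  if (any(bb < 0) || any(abs(rowSums(bb) - 1) > 1e-9))
    stop("behaviour budgets per phase must be non-negative and sum to 1")
  rownames(bb) <- c("before", "during", "after")
  colnames(bb) <- c("lying", "sitting_standing", "jute_rooting")

  default_rates <- c(sow_vocal = 0.3, jute_rooting = 10, trough = 1.5,
                     fence = 1.0, piglet_move = 3, neighbour = 0.5,
                     clutter = 1.0)
  if (!is.null(rates)) {
    bad <- setdiff(names(rates), names(default_rates))
    if (length(bad)) stop("unknown rate name(s): ", paste(bad, collapse = ", "))
    default_rates[names(rates)] <- rates
  }
  if (any(default_rates < 0)) stop("event rates must be >= 0")

  cfg <- structure(list(
    seed = as.integer(seed), profile = profile, fs = fs,
    litter_size = litter_size,
    pre_farrowing_s = pre_farrowing_s,
    onset_to_first_birth_s = onset_to_first_birth_s,
    birth_interval_mean_s = birth_interval_mean_s,
    end_buffer_s = end_buffer_s,
    post_farrowing_s = post_farrowing_s,
    behaviour_budgets = bb,
    dwell_mean_s = dwell_mean_s, dwell_shape = dwell_shape,
    rates = default_rates,
    piglet_move_window_s = 600,
    audibility_threshold = audibility_threshold,
    snr_db = snr_db, amp_median = amp_median, amp_sdlog = amp_sdlog,
    cf_range = c(39800, 41400), bandwidth_hz = 3000,
    record_lag_s = record_lag_s,
    c_sound = 343
  ), class = "fc_sim_config")
  fmax <- max(cfg$cf_range) + cfg$bandwidth_hz / 2
  if (fs <= 2 * fmax)
    stop(sprintf("fs = %g too low: must exceed twice the highest simulated frequency (%g Hz)",
                 fs, fmax))
  cfg
}

#' @export
print.fc_sim_config <- function(x, ...) {
  cat(sprintf("Scene simulation config (profile '%s', seed %d)\n", x$profile,
              x$seed))
  cat(sprintf("  litter %d, pre %g s / post %g s, fs %g Hz, snr %g dB\n",
              x$litter_size, x$pre_farrowing_s, x$post_farrowing_s, x$fs,
              x$snr_db))
  invisible(x)
}

# Broadband background-noise RMS implied by snr_db: snr_db is the in-band
# SNR at 1 m of a median-amplitude event against a 2000 Hz analysis band.
noise_rms <- function(cfg) {
  if (!is.finite(cfg$snr_db)) return(0)
  inband <- cfg$amp_median * 10^(-cfg$snr_db / 20)
  inband / sqrt(2000 / (cfg$fs / 2))
}
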