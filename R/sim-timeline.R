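#' Generate a farrowing timeline
#'
#' Draws the key times of one farrowing: observation start, farrowing onset
#' (the cross-over from nest building to lying), the ordered birth times, end
#' of farrowing, and observation stop. Birth intervals are gamma distributed
#' around the configured mean; a litter of zero collapses the farrowing
#' phase (onset equals end of farrowing, no births).
#'
#' @param cfg a [sim_config()]
#' @return object of class `fc_timeline`: list with `t_start`, `t_onset`,
#'   `birth_times`, `t_end_farrowing`, `t_stop` (seconds from scene start)
#' @examples
#' tl <- generate_timeline(sim_config(seed = 7))
#' length(tl$birth_times)
#' @export
generate_timeline <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "fc_sim_config"))
  with_seed(cfg$seed + 101L, {
    t_onset <- cfg$pre_farrowing_s
    if (cfg$litter_size > 0) {
      first <- t_onset + rgamma(1, shape = 4,
                                scale = cfg$onset_to_first_birth_s / 4)
      gaps <- if (cfg$litter_size > 1)
        rgamma(cfg$litter_size - 1, shape = 2,
               scale = cfg$birth_interval_mean_s / 2) else numeric()
      births <- first + c(0, cumsum(gaps))
      t_end <- births[length(births)] + cfg$end_buffer_s
    } else {
      births <- numeric()
      t_end <- t_onset
    }
    tl <- structure(list(t_start = 0, t_onset = t_onset,
                         birth_times = births, t_end_farrowing = t_end,
                         t_stop = t_end + cfg$post_farrowing_s),
                    class = "fc_timeline")
    validate_timeline(tl)
    tl
  })
}

validate_timeline <- function(tl) {
  ord <- c(tl$t_start, tl$t_onset, tl$birth_times, tl$t_end_farrowing,
           tl$t_stop)
  if (is.unsorted(ord)) stop("timeline times must be ordered")
  if (length(tl$birth_times) > 1 && any(diff(tl$birth_times) <= 0))
    stop("birth times must be strictly increasing")
  invisible(tl)
}

#' @export
print.fc_timeline <- function(x, ...) {
  cat(sprintf("Farrowing timeline: onset at %.0f s, %d births, farrowing ends %.0f s, scene ends %.0f s\n",
              x$t_onset, length(x$birth_times), x$t_end_farrowing, x$t_stop))
  invisible(x)
}

# Phase windows of a timeline as a data frame.
timeline_phases <- function(tl) {
  data.frame(phase = c("before", "during", "after"),
             start_s = c(tl$t_start, tl$t_onset, tl$t_end_farrowing),
             end_s = c(tl$t_onset, tl$t_end_farrowing, tl$t_stop),
             stringsAsFactors = FALSE)
}
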