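#' Generate a sow behaviour script
#'
#' Samples a sequence of behaviour bouts (lying, sitting/standing, jute
#' sack/rooting) tiling the whole timeline. Within each farrowing phase,
#' bouts are drawn by renewal sampling: the next state is chosen with
#' probability proportional to (phase budget / mean bout length) and its
#' duration from a gamma distribution, so long-run time shares converge to
#' the configured phase budgets. After the end of farrowing the sow only
#' lies (the post-farrowing budget), and rooting during farrowing is limited
#' to the configured residual share.
#'
#' @param timeline a [generate_timeline()] result
#' @param cfg a [sim_config()]
#' @return object of class `fc_behaviour`: data frame with `start_s`,
#'   `end_s`, `state`; intervals are contiguous and cover the timeline
#' @export
generate_behaviour <- function(timeline, cfg = sim_config()) {
  stopifnot(inherits(timeline, "fc_timeline"), inherits(cfg, "fc_sim_config"))
  bb <- cfg$behaviour_budgets
  if (any(abs(rowSums(bb) - 1) > 1e-9)) stop("budgets must sum to 1 per phase")
  phases <- timeline_phases(timeline)
  parts <- vector("list", nrow(phases))
  with_seed(cfg$seed + 202L, {
    for (i in seq_len(nrow(phases))) {
      parts[[i]] <- sample_phase_bouts(phases$start_s[i], phases$end_s[i],
                                       bb[phases$phase[i], ], cfg)
    }
  })
  script <- do.call(rbind, parts)
  if (is.null(script) || nrow(script) == 0) {
    script <- data.frame(start_s = numeric(), end_s = numeric(),
                         state = character(), stringsAsFactors = FALSE)
  } else {
    script <- merge_adjacent_bouts(script)
  }
  structure(script, class = c("fc_behaviour", "data.frame"))
}

sample_phase_bouts <- function(t0, t1, budget, cfg) {
  if (t1 - t0 <= 0) return(NULL)
  states <- names(budget)
  active <- budget > 0
  if (sum(active) == 1) {
    return(data.frame(start_s = t0, end_s = t1, state = states[active],
                      stringsAsFactors = FALSE))
  }
  m <- cfg$dwell_mean_s[states]
  q <- (budget / m)[active]
  q <- q / sum(q)
  st <- states[active]
  # draw in batches until the phase is covered
  out_s <- numeric(0); out_state <- character(0)
  t <- t0
  while (t < t1) {
    n <- max(16L, ceiling((t1 - t) / min(m[active]) / 2))
    s <- sample(st, n, replace = TRUE, prob = q)
    d <- rgamma(n, shape = cfg$dwell_shape,
                scale = cfg$dwell_mean_s[s] / cfg$dwell_shape)
    cut <- which(cumsum(d) >= (t1 - t))[1]  # keep up to the bout crossing t1
    if (!is.na(cut)) { s <- s[seq_len(cut)]; d <- d[seq_len(cut)] }
    out_s <- c(out_s, t + c(0, cumsum(d))[seq_along(d)])
    out_state <- c(out_state, s)
    t <- t + sum(d)
  }
  ends <- c(out_s[-1], t1)
  keep <- out_s < t1
  data.frame(start_s = out_s[keep], end_s = pmin(ends[keep], t1),
             state = out_state[keep], stringsAsFactors = FALSE)
}

merge_adjacent_bouts <- function(df) {
  if (nrow(df) < 2) return(df)
  same <- c(FALSE, df$state[-1] == df$state[-nrow(df)] &
              abs(df$start_s[-1] - df$end_s[-nrow(df)]) < 1e-9)
  grp <- cumsum(!same)
  out <- data.frame(
    start_s = tapply(df$start_s, grp, min),
    end_s = tapply(df$end_s, grp, max),
    state = tapply(df$state, grp, function(s) s[1]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$start_s), , drop = FALSE]
}

#' @export
print.fc_behaviour <- function(x, ...) {
  cat(sprintf("Behaviour script: %d bouts", nrow(x)))
  if (nrow(x)) {
    share <- tapply(x$end_s - x$start_s, x$state, sum)
    share <- share / sum(share) * 100
    cat(" (", paste(sprintf("%s %.1f%%", names(share), share),
                    collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Per-phase behaviour time budgets of a log or script
#'
#' Computes the proportion of time spent in each behaviour state within each
#' farrowing phase. Behaviour coverage must tile each phase (no gaps, no
#' overlaps); violations are rejected.
#'
#' @param log a behaviour [event_log] (stream `behaviour`) or a
#'   [generate_behaviour()] script
#' @param timeline a [generate_timeline()] result (defines the phases)
#' @return data frame with columns `phase`, `state`, `proportion`;
#'   proportions sum to 1 within each non-empty phase
#' @export
time_budget <- function(log, timeline) {
  iv <- behaviour_intervals(log)
  phases <- timeline_phases(timeline)
  out <- list()
  for (i in seq_len(nrow(phases))) {
    t0 <- phases$start_s[i]; t1 <- phases$end_s[i]
    if (t1 - t0 <= 0) next
    s <- pmax(iv$start_s, t0); e <- pmin(iv$end_s, t1)
    keep <- e > s
    if (!any(keep)) stop("behaviour log does not cover phase ", phases$phase[i])
    s <- s[keep]; e <- e[keep]; st <- iv$state[keep]
    o <- order(s)
    s <- s[o]; e <- e[o]; st <- st[o]
    if (abs(s[1] - t0) > 1e-6 || abs(e[length(e)] - t1) > 1e-6 ||
        (length(s) > 1 && any(abs(s[-1] - e[-length(e)]) > 1e-6)))
      stop("behaviour intervals must tile phase ", phases$phase[i],
           " without gaps or overlaps")
    dur <- tapply(e - s, st, sum)
    out[[length(out) + 1L]] <- data.frame(
      phase = phases$phase[i], state = names(dur),
      proportion = as.numeric(dur) / (t1 - t0), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

behaviour_intervals <- function(log) {
  if (inherits(log, "fc_behaviour"))
    return(data.frame(start_s = log$start_s, end_s = log$end_s,
                      state = log$state, stringsAsFactors = FALSE))
  log <- as_event_log(log)
  b <- log[log$stream == "behaviour", , drop = FALSE]
  data.frame(start_s = b$time_s, end_s = b$time_s + b$duration_s,
             state = b$label, stringsAsFactors = FALSE)
}
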