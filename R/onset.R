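#' Onset-monitor configuration
#'
#' Thresholds for detecting farrowing onset, progress and end from a
#' zone-annotated spot stream. Onset is flagged when head-zone spot activity
#' (jute-sack play and rooting near the sow's head) collapses from a high
#' to a low rate and piglet-associated spot clusters appear behind the sow;
#' progress is tracked by new rear-zone clusters; their sustained absence
#' marks the end.
#'
#' @param window_s sliding-window length for the head-zone rate (s)
#' @param rooting_rate_high rate (events/min) the head-zone stream must have
#'   exceeded before a cessation counts
#' @param rooting_rate_low rate (events/min) below which rooting has
#'   "stopped"
#' @param rear_cluster_min minimum rear-zone spots within `cluster_span_s`
#'   to count as a piglet-activity cluster
#' @param cluster_span_s span of a rear-zone cluster (s)
#' @param progress_timeout_s a rear-zone silence of this length ends (or
#'   stalls) the farrowing process
#' @return object of class `fc_onset_config`
#' @export
onset_config <- function(window_s = 600, rooting_rate_high = 2.5,
                         rooting_rate_low = 0.6, rear_cluster_min = 5,
                         cluster_span_s = 120, progress_timeout_s = 1800) {
  if (window_s <= 0) stop("window_s must be positive")
  if (rooting_rate_low >= rooting_rate_high)
    stop("rooting_rate_low must be below rooting_rate_high")
  structure(list(window_s = window_s, rooting_rate_high = rooting_rate_high,
                 rooting_rate_low = rooting_rate_low,
                 rear_cluster_min = rear_cluster_min,
                 cluster_span_s = cluster_span_s,
                 progress_timeout_s = progress_timeout_s),
            class = "fc_onset_config")
}

# Rear-zone spot clusters: a spot belongs to a cluster when it lies in some
# span-long window holding at least `min_n` rear spots; clustered spots
# within `span` of each other merge into one cluster. Returns one row per
# cluster with its first and last spot time.
rear_clusters <- function(rear_t, min_n, span) {
  rear_t <- sort(rear_t)
  n <- length(rear_t)
  empty <- data.frame(start_s = numeric(), end_s = numeric())
  if (n < min_n) return(empty)
  hi <- seq_len(n) + min_n - 1L
  q <- which(hi <= n & rear_t[pmin(hi, n)] - rear_t <= span)
  if (!length(q)) return(empty)
  clustered <- logical(n)
  for (i in q) clustered[rear_t >= rear_t[i] & rear_t <= rear_t[i] + span] <- TRUE
  tt <- rear_t[clustered]
  brk <- c(0, which(diff(tt) > span), length(tt))
  data.frame(start_s = tt[utils::head(brk, -1) + 1], end_s = tt[brk[-1]])
}

#' Detect farrowing onset from a spot stream
#'
#' Finds the first time the sliding-window head-zone spot rate falls below
#' `rooting_rate_low` after having exceeded `rooting_rate_high`, confirmed
#' by a rear-zone spot cluster within `window_s` of the crossing. The onset
#' estimate itself is the change point of the head-zone spot rate around
#' the crossing (two-rate Poisson fit), i.e. the moment nest-building
#' activity ceased.
#'
#' @param spots a zone-annotated spot [event_log]
#' @param cfg an [onset_config()]
#' @return object of class `fc_report`: list with `t_onset_est` (`NA` if no
#'   onset), `t_end_est`, `progress_intervals`, `alerts`, plus diagnostic
#'   fields
#' @export
detect_onset <- function(spots, cfg = onset_config()) {
  spots <- as_event_log(spots)
  sp <- spots[spots$stream == "spot", , drop = FALSE]
  if (nrow(sp) && all(is.na(sp$zone)))
    stop("spot log must be zone-annotated")
  head_t <- sp$time_s[sp$zone %in% "head"]
  rear_t <- sp$time_s[sp$zone %in% "rump"]
  report <- structure(list(t_onset_est = NA_real_, t_end_est = NA_real_,
                           progress_intervals = data.frame(start_s = numeric(),
                                                           end_s = numeric()),
                           alerts = data.frame(t = numeric(),
                                               kind = character(),
                                               stringsAsFactors = FALSE),
                           crossing_t = NA_real_, config = cfg),
                      class = "fc_report")
  if (!length(head_t) || !nrow(sp)) return(report)

  span <- range(sp$time_s)
  grid <- seq(span[1] + cfg$window_s, span[2], by = min(30, cfg$window_s / 4))
  if (!length(grid)) return(report)
  rate <- vapply(grid, function(g)
    sum(head_t > g - cfg$window_s & head_t <= g), numeric(1)) /
    (cfg$window_s / 60)
  was_high <- cumsum(rate >= cfg$rooting_rate_high) > 0
  cand <- grid[was_high & rate < cfg$rooting_rate_low]
  # nest building does not resume once farrowing has started: discard dips
  # after which the head-zone rate climbs back to the "high" regime
  sustained <- vapply(cand, function(tc) {
    ahead <- rate[grid > tc & grid <= tc + 2 * cfg$window_s]
    !length(ahead) || max(ahead) < cfg$rooting_rate_high
  }, logical(1))
  cand <- cand[sustained]
  if (!length(cand)) return(report)

  clusters <- rear_clusters(rear_t, cfg$rear_cluster_min, cfg$cluster_span_s)
  confirmed <- NA_real_
  for (tc in cand) {
    if (nrow(clusters) &&
        any(clusters$start_s <= tc + cfg$window_s &
              clusters$end_s >= tc - cfg$window_s)) {
      confirmed <- tc
      break
    }
  }
  if (is.na(confirmed)) return(report)

  report$crossing_t <- confirmed
  report$t_onset_est <- head_rate_changepoint(head_t, confirmed, cfg)
  report$alerts <- data.frame(t = report$t_onset_est, kind = "onset",
                              stringsAsFactors = FALSE)
  report
}

# Two-rate Poisson change-point of the head-zone spot times around the
# detected crossing: the cessation moment maximising the piecewise
# constant-rate likelihood.
head_rate_changepoint <- function(head_t, crossing, cfg) {
  a <- crossing - 2 * cfg$window_s
  b <- crossing + cfg$window_s
  tt <- sort(head_t[head_t >= a & head_t <= b])
  if (length(tt) < 2) return(crossing - cfg$window_s / 2)
  best <- -Inf; best_s <- tt[length(tt)]
  for (s in tt) {
    n1 <- sum(tt <= s); n2 <- length(tt) - n1
    d1 <- s - a; d2 <- b - s
    if (d1 <= 0 || d2 <= 0) next
    ll <- n1 * log(max(n1, 1) / d1) + n2 * log(max(n2, 1e-6) / d2) -
      max(n1, 1) - n2
    if (ll > best) { best <- ll; best_s <- s }
  }
  best_s
}

#' Track farrowing progress and detect its end
#'
#' After onset, rear-zone spot clusters (newborn piglets moving behind the
#' sow) mark a farrowing still in progress. Gaps of at least
#' `progress_timeout_s` between clusters raise a "stalled" alert; the end
#' of farrowing is estimated as the last rear-zone cluster plus the
#' timeout, once rear activity has ceased for good.
#'
#' @param spots a zone-annotated spot [event_log]
#' @param report a [detect_onset()] result with a detected onset
#' @param cfg an [onset_config()]
#' @return the updated `fc_report`
#' @export
monitor_progress <- function(spots, report, cfg = onset_config()) {
  if (!inherits(report, "fc_report")) stop("report must come from detect_onset()")
  if (is.na(report$t_onset_est))
    stop("monitor_progress() requires a detected onset")
  spots <- as_event_log(spots)
  sp <- spots[spots$stream == "spot", , drop = FALSE]
  rear_t <- sp$time_s[sp$zone %in% "rump" &
                        sp$time_s >= report$t_onset_est - cfg$window_s]
  clusters <- rear_clusters(rear_t, cfg$rear_cluster_min, cfg$cluster_span_s)
  if (!nrow(clusters)) {
    report$t_end_est <- report$t_onset_est
    report$alerts <- rbind(report$alerts,
                           data.frame(t = report$t_onset_est, kind = "ended",
                                      stringsAsFactors = FALSE))
    return(report)
  }
  nc <- nrow(clusters)
  gaps <- if (nc > 1) clusters$start_s[-1] - clusters$end_s[-nc] else numeric()
  stalled_at <- clusters$end_s[which(gaps >= cfg$progress_timeout_s)] +
    cfg$progress_timeout_s
  brk <- c(0, which(gaps >= cfg$progress_timeout_s), nc)
  iv <- data.frame(
    start_s = clusters$start_s[utils::head(brk, -1) + 1],
    end_s = clusters$end_s[brk[-1]])
  report$progress_intervals <- iv
  report$t_end_est <- clusters$end_s[nc] + cfg$progress_timeout_s
  alerts <- rbind(
    report$alerts[report$alerts$kind == "onset", , drop = FALSE],
    if (length(stalled_at)) data.frame(t = stalled_at, kind = "stalled",
                                       stringsAsFactors = FALSE),
    data.frame(t = report$t_end_est, kind = "ended", stringsAsFactors = FALSE))
  report$alerts <- alerts[order(alerts$t), , drop = FALSE]
  rownames(report$alerts) <- NULL
  report
}

#' @export
print.fc_report <- function(x, ...) {
  if (is.na(x$t_onset_est)) {
    cat("Farrowing report: no onset detected\n")
  } else {
    cat(sprintf("Farrowing report: onset at %.0f s", x$t_onset_est))
    if (!is.na(x$t_end_est)) cat(sprintf(", end at %.0f s", x$t_end_est))
    cat(sprintf("; %d progress interval(s), %d alert(s)\n",
                nrow(x$progress_intervals), nrow(x$alerts)))
  }
  invisible(x)
}
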