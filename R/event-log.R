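#' Event logs
#'
#' The shared event-log format used by every stage: one row per event with
#' columns `time_s`, `duration_s`, `stream` (one of `audible`, `behaviour`,
#' `spot`), `label`, `zone`, `x_m`, `y_m`, `audible`. Behaviours are state
#' intervals (duration > 0); audible sounds and spots are (near-)point
#' events. Logs are kept time-sorted.
#'
#' @name event_log
NULL

log_columns <- function() {
  c("time_s", "duration_s", "stream", "label", "zone", "x_m", "y_m", "audible")
}

#' Build an event log from vectors
#'
#' @param time_s event start times (s)
#' @param duration_s durations (s, 0 for point events)
#' @param stream one of `"audible"`, `"behaviour"`, `"spot"` (recycled)
#' @param label event label (sound label, behaviour state, or `"spot"`)
#' @param zone zone name or `NA`
#' @param x_m,y_m pen-plane position or `NA`
#' @param audible logical flag or `NA`
#' @return a `fc_event_log` (data frame), sorted by time
#' @export
event_log <- function(time_s = numeric(), duration_s = 0, stream = "spot",
                      label = "spot", zone = NA_character_,
                      x_m = NA_real_, y_m = NA_real_, audible = NA) {
  n <- length(time_s)
  df <- data.frame(
    time_s = as.numeric(time_s),
    duration_s = rep_len(as.numeric(duration_s), n),
    stream = rep_len(as.character(stream), n),
    label = rep_len(as.character(label), n),
    zone = rep_len(as.character(zone), n),
    x_m = rep_len(as.numeric(x_m), n),
    y_m = rep_len(as.numeric(y_m), n),
    audible = rep_len(as.logical(audible), n),
    stringsAsFactors = FALSE
  )
  as_event_log(df)
}

#' Coerce a data frame to an event log
#'
#' Validates columns and values, sorts by time (then stream, then label for
#' a stable order), and classes the result.
#'
#' @param df a data frame with the event-log columns
#' @return a `fc_event_log`
#' @export
as_event_log <- function(df) {
  if (inherits(df, "fc_event_log") && !is.unsorted(df$time_s)) return(df)
  missing_cols <- setdiff(log_columns(), names(df))
  if (length(missing_cols))
    stop("event log is missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, log_columns(), drop = FALSE]
  if (nrow(df)) {
    if (any(!is.finite(df$time_s))) stop("event log has non-finite time_s")
    if (any(df$duration_s < 0, na.rm = TRUE)) stop("durations must be >= 0")
    bad <- !df$stream %in% c("audible", "behaviour", "spot")
    if (any(bad)) stop("unknown stream value(s): ",
                       paste(unique(df$stream[bad]), collapse = ", "))
    badz <- !is.na(df$zone) & !df$zone %in% pen_zones()
    if (any(badz)) stop("unknown zone value(s): ",
                        paste(unique(df$zone[badz]), collapse = ", "))
    df <- df[order(df$time_s, df$stream, df$label), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("fc_event_log", "data.frame")
  df
}

#' @export
print.fc_event_log <- function(x, ...) {
  cat(sprintf("Event log: %d entries", nrow(x)))
  if (nrow(x)) {
    cat(sprintf(" over [%.1f, %.1f] s", min(x$time_s),
                max(x$time_s + x$duration_s)))
    tab <- table(x$stream)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Read / write event logs
#'
#' CSV I/O for the shared dialect. `read_log()` validates the header and the
#' rows (reporting the offending line on failure), sorts unsorted input with
#' a message, and returns a `fc_event_log`; `write_log()` is its inverse
#' (`write_log()` then `read_log()` round-trips losslessly).
#'
#' @param path file path
#' @return `read_log()`: a `fc_event_log`; `write_log()`: `path`, invisibly
#' @export
read_log <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(log_columns(), names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")))
  if (nrow(df)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df$time_s))))
    if (length(bad))
      stop(sprintf("%s: malformed time_s at data line %d", path, bad[1]))
    df$time_s <- as.numeric(df$time_s)
    df$duration_s <- as.numeric(df$duration_s)
    df$x_m <- as.numeric(df$x_m)
    df$y_m <- as.numeric(df$y_m)
    df$audible <- as.logical(df$audible)
    for (col in c("zone", "label")) {
      df[[col]] <- as.character(df[[col]])
      df[[col]][!nzchar(df[[col]]) | is.na(df[[col]])] <- NA_character_
    }
    if (is.unsorted(df$time_s))
      message(sprintf("%s: entries out of time order; sorted on read", path))
  }
  as_event_log(df)
}

#' @rdname read_log
#' @param log a `fc_event_log`
#' @export
write_log <- function(log, path) {
  log <- as_event_log(log)
  write.csv(as.data.frame(log), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Merge several logs into one sorted log.
bind_logs <- function(...) {
  parts <- Filter(function(d) !is.null(d) && nrow(d) > 0, list(...))
  if (!length(parts)) return(event_log())
  as_event_log(do.call(rbind, lapply(parts, as.data.frame)))
}
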