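#' Pen zones
#'
#' The pen plane is partitioned into named zones used when judging whether a
#' sound spot sits at the right location for a reference sound or behaviour:
#' head / rump of the sow (front / rear thirds of the crate footprint,
#' extended across the pen width), trough (at the head end, in front of the
#' crate), fence (a strip along the pen boundary), `outside_pen` (beyond the
#' pen), and `none` (mid-pen positions belonging to no named zone). `cloud`
#' is a derived zone: it never comes from a position, only from clustering
#' many near-simultaneous spots (see [annotate_clouds()]).
#'
#' @return character vector of valid zone names
#' @export
pen_zones <- function() {
  c("head", "rump", "fence", "trough", "outside_pen", "cloud", "none")
}

#' Map a pen-plane position to its zone
#'
#' Deterministic, total partition: every position maps to exactly one zone.
#' Precedence: outside the pen, then the fence strip, then the trough box,
#' then head / rump thirds by x, else `none`.
#'
#' @param x,y position in metres (vectorised)
#' @param geometry a [pen_geometry()]
#' @param fence_strip_m width of the boundary strip counted as "fence"
#' @return character vector of zones
#' @examples
#' zone_of(0.4, 0.875)   # crate front centre -> "head"
#' zone_of(3.3, 0.875)   # beyond the pen -> "outside_pen"
#' @export
zone_of <- function(x, y, geometry = pen_geometry(), fence_strip_m = 0.15) {
  stopifnot(length(x) == length(y))
  L <- geometry$pen_length_m; W <- geometry$pen_width_m
  hx <- geometry$sow_head_x
  third <- geometry$crate_length_m / 3
  head_hi <- hx + third          # front third of the crate
  rump_lo <- hx + 2 * third      # rear third of the crate
  trough <- trough_box(geometry, fence_strip_m)

  z <- rep("none", length(x))
  outside <- x < 0 | x > L | y < 0 | y > W
  fence <- !outside & (x < fence_strip_m | x > L - fence_strip_m |
                         y < fence_strip_m | y > W - fence_strip_m)
  tr <- !outside & !fence & in_rect(x, y, trough)
  hd <- !outside & !fence & !tr & x < head_hi
  rp <- !outside & !fence & !tr & x >= rump_lo
  z[outside] <- "outside_pen"
  z[fence] <- "fence"
  z[tr] <- "trough"
  z[hd] <- "head"
  z[rp] <- "rump"
  z
}

# Trough footprint: between the fence strip and the crate head end, centred
# across the pen width.
trough_box <- function(geometry, fence_strip_m = 0.15) {
  x0 <- fence_strip_m
  x1 <- max(geometry$sow_head_x, x0 + 0.01)
  cy <- geometry$pen_width_m / 2
  rect_region(x0, x1, cy - 0.3, cy + 0.3)
}

# Floor area behind the sow where piglets are born and move about:
# rear part of the crate footprint and the floor behind it.
rear_zone_box <- function(geometry, fence_strip_m = 0.15) {
  rect_region(geometry$sow_head_x + 2 * geometry$crate_length_m / 3 + 0.05,
              geometry$pen_length_m - fence_strip_m - 0.05,
              fence_strip_m + 0.2,
              geometry$pen_width_m - fence_strip_m - 0.2)
}

#' Flag clusters of sound spots as "cloud" events
#'
#' The camera sometimes shows a burst of spots at once (a "cloud"). A spot is
#' relabelled `cloud` when at least `min_spots` spots fall within `window_s`
#' seconds and `radius_m` metres of it.
#'
#' @param log an event log (see [read_log()]) whose `spot` entries carry
#'   `x_m`, `y_m`
#' @param min_spots,window_s,radius_m cluster thresholds
#' @return the log with the `zone` of clustered spots set to `"cloud"`
#' @export
annotate_clouds <- function(log, min_spots = 5, window_s = 1, radius_m = 0.3) {
  log <- as_event_log(log)
  idx <- which(log$stream == "spot")
  if (length(idx) < min_spots) return(log)
  t <- log$time_s[idx]; x <- log$x_m[idx]; y <- log$y_m[idx]
  is_cloud <- logical(length(idx))
  for (i in seq_along(idx)) {
    near <- abs(t - t[i]) <= window_s &
      sqrt((x - x[i])^2 + (y - y[i])^2) <= radius_m
    if (sum(near, na.rm = TRUE) >= min_spots) is_cloud[i] <- TRUE
  }
  log$zone[idx[is_cloud]] <- "cloud"
  log
}
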