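#' Farrowing-pen geometry
#'
#' Describes the pen used throughout the package: a rectangular farrowing pen
#' containing a farrowing crate, observed from above by a microphone array.
#' Coordinates are metres in the pen plane, origin at the pen corner, x along
#' the long (2.80 m) axis with the sow's head at low x, y across the width.
#'
#' @param pen_length_m pen length along x (m)
#' @param pen_width_m pen width along y (m)
#' @param crate_length_m farrowing-crate length (m), must fit in the pen
#' @param crate_width_m farrowing-crate width (m)
#' @param camera_height_m height of the overhead camera/array above the floor (m)
#' @param sow_head_x x coordinate of the head end of the crate (m)
#' @return an object of class `fc_pen` (a named list of the fields above,
#'   plus the derived crate y-offset centring the crate across the pen)
#' @examples
#' geom <- pen_geometry()
#' geom$pen_length_m
#' @export
pen_geometry <- function(pen_length_m = 2.80, pen_width_m = 1.75,
                         crate_length_m = 2.1, crate_width_m = 1.0,
                         camera_height_m = 2.0, sow_head_x = 0.35) {
  lens <- c(pen_length_m, pen_width_m, crate_length_m, crate_width_m,
            camera_height_m)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all pen/crate/camera dimensions must be positive and finite")
  if (crate_length_m > pen_length_m || crate_width_m > pen_width_m)
    stop("crate dimensions must not exceed pen dimensions")
  if (sow_head_x < 0 || sow_head_x + crate_length_m > pen_length_m)
    stop("crate (sow_head_x + crate_length_m) must lie inside the pen")
  structure(list(
    pen_length_m = pen_length_m, pen_width_m = pen_width_m,
    crate_length_m = crate_length_m, crate_width_m = crate_width_m,
    camera_height_m = camera_height_m, sow_head_x = sow_head_x,
    crate_y0 = (pen_width_m - crate_width_m) / 2
  ), class = "fc_pen")
}

#' @export
print.fc_pen <- function(x, ...) {
  cat(sprintf("Farrowing pen %.2f x %.2f m, crate %.2f x %.2f m (head end at x = %.2f m)\n",
              x$pen_length_m, x$pen_width_m, x$crate_length_m, x$crate_width_m,
              x$sow_head_x))
  cat(sprintf("Camera/array height: %.2f m above floor\n", x$camera_height_m))
  invisible(x)
}

#' Overhead microphone array
#'
#' A planar square grid of microphones (8 x 8 = 64 by default) centred over
#' the pen at camera height, mimicking an acoustic-camera front end.
#'
#' @param geometry an [pen_geometry()] object
#' @param n_side microphones per side of the square grid
#' @param pitch_m spacing between adjacent microphones (m)
#' @return an object of class `fc_array`: list with `positions` (n x 3 matrix
#'   of x, y, z in metres) and `n_mics`
#' @examples
#' arr <- mic_array()
#' arr$n_mics
#' @export
mic_array <- function(geometry = pen_geometry(), n_side = 8, pitch_m = 0.04) {
  if (n_side < 1 || pitch_m <= 0) stop("invalid array geometry")
  cx <- geometry$pen_length_m / 2
  cy <- geometry$pen_width_m / 2
  off <- (seq_len(n_side) - (n_side + 1) / 2) * pitch_m
  pos <- as.matrix(expand.grid(x = cx + off, y = cy + off))
  pos <- cbind(pos, z = geometry$camera_height_m)
  if (anyDuplicated(pos)) stop("microphone positions must be distinct")
  structure(list(positions = unname(pos), n_mics = nrow(pos),
                 pitch_m = pitch_m, n_side = n_side),
            class = "fc_array")
}

#' @export
print.fc_array <- function(x, ...) {
  cat(sprintf("Microphone array: %d mics (%d x %d grid, %.0f mm pitch) at z = %.2f m\n",
              x$n_mics, x$n_side, x$n_side, x$pitch_m * 1000,
              x$positions[1, 3]))
  invisible(x)
}

#' Analysis frequency band
#'
#' The camera denoises by visualising only a narrow ultrasonic band. The
#' usable range is 39--49 kHz; each camera is tuned to a 2000 Hz band inside
#' it (default here: 39,570--41,570 Hz).
#'
#' @param f_lo,f_hi band edges in Hz
#' @param strict if `TRUE` (default) require the band to lie within the
#'   39--49 kHz range used in the field
#' @return object of class `fc_band`
#' @export
band_config <- function(f_lo = 39570, f_hi = 41570, strict = TRUE) {
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo <= 0 || f_lo >= f_hi)
    stop("invalid band: need 0 < f_lo < f_hi")
  if (strict && (f_lo < 39000 || f_hi > 49000))
    stop("band outside the 39,000-49,000 Hz range; use strict = FALSE to override")
  structure(list(f_lo = f_lo, f_hi = f_hi), class = "fc_band")
}

# Axis-aligned rectangle helper used for spatial regions and zone boxes.
rect_region <- function(x0, x1, y0, y1) {
  stopifnot(x0 < x1, y0 < y1)
  c(x0 = unname(x0), x1 = unname(x1), y0 = unname(y0), y1 = unname(y1))
}

in_rect <- function(x, y, r) {
  x >= r["x0"] & x <= r["x1"] & y >= r["y0"] & y <= r["y1"]
}
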