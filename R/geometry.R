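#' Screen geometry for pixel/degree conversion
#'
#' Captures the physical viewing setup needed to convert on-screen pixel
#' displacements into visual angles. Defaults describe the study setup: a
#' participant seated 80 cm from a 24-inch 16:9 monitor (1920 px across
#' 531.4 mm of active width, i.e. a pixel pitch of 0.2766 mm/px).
#'
#' @param distance_mm Viewing distance from eye to screen plane, mm.
#' @param pitch_mm_px Physical size of one pixel, mm.
#' @param resolution_px Integer vector `c(width, height)` of the display,
#'   carried as metadata only.
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(distance_mm = 800, pitch_mm_px = 0.2766,
                            resolution_px = c(1920L, 1080L)) {
  stopifnot(distance_mm > 0, pitch_mm_px > 0, all(resolution_px > 0))
  structure(list(distance_mm = distance_mm, pitch_mm_px = pitch_mm_px,
                 resolution_px = as.integer(resolution_px)),
            class = "screen_geometry")
}

#' Convert a pixel displacement to visual degrees
#'
#' Uses the exact subtended-angle formula
#' \deqn{\theta = 2 \arctan\!\left(\frac{d \cdot p}{2 D}\right)}
#' where `d` is the displacement in pixels, `p` the pixel pitch (mm/px) and
#' `D` the viewing distance (mm).
#'
#' @param displacement_px Numeric vector of displacements in pixels
#'   (non-negative magnitudes; signs are preserved through `atan`).
#' @param geometry A [screen_geometry()].
#' @return Visual angle(s) in degrees.
#' @export
pixels_to_degrees <- function(displacement_px, geometry = screen_geometry()) {
  stopifnot(inherits(geometry, "screen_geometry"))
  2 * atan((displacement_px * geometry$pitch_mm_px) /
             (2 * geometry$distance_mm)) * 180 / pi
}

#' Convert a visual angle to a pixel displacement
#'
#' Inverse of [pixels_to_degrees()].
#'
#' @param degrees Visual angle(s), degrees.
#' @inheritParams pixels_to_degrees
#' @return Displacement(s) in pixels.
#' @export
degrees_to_pixels <- function(degrees, geometry = screen_geometry()) {
  stopifnot(inherits(geometry, "screen_geometry"))
  2 * geometry$distance_mm * tan(degrees * pi / 360) / geometry$pitch_mm_px
}
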