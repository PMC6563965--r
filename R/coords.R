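#' Visual-field coordinate conventions
#'
#' Throughout the package the visual field is parameterised with x rightward,
#' y upward and the origin at fixation. Polar angle is measured
#' counterclockwise from the *upper vertical meridian* in `[0, 360)` degrees,
#' so straight up is 0, left is 90, straight down is 180 and right is 270.
#' This puts the four quadrants of a hemifield (upper, middle-upper,
#' middle-lower, lower) at successive 45-degree steps away from the upper
#' vertical meridian on either side.
#'
#' @param x,y field coordinates in degrees of visual angle.
#' @return `field_angle()` returns polar angles in degrees in `[0, 360)`;
#'   `field_ecc()` returns eccentricities in degrees.
#' @examples
#' field_angle(0, 1)   # upper vertical meridian -> 0
#' field_angle(-1, 0)  # left horizontal meridian -> 90
#' @export
field_angle <- function(x, y) {
  (atan2(y, x) * 180 / pi - 90) %% 360
}

#' @rdname field_angle
#' @export
field_ecc <- function(x, y) sqrt(x^2 + y^2)

#' Convert polar-angle/eccentricity to cartesian field coordinates
#'
#' Inverse of [field_angle()]/[field_ecc()] under the package's angle
#' convention (degrees counterclockwise from the upper vertical meridian).
#'
#' @param angle polar angle in degrees.
#' @param ecc eccentricity in degrees.
#' @return a list with numeric components `x` and `y`.
#' @export
angle_to_xy <- function(angle, ecc) {
  phi <- (angle + 90) * pi / 180
  list(x = ecc * cos(phi), y = ecc * sin(phi))
}

#' Angular distance from the upper vertical meridian through a hemifield
#'
#' Maps a polar angle to its distance (0..180 degrees) from the upper vertical
#' meridian travelled through the named hemifield: 0 is the upper vertical
#' meridian, 90 the horizontal meridian, 180 the lower vertical meridian.
#' Angles on the opposite (ipsilateral) side come out negative or above 180
#' after wrapping into (-180, 180], which downstream sector logic treats as
#' outside the hemifield.
#'
#' @param angle polar angle in degrees (package convention).
#' @param hemifield `"left"` or `"right"`.
#' @return signed meridian distance in degrees in `(-180, 180]`.
#' @export
meridian_distance <- function(angle, hemifield = c("left", "right")) {
  hemifield <- match.arg(hemifield)
  d <- if (hemifield == "left") angle %% 360 else (360 - angle) %% 360
  d2 <- ((d + 180) %% 360) - 180
  # wrap into (-180, 180]; 180 itself (lower vertical meridian) stays 180
  ifelse(d2 == -180, 180, d2)
}

# internal: angular distance between two angles in degrees, in [0, 180]
ang_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
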