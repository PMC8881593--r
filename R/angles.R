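#' Wrap angles to the principal interval
#'
#' All headings in the package are expressed in radians, counter-clockwise
#' positive, with 0 along the +x axis, and wrapped to (-pi, pi].  Bearings
#' (egocentric landmark angles) use the same convention but in degrees,
#' wrapped to (-180, 180].
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to (-pi, pi].
#' @export
wrap_angle <- function(x) {
  w <- x - 2 * pi * floor((x + pi) / (2 * pi))
  # floor() maps the upper boundary to -pi; the convention is (-pi, pi]
  w[w <= -pi] <- pi
  w
}

#' @rdname wrap_angle
#' @export
wrap_deg <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  w[w <= -180] <- 180
  w
}

#' Signed smallest difference between two angles (radians)
#'
#' @param a,b angles in radians.
#' @return wrapped `a - b` in (-pi, pi].
#' @export
angle_diff <- function(a, b) wrap_angle(a - b)

#' @rdname wrap_angle
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname wrap_angle
#' @export
rad2deg <- function(x) x * 180 / pi

#' Unwrap a wrapped angle series into a continuous one
#'
#' Inverse of [wrap_angle()] up to a constant: consecutive jumps larger than
#' pi in magnitude are interpreted as wrap-arounds.
#'
#' @param x numeric vector of wrapped angles (radians).
#' @return continuous angle series with `x[1]` unchanged.
#' @export
unwrap_angle <- function(x) {
  if (length(x) < 2L) return(x)
  d <- wrap_angle(diff(x))
  cumsum(c(x[1], d))
}
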