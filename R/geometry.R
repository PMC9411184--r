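#' Build a circular phased-array geometry
#'
#' Places `n_elements` point-like line sources equally spaced on a circle
#' of `chamber_diameter`, with unit normals pointing at the array centre.
#' Defaults reproduce the reference device: a 64-element circular array
#' around a 10.98 mm water-filled chamber driven at 2.35 MHz.
#'
#' The device operating wavelength may differ slightly from `c0/frequency`
#' (transducer calibration fixes it in practice); `wavelength` therefore
#' defaults to the device value 0.644 mm, and can be set to `NULL` to
#' derive it from the medium (`c0/frequency` = 0.638 mm at 1500 m/s).
#' The wavenumber is always `k = 2*pi/wavelength`.
#'
#' @param n_elements Number of array elements (>= 3).
#' @param chamber_diameter Chamber diameter (m).
#' @param element_width Element aperture width `a` (m), used by the
#'   far-field sinc directivity. Default 0.45 mm (the inter-element arc
#'   pitch of the default device minus a small kerf).
#' @param frequency Drive frequency (Hz).
#' @param med Host [medium()].
#' @param wavelength Operating wavelength (m), or `NULL` for `c0/frequency`.
#' @return Object of class `array_geometry` with element positions (N x 2,
#'   metres, origin at the array centre), inward unit normals, element ring
#'   angles, `k`, `wavelength`, and the constructor arguments.
#' @examples
#' geom <- build_circular_array()
#' geom$n_elements      # 64
#' geom$wavelength      # 6.44e-4
#' @export
build_circular_array <- function(n_elements = 64,
                                 chamber_diameter = 10.98e-3,
                                 element_width = 0.45e-3,
                                 frequency = 2.35e6,
                                 med = medium(),
                                 wavelength = 0.644e-3) {
  if (n_elements < 3 || n_elements != round(n_elements)) {
    stop("invalid geometry: n_elements must be an integer >= 3", call. = FALSE)
  }
  if (any(c(chamber_diameter, element_width, frequency) <= 0)) {
    stop("invalid geometry: dimensions and frequency must be positive",
         call. = FALSE)
  }
  if (is.null(wavelength)) wavelength <- med$c0 / frequency
  if (wavelength <= 0) stop("invalid geometry: wavelength must be positive",
                            call. = FALSE)
  radius <- chamber_diameter / 2
  angles <- 2 * pi * (seq_len(n_elements) - 1) / n_elements
  positions <- cbind(radius * cos(angles), radius * sin(angles))
  normals <- -cbind(cos(angles), sin(angles))  # inward
  structure(
    list(
      n_elements = as.integer(n_elements),
      chamber_diameter = chamber_diameter,
      chamber_radius = radius,
      element_width = element_width,
      frequency = frequency,
      medium = med,
      wavelength = wavelength,
      k = 2 * pi / wavelength,
      element_angles = angles,
      element_positions = positions,
      element_normals = normals
    ),
    class = "array_geometry"
  )
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf(
    "circular array: %d elements, chamber %.2f mm, %.2f MHz, lambda %.3f mm\n",
    x$n_elements, x$chamber_diameter * 1e3, x$frequency * 1e-6,
    x$wavelength * 1e3
  ))
  invisible(x)
}

# Is a point (or matrix of points) inside the chamber?
inside_chamber <- function(geometry, point, margin = 0) {
  p <- matrix(point, ncol = 2)
  sqrt(rowSums(p^2)) < geometry$chamber_radius - margin
}
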