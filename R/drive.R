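#' Per-element drive state of the array
#'
#' One acoustic state: a non-negative source amplitude and a phase for
#' every array element. Phases are stored wrapped to (-pi, pi].
#'
#' @param amplitudes Numeric vector of per-element amplitudes (>= 0),
#'   in pressure-source units.
#' @param phases Numeric vector of per-element phases (radians).
#' @param label Short text tag.
#' @return Object of class `drive_state`.
#' @export
drive_state <- function(amplitudes, phases, label = "") {
  if (length(amplitudes) != length(phases)) {
    stop("amplitudes and phases must have the same length", call. = FALSE)
  }
  if (any(amplitudes < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  structure(
    list(amplitudes = as.numeric(amplitudes),
         phases = wrap_phase(phases),
         label = as.character(label)),
    class = "drive_state"
  )
}

#' Wrap phases to (-pi, pi]
#' @param phi Phases in radians.
#' @return Wrapped phases.
#' @export
wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

# complex per-element source term a0 * exp(i phi)
drive_complex <- function(drive) {
  drive$amplitudes * exp(1i * drive$phases)
}

#' Bessel (vortex) drive state
#'
#' Phase law for an order-`m` Bessel-shaped field focused at a point:
#' element `n` carries
#' \eqn{\phi_n = s \, 2 m \pi (n-1)/N - k r_n}
#' with `s` the chirality (winding handedness), `N` the element count and
#' `r_n` the element-to-focus distance. Order 0 is a plain focus; higher
#' orders produce a vortex with a low-intensity core whose radius grows
#' with the order.
#'
#' @param geometry An [build_circular_array()] geometry.
#' @param order Angular order (helicity) m, non-negative integer.
#' @param chirality +1 or -1 winding direction.
#' @param focus Focal point, length-2 (m).
#' @param amplitude Uniform element amplitude.
#' @return A [drive_state()].
#' @export
bessel_drive <- function(geometry, order = 0, chirality = 1,
                         focus = c(0, 0), amplitude = 1) {
  stopifnot(inherits(geometry, "array_geometry"))
  if (order < 0 || order != round(order)) stop("order must be a non-negative integer",
                                               call. = FALSE)
  if (!chirality %in% c(-1, 1)) stop("chirality must be +1 or -1", call. = FALSE)
  if (!inside_chamber(geometry, focus)) {
    stop("focus outside chamber", call. = FALSE)
  }
  n <- geometry$n_elements
  r_n <- sqrt(colSums((t(geometry$element_positions) - focus)^2))
  # focusing term +k*r_n: pre-advances each element so all arrivals are in
  # phase at the focus under the e^{-ikr} outgoing-wave convention (with
  # the opposite time convention the same law is written with -k*r_n)
  phi <- chirality * 2 * order * pi * (seq_len(n) - 1) / n + geometry$k * r_n
  drive_state(rep(amplitude, n), phi,
              label = sprintf("bessel m=%d chi=%+d", order, chirality))
}

#' Twin-trap drive state
#'
#' A twin trap is the sum of a focusing field and a cancellation field:
#' all elements are focused at the trap point (order-0 phase law) and the
#' elements on one side of a cancellation axis through the focus are
#' phase-inverted by pi. The two halves cancel on the axis, leaving a
#' low-pressure trapping centre flanked by two high-pressure lobes.
#' Elements lying on the axis (within half the element angular pitch of
#' either axis-circle intersection) are switched off.
#'
#' @param geometry An [build_circular_array()] geometry.
#' @param focus Trap centre, length-2 (m).
#' @param axis_angle Orientation of the cancellation axis (radians); the
#'   two pressure lobes lie perpendicular to it.
#' @param amplitude Uniform element amplitude for the active elements.
#' @return A [drive_state()].
#' @export
twin_trap_drive <- function(geometry, focus = c(0, 0), axis_angle = 0,
                            amplitude = 1) {
  stopifnot(inherits(geometry, "array_geometry"))
  if (!inside_chamber(geometry, focus)) {
    stop("focus outside chamber", call. = FALSE)
  }
  base <- bessel_drive(geometry, order = 0, focus = focus,
                       amplitude = amplitude)
  u <- c(cos(axis_angle), sin(axis_angle))
  rel <- sweep(geometry$element_positions, 2, focus)
  # signed perpendicular offset from the cancellation axis
  side <- rel[, 2] * u[1] - rel[, 1] * u[2]
  phi <- base$phases + ifelse(side > 0, pi, 0)
  # axis-circle intersections: |focus + t u| = R
  b <- sum(focus * u)
  disc <- b^2 - (sum(focus^2) - geometry$chamber_radius^2)
  t_hit <- c(-b + sqrt(disc), -b - sqrt(disc))
  hit_ang <- atan2(focus[2] + t_hit * u[2], focus[1] + t_hit * u[1])
  pitch <- 2 * pi / geometry$n_elements
  on_axis <- rep(FALSE, geometry$n_elements)
  for (a in hit_ang) {
    on_axis <- on_axis |
      abs(wrap_phase(geometry$element_angles - a)) < pitch / 2
  }
  amp <- ifelse(on_axis, 0, amplitude)
  drive_state(amp, phi, label = sprintf("twin trap (%.2f, %.2f) mm",
                                        focus[1] * 1e3, focus[2] * 1e3))
}

#' Standing-wave (conveyor) drive state
#'
#' Activates two opposing sub-apertures of the ring which emit
#' counter-propagating plane waves along `axis_angle`, forming a standing
#' wave across the chamber. Each active element carries a curvature
#' correction `k * r_sw`, with `r_sw` its distance to the wavefront plane
#' through the centre, so the emitted wave is plane at the chamber. A loop
#' of three such states, stepped by a phase offset of 2*pi/3 added on one
#' side and subtracted on the other, translates the node lattice by one
#' sixth of a wavelength per step and acts as a particle conveyor belt.
#'
#' @param geometry An [build_circular_array()] geometry.
#' @param aperture_half_count Elements in each of the two sub-apertures.
#' @param axis_angle Propagation axis (radians).
#' @param step_index Conveyor step, taken modulo 3.
#' @param offset_sign +1 or -1; flips the transport direction.
#' @param amplitude Uniform amplitude on the active elements.
#' @return A [drive_state()].
#' @export
standing_wave_drive <- function(geometry, aperture_half_count = 11,
                                axis_angle = 0, step_index = 0,
                                offset_sign = 1, amplitude = 1) {
  stopifnot(inherits(geometry, "array_geometry"))
  n <- geometry$n_elements
  if (aperture_half_count < 1 || aperture_half_count > n / 2) {
    stop("invalid aperture: aperture_half_count must be in [1, N/2]",
         call. = FALSE)
  }
  if (!offset_sign %in% c(-1, 1)) stop("offset_sign must be +1 or -1",
                                       call. = FALSE)
  step <- step_index %% 3
  u <- c(cos(axis_angle), sin(axis_angle))
  along <- geometry$element_positions %*% u  # signed position along axis
  # side A (behind the centre, emits towards +u), side B opposite
  ang_dist_a <- abs(wrap_phase(geometry$element_angles - (axis_angle + pi)))
  ang_dist_b <- abs(wrap_phase(geometry$element_angles - axis_angle))
  side_a <- order(ang_dist_a)[seq_len(aperture_half_count)]
  side_b <- order(ang_dist_b)[seq_len(aperture_half_count)]
  amp <- numeric(n)
  amp[c(side_a, side_b)] <- amplitude
  phi <- geometry$k * abs(along)  # plane-wave curvature correction
  phi[side_a] <- phi[side_a] + offset_sign * step * 2 * pi / 3
  phi[side_b] <- phi[side_b] - offset_sign * step * 2 * pi / 3
  drive_state(amp, phi,
              label = sprintf("standing wave step %d axis %.2f", step,
                              axis_angle))
}

#' Linear combination of drive states
#'
#' Complex superposition of two drives: the element-wise sum of their
#' complex source terms. Useful for composing fields before synthesis.
#'
#' @param d1,d2 [drive_state()] objects of equal length.
#' @param w1,w2 Complex or real weights.
#' @return A [drive_state()].
#' @export
combine_drives <- function(d1, d2, w1 = 1, w2 = 1) {
  z <- w1 * drive_complex(d1) + w2 * drive_complex(d2)
  drive_state(Mod(z), Arg(z), label = paste(d1$label, "+", d2$label))
}
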