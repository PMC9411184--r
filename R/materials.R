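#' Acoustic propagation medium
#'
#' Bundle of host-fluid material constants. Compressibility is derived as
#' \eqn{\kappa_0 = 1/(\rho_0 c_0^2)}. Defaults describe water at 25 C,
#' the host fluid of the reference device.
#'
#' @param c0 Speed of sound (m/s).
#' @param rho0 Density (kg/m^3).
#' @param mu0 Dynamic viscosity (Pa s).
#' @return An object of class `medium` with fields `c0`, `rho0`, `mu0`
#'   and the derived compressibility `kappa0` (1/Pa).
#' @examples
#' m <- medium()
#' m$kappa0 * m$rho0 * m$c0^2  # == 1
#' @export
medium <- function(c0 = 1500, rho0 = 997, mu0 = 0.89e-3) {
  if (!all(is.finite(c(c0, rho0, mu0))) || any(c(c0, rho0, mu0) <= 0)) {
    stop("medium constants must be finite and positive", call. = FALSE)
  }
  structure(
    list(c0 = c0, rho0 = rho0, mu0 = mu0, kappa0 = 1 / (rho0 * c0^2)),
    class = "medium"
  )
}

#' Particle material properties
#'
#' Small-sphere material bundle used by the Gor'kov model. The
#' compressibility \eqn{\kappa_p = 1/(\rho_p c_p^2)} and the monopole and
#' dipole contrast factors
#' \eqn{f_1 = 1 - \kappa_p/\kappa_0} and
#' \eqn{f_2 = 2(\rho_p - \rho_0)/(2\rho_p + \rho_0)}
#' are derived against the bound `medium`. Defaults describe a 90 um
#' diameter polystyrene sphere in water (positive acoustic contrast, so
#' particles migrate to pressure nodes).
#'
#' @param radius Particle radius r_p (m). Default 45e-6 (90 um diameter).
#' @param density Particle density rho_p (kg/m^3).
#' @param sound_speed Compressional sound speed in the particle c_p (m/s).
#' @param med A [medium()] the contrast factors are computed against.
#' @return Object of class `particle_material` with fields `radius`,
#'   `density`, `sound_speed`, `kappa_p`, `f1`, `f2` and the bound `medium`.
#' @export
particle_material <- function(radius = 45e-6, density = 1050,
                              sound_speed = 2047, med = medium()) {
  stopifnot(inherits(med, "medium"))
  if (any(c(radius, density, sound_speed) <= 0)) {
    stop("particle material constants must be positive", call. = FALSE)
  }
  kappa_p <- 1 / (density * sound_speed^2)
  structure(
    list(
      radius = radius, density = density, sound_speed = sound_speed,
      kappa_p = kappa_p,
      f1 = 1 - kappa_p / med$kappa0,
      f2 = 2 * (density - med$rho0) / (2 * density + med$rho0),
      medium = med
    ),
    class = "particle_material"
  )
}

#' Virtual (entrained-flow) mass of a particle
#'
#' \eqn{m_v = \frac{4}{3}\pi r_p^3 (\rho_p + \rho_0/2)}: the sphere mass
#' augmented by half the displaced fluid mass, accounting for the fluid
#' entrained by an accelerating particle.
#'
#' @param mat A [particle_material()].
#' @param med A [medium()]; defaults to the one bound to `mat`.
#' @return Mass in kg.
#' @export
virtual_mass <- function(mat, med = mat$medium) {
  stopifnot(inherits(mat, "particle_material"), inherits(med, "medium"))
  (4 / 3) * pi * mat$radius^3 * (mat$density + med$rho0 / 2)
}

#' Viscous relaxation time of a particle
#'
#' \eqn{\tau = m_v / (6\pi\mu_0 r_p)}: the time scale over which the
#' particle velocity equilibrates with the Stokes drag. Used to pick a
#' stable integration time step.
#'
#' @inheritParams virtual_mass
#' @return Time in seconds.
#' @export
viscous_relaxation_time <- function(mat, med = mat$medium) {
  virtual_mass(mat, med) / (6 * pi * med$mu0 * mat$radius)
}
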