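# Finite-difference gradient of a (ny x nx) matrix sampled on a uniform
# grid: central differences in the interior, one-sided at the borders.
grad_x <- function(m, dx) {
  nx <- ncol(m)
  g <- m
  if (nx < 2) return(g * 0)
  g[, 2:(nx - 1)] <- (m[, 3:nx] - m[, 1:(nx - 2)]) / (2 * dx)
  g[, 1] <- (m[, 2] - m[, 1]) / dx
  g[, nx] <- (m[, nx] - m[, nx - 1]) / dx
  g
}

grad_y <- function(m, dy) {
  ny <- nrow(m)
  g <- m
  if (ny < 2) return(g * 0)
  g[2:(ny - 1), ] <- (m[3:ny, ] - m[1:(ny - 2), ]) / (2 * dy)
  g[1, ] <- (m[2, ] - m[1, ]) / dy
  g[ny, ] <- (m[ny, ] - m[ny - 1, ]) / dy
  g
}

#' First-order acoustic particle velocity of a field
#'
#' Linearized momentum balance closure: for a time-harmonic complex
#' pressure amplitude the acoustic velocity amplitude is
#' \eqn{v = \nabla p / (-i \omega \rho_0)}, evaluated here with central
#' differences on the field grid. Only its magnitude enters the Gor'kov
#' potential through \eqn{\langle v^2\rangle = |v|^2/2}.
#'
#' @param field A [synthesize_pressure()] result.
#' @param med Host [medium()]; defaults to the one bound to the geometry.
#' @return List with complex matrices `vx`, `vy` (m/s) on the field grid.
#' @export
acoustic_velocity <- function(field, med = field$geometry$medium) {
  stopifnot(inherits(field, "pressure_field"))
  omega <- 2 * pi * field$geometry$frequency
  fac <- 1 / (-1i * omega * med$rho0)
  list(vx = fac * grad_x(field$p, field$spacing),
       vy = fac * grad_y(field$p, field$spacing))
}

#' Gor'kov potential of a small particle in a pressure field
#'
#' For a particle small relative to the wavelength,
#' \deqn{U = \frac{4 r_p^3}{3}\left[ f_1 \frac{1}{2}\kappa_0
#'   \langle p^2\rangle - f_2 \frac{3}{4}\rho_0 \langle v^2\rangle\right]}
#' with time averages \eqn{\langle p^2\rangle = |p|^2/2} and
#' \eqn{\langle v^2\rangle = |v|^2/2} of the complex amplitudes. The
#' leading factor is `4 r_p^3 / 3` by default; set
#' `conventional_prefactor = TRUE` for the `4*pi*r_p^3/3` variant. The
#' absolute scale is irrelevant for patterning runs, which normalize the
#' force amplitude downstream.
#'
#' @param field A [synthesize_pressure()] result.
#' @param mat A [particle_material()].
#' @param med Host [medium()].
#' @param conventional_prefactor Use `4*pi*r^3/3` instead of `4*r^3/3`.
#' @return Matrix of potential values (J) on the field grid.
#' @export
gorkov_potential <- function(field, mat, med = mat$medium,
                             conventional_prefactor = FALSE) {
  stopifnot(inherits(field, "pressure_field"),
            inherits(mat, "particle_material"))
  lam <- field$geometry$wavelength
  if (mat$radius > lam / 10) {
    warning("particle radius exceeds lambda/10; small-particle model is marginal")
  }
  v <- acoustic_velocity(field, med)
  msp <- Mod(field$p)^2 / 2
  msv <- (Mod(v$vx)^2 + Mod(v$vy)^2) / 2
  pref <- if (conventional_prefactor) 4 * pi * mat$radius^3 / 3 else
    4 * mat$radius^3 / 3
  pref * (mat$f1 * 0.5 * med$kappa0 * msp - mat$f2 * 0.75 * med$rho0 * msv)
}

#' Acoustic radiation force field from a potential
#'
#' \eqn{F_{ac} = -\nabla U}, by central differences (one-sided at grid
#' borders).
#'
#' @param potential Matrix of Gor'kov potential values, or a
#'   `pressure_field` (in which case `mat` is required and the potential
#'   is computed first).
#' @param grid The [field_grid()] the potential is sampled on (ignored if
#'   `potential` is a `pressure_field`).
#' @param mat A [particle_material()], when `potential` is a field.
#' @param ... Passed on to [gorkov_potential()].
#' @return Object of class `force_grid`: coordinates `x`, `y`, matrices
#'   `fx`, `fy` (N) and `potential` (J).
#' @export
radiation_force <- function(potential, grid = NULL, mat = NULL, ...) {
  if (inherits(potential, "pressure_field")) {
    field <- potential
    if (is.null(mat)) stop("mat is required to evaluate the potential",
                           call. = FALSE)
    u <- gorkov_potential(field, mat, ...)
    x <- field$x; y <- field$y; h <- field$spacing
  } else {
    stopifnot(inherits(grid, "field_grid_spec"))
    u <- potential
    x <- grid$x; y <- grid$y; h <- grid$spacing
  }
  structure(
    list(x = x, y = y, spacing = h,
         fx = -grad_x(u, h), fy = -grad_y(u, h), potential = u),
    class = "force_grid"
  )
}

#' Rescale a force field to a maximum force magnitude
#'
#' Multiplies the force (and potential) by a single scalar so the maximum
#' force magnitude over the grid equals `f_max`. Patterning simulations
#' use 10 nN. Idempotent and invariant to the input scale.
#'
#' @param fg A [radiation_force()] grid.
#' @param f_max Target maximum force magnitude (N). Default 1e-8 (10 nN).
#' @param within_radius Only nodes within this radius of the array centre
#'   define the maximum (default all). Used for grids that graze the
#'   transducer ring, where the singular 1/sqrt(r) near field would
#'   otherwise dominate the normalization.
#' @return The rescaled `force_grid`.
#' @export
normalize_force <- function(fg, f_max = 1e-8, within_radius = Inf) {
  stopifnot(inherits(fg, "force_grid"))
  m2 <- fg$fx^2 + fg$fy^2
  if (is.finite(within_radius)) {
    rr <- outer(fg$y^2, fg$x^2, `+`)
    m2 <- m2[rr <= within_radius^2]
    if (length(m2) == 0) stop("no grid nodes within the normalization radius",
                              call. = FALSE)
  }
  peak <- sqrt(max(m2))
  if (peak == 0) stop("cannot normalize an all-zero force field", call. = FALSE)
  s <- f_max / peak
  fg$fx <- fg$fx * s
  fg$fy <- fg$fy * s
  fg$potential <- fg$potential * s
  fg
}

#' Quasi-steady drag force on a moving particle
#'
#' Sphere drag with finite-Reynolds correction,
#' \eqn{|F_d| = \tfrac{1}{2}\rho_0 \pi r_p^2 C_d |\dot x|^2},
#' \eqn{C_d = (24/Re)(1 + \tfrac{3}{16}|Re|)^{1/2}},
#' \eqn{Re = 2 r_p \rho_0 |\dot x| / \mu_0},
#' directed against the velocity. As `Re -> 0` this reduces to the Stokes
#' drag `6*pi*mu*r*v`. Returns the opposing force vector (its dot product
#' with the velocity is never positive); `v = 0` gives zero drag.
#'
#' @param velocity Length-2 velocity (m/s), or an `n x 2` matrix.
#' @param mat A [particle_material()].
#' @param med Host [medium()].
#' @return Drag force (N), same shape as `velocity`.
#' @export
drag_force <- function(velocity, mat, med = mat$medium) {
  v <- if (is.matrix(velocity)) velocity else matrix(velocity, ncol = 2)
  speed <- sqrt(rowSums(v^2))
  re <- 2 * mat$radius * med$rho0 * speed / med$mu0
  # 1/2 rho pi r^2 Cd v^2 == 6 pi mu r v sqrt(1 + 3 Re/16)
  coef <- -6 * pi * med$mu0 * mat$radius * sqrt(1 + 3 * re / 16)
  out <- v * coef
  if (is.matrix(velocity)) out else as.vector(out)
}

# Bilinear interpolation of a force grid at arbitrary positions
# (n x 2 matrix). Positions outside the grid use the nearest edge value
# unless outside_zero is TRUE, in which case the force is zero there.
force_at <- function(fg, positions, outside_zero = FALSE) {
  p <- if (is.matrix(positions)) positions else matrix(positions, ncol = 2)
  nx <- length(fg$x); ny <- length(fg$y)
  fx <- numeric(nrow(p)); fy <- numeric(nrow(p))
  gx <- (p[, 1] - fg$x[1]) / fg$spacing
  gy <- (p[, 2] - fg$y[1]) / fg$spacing
  out <- gx < 0 | gx > nx - 1 | gy < 0 | gy > ny - 1
  cgx <- pmin(pmax(gx, 0), nx - 1 - 1e-9)
  cgy <- pmin(pmax(gy, 0), ny - 1 - 1e-9)
  i0 <- floor(cgx); j0 <- floor(cgy)
  tx <- cgx - i0; ty <- cgy - j0
  idx <- function(j, i) j + 1 + i * ny  # column-major (ny x nx)
  w00 <- (1 - tx) * (1 - ty); w10 <- tx * (1 - ty)
  w01 <- (1 - tx) * ty;       w11 <- tx * ty
  fxv <- as.vector(fg$fx); fyv <- as.vector(fg$fy)
  fx <- w00 * fxv[idx(j0, i0)] + w10 * fxv[idx(j0, i0 + 1)] +
        w01 * fxv[idx(j0 + 1, i0)] + w11 * fxv[idx(j0 + 1, i0 + 1)]
  fy <- w00 * fyv[idx(j0, i0)] + w10 * fyv[idx(j0, i0 + 1)] +
        w01 * fyv[idx(j0 + 1, i0)] + w11 * fyv[idx(j0 + 1, i0 + 1)]
  if (outside_zero && any(out)) {
    fx[out] <- 0; fy[out] <- 0
  }
  matrix(c(fx, fy), ncol = 2)
}

#' Default integration time step
#'
#' `dt = min(dwell/20, tau/50)` with `tau` the viscous relaxation time
#' [viscous_relaxation_time()]: small enough that force and velocity are
#' effectively constant over a step, and that each dwell is resolved.
#'
#' @param mat A [particle_material()].
#' @param dwell Smallest dwell time in the schedule (s), or `Inf`.
#' @param med Host [medium()].
#' @return Time step (s).
#' @export
default_dt <- function(mat, dwell = Inf, med = mat$medium) {
  min(dwell / 20, viscous_relaxation_time(mat, med) / 50)
}

#' Advance one particle by one explicit time step
#'
#' Position update
#' \eqn{x_{t+\Delta t} = x_t + \dot x_t \Delta t + F_e \Delta t^2 / m_v}
#' and velocity update \eqn{\dot x_{t+\Delta t} = \dot x_t + F_e \Delta t / m_v},
#' with \eqn{F_e = F_{ac}(x) + F_d(\dot x)} (the drag vector already
#' opposes the motion). The position is clamped to the chamber radius
#' minus the particle radius, with the velocity zeroed at contact.
#' Primarily a readable reference path; ensemble simulations use the
#' compiled integrator.
#'
#' @param position,velocity Length-2 state (m, m/s).
#' @param force_lookup Function mapping a position to a length-2 force (N).
#' @param dt Time step (s); must not exceed one fifth of the viscous
#'   relaxation time (explicit-update stability bound).
#' @param mat A [particle_material()].
#' @param med Host [medium()].
#' @param chamber_radius Clamping radius (m), `Inf` to disable.
#' @param drag Logical; include the drag force.
#' @return List with updated `position` and `velocity`.
#' @export
step_particle <- function(position, velocity, force_lookup, dt, mat,
                          med = mat$medium, chamber_radius = Inf,
                          drag = TRUE) {
  tau <- viscous_relaxation_time(mat, med)
  if (dt > tau / 5) {
    stop(sprintf("dt = %.3g s exceeds the stability bound tau/5 = %.3g s",
                 dt, tau / 5), call. = FALSE)
  }
  m_v <- virtual_mass(mat, med)
  f <- force_lookup(position)
  if (drag) f <- f + drag_force(velocity, mat, med)
  position <- position + velocity * dt + f * dt^2 / m_v
  velocity <- velocity + f * dt / m_v
  r_eff <- chamber_radius - mat$radius
  rr <- sqrt(sum(position^2))
  if (is.finite(r_eff) && rr > r_eff) {
    position <- position * (r_eff / rr)
    velocity <- c(0, 0)
  }
  list(position = position, velocity = velocity)
}

#' Integrate one particle under an arbitrary force function (reference path)
#'
#' Repeatedly applies [step_particle()]. Used for closed-form validation
#' cases and as an independent cross-check of the compiled integrator.
#'
#' @inheritParams step_particle
#' @param n_steps Number of steps.
#' @param record_every Record every k-th step (0 = only final state).
#' @return List with final `position`, `velocity` and, when recording,
#'   a trajectory data.frame (t, x, y, vx, vy).
#' @export
integrate_particle <- function(position, velocity, force_lookup, dt,
                               n_steps, mat, med = mat$medium,
                               chamber_radius = Inf, drag = TRUE,
                               record_every = 0) {
  rec <- NULL
  if (record_every > 0) {
    n_rec <- floor(n_steps / record_every)
    rec <- matrix(NA_real_, n_rec, 5)
  }
  k <- 0
  for (i in seq_len(n_steps)) {
    st <- step_particle(position, velocity, force_lookup, dt, mat, med,
                        chamber_radius, drag)
    position <- st$position
    velocity <- st$velocity
    if (record_every > 0 && i %% record_every == 0) {
      k <- k + 1
      rec[k, ] <- c(i * dt, position, velocity)
    }
  }
  out <- list(position = position, velocity = velocity)
  if (!is.null(rec)) {
    out$trajectory <- data.frame(t = rec[, 1], x = rec[, 2], y = rec[, 3],
                                 vx = rec[, 4], vy = rec[, 5])
  }
  out
}
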