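#' Applied impulse of one switching state
#'
#' The control variable of impulse switching: the maximum acoustic force
#' of a state times its dwell time, `I_app = max(F_ac) * dt_s`. 10 nN
#' held for 1 ms gives 1e-11 N s = 10 pN s.
#'
#' @param f_max Maximum force of the state (N), >= 0.
#' @param dt_s Dwell (switching) time (s), > 0.
#' @return Impulse (N s).
#' @export
applied_impulse <- function(f_max, dt_s) {
  if (any(f_max < 0)) stop("f_max must be non-negative", call. = FALSE)
  if (any(dt_s <= 0)) stop("dt_s must be positive", call. = FALSE)
  f_max * dt_s
}

#' Impulse exerted on a particle over one dwell
#'
#' Time integral of the acoustic force along a recorded trajectory,
#' \eqn{I_q = \int_0^{\Delta t_q} F_{ac,q}(x(t)) dt}, evaluated by the
#' trapezoidal rule on the trajectory samples.
#'
#' @param trajectory Data frame with columns `t`, `x`, `y` (SI units),
#'   covering at least `[0, dwell]` (a leading `t = 0` sample is assumed
#'   to be present or is added from the first row).
#' @param force_lookup Function mapping an `n x 2` position matrix to an
#'   `n x 2` force matrix, e.g. built from a force grid via [force_at()].
#' @param dwell Dwell time (s).
#' @return Length-2 impulse vector (N s).
#' @export
exerted_impulse <- function(trajectory, force_lookup, dwell) {
  tt <- trajectory$t
  if (max(tt) < dwell) {
    stop("trajectory does not cover the dwell", call. = FALSE)
  }
  keep <- tt <= dwell + 1e-15
  tt <- tt[keep]
  pos <- cbind(trajectory$x[keep], trajectory$y[keep])
  if (tt[length(tt)] < dwell) {        # append endpoint by interpolation
    i <- length(tt)
    j <- which(trajectory$t > dwell)[1]
    w <- (dwell - tt[i]) / (trajectory$t[j] - tt[i])
    pos <- rbind(pos, (1 - w) * pos[i, ] +
                   w * c(trajectory$x[j], trajectory$y[j]))
    tt <- c(tt, dwell)
  }
  f <- force_lookup(pos)
  dt <- diff(tt)
  c(sum(dt * (f[-nrow(f), 1] + f[-1, 1]) / 2),
    sum(dt * (f[-nrow(f), 2] + f[-1, 2]) / 2))
}

#' Switching schedule
#'
#' Ordered sequence of drive states (or precomputed force grids) with
#' dwell times, cycled during a switched simulation.
#'
#' @param states List of [drive_state()] objects or `force_grid`s.
#' @param dwell Dwell time(s) (s), recycled over the states.
#' @param label Schedule tag.
#' @return Object of class `switching_schedule`.
#' @export
switching_schedule <- function(states, dwell, label = "") {
  if (!is.list(states) || (length(states) &&
      !all(vapply(states, inherits, TRUE, c("drive_state")) |
           vapply(states, inherits, TRUE, c("force_grid"))))) {
    stop("states must be a list of drive_state or force_grid objects",
         call. = FALSE)
  }
  if (length(states) == 0) {
    return(structure(list(states = list(), dwell = numeric(0), label = label),
                     class = "switching_schedule"))
  }
  dwell <- rep_len(dwell, length(states))
  if (any(dwell <= 0)) stop("all dwells must be positive", call. = FALSE)
  structure(
    list(states = states, dwell = dwell[seq_along(states)], label = label),
    class = "switching_schedule"
  )
}

#' @export
print.switching_schedule <- function(x, ...) {
  cat(sprintf("switching schedule '%s': %d states, period %.3g s\n",
              x$label, length(x$states), sum(x$dwell)))
  invisible(x)
}

#' Compile a schedule into normalized force grids
#'
#' Synthesizes the pressure field of every drive state on the grid,
#' evaluates the Gor'kov radiation force for the given particle material
#' and rescales each state to the same maximum force `f_max` (the
#' simulation convention standing in for per-state source calibration).
#' States that already are `force_grid`s pass through unchanged.
#'
#' A switching period much longer than the acoustic period is assumed by
#' the time-averaged force model; a warning is issued if any dwell is
#' shorter than 100 acoustic periods.
#'
#' @param schedule A [switching_schedule()].
#' @param geometry An [build_circular_array()] geometry.
#' @param grid A [field_grid()] spec.
#' @param mat A [particle_material()].
#' @param f_max Per-state maximum force (N).
#' @param h Optional precomputed [transfer_matrix()] for `grid`.
#' @param norm_radius Normalization radius passed to [normalize_force()];
#'   defaults to 0.3 mm inside the transducer ring, keeping the singular
#'   near field out of the normalization on full-chamber grids.
#' @return A `compiled_schedule`: list of `force_grid`s plus dwells.
#' @export
compile_schedule <- function(schedule, geometry, grid, mat,
                             f_max = 1e-8, h = NULL,
                             norm_radius = geometry$chamber_radius - 0.3e-3) {
  stopifnot(inherits(schedule, "switching_schedule"))
  if (length(schedule$states) == 0) {
    return(structure(list(forces = list(), dwell = numeric(0),
                          label = schedule$label),
                     class = "compiled_schedule"))
  }
  if (any(schedule$dwell < 100 / geometry$frequency)) {
    warning("dwell is shorter than 100 acoustic periods; the time-averaged force model assumes switching far slower than the acoustic oscillation")
  }
  need_h <- any(vapply(schedule$states, inherits, TRUE, "drive_state"))
  if (need_h && is.null(h)) h <- transfer_matrix(geometry, grid)
  forces <- lapply(schedule$states, function(st) {
    if (inherits(st, "force_grid")) return(st)
    field <- synthesize_pressure(h, st)
    normalize_force(radiation_force(field, mat = mat), f_max,
                    within_radius = norm_radius)
  })
  structure(list(forces = forces, dwell = schedule$dwell,
                 label = schedule$label),
            class = "compiled_schedule")
}

#' Dwell-weighted mean (summed) force field
#'
#' The effective force field experienced in the low impulse regime:
#' \deqn{F_{sum} = \frac{\sum_q F_{ac,q} \Delta t_q}{\sum_q \Delta t_q}}
#' With equal dwells this is the plain mean of the state force fields.
#' Invariant to cyclic rotation of the schedule and to splitting a state
#' into consecutive half-dwell copies.
#'
#' @param compiled A [compile_schedule()] result (or a list of congruent
#'   `force_grid`s, in which case `dwell` must be given).
#' @param dwell Dwell weights when `compiled` is a plain list.
#' @return A `force_grid`.
#' @export
summed_field <- function(compiled, dwell = NULL) {
  if (inherits(compiled, "compiled_schedule")) {
    forces <- compiled$forces
    dwell <- compiled$dwell
  } else {
    forces <- compiled
  }
  if (length(forces) == 0) stop("empty schedule has no summed field",
                                call. = FALSE)
  ref <- forces[[1]]
  for (fg in forces[-1]) {
    if (!identical(dim(fg$fx), dim(ref$fx)) ||
        abs(fg$x[1] - ref$x[1]) > 1e-12 || abs(fg$y[1] - ref$y[1]) > 1e-12) {
      stop("force grids are not congruent", call. = FALSE)
    }
  }
  w <- dwell / sum(dwell)
  out <- ref
  out$fx <- Reduce(`+`, Map(function(fg, wi) fg$fx * wi, forces, w))
  out$fy <- Reduce(`+`, Map(function(fg, wi) fg$fy * wi, forces, w))
  out$potential <- Reduce(`+`, Map(function(fg, wi) fg$potential * wi,
                                   forces, w))
  out
}

#' Simulate an ensemble under a switched schedule
#'
#' Integrates every particle with the active state's force field, cycling
#' the states with their dwell times, using the compiled time-domain
#' integrator (explicit update with drag and virtual mass; positions
#' clamped to the chamber radius minus the particle radius with velocity
#' zeroed at contact).
#'
#' @param ensemble An [random_ensemble()] (or any list with `positions`,
#'   `velocities`, `material`, `chamber_radius`).
#' @param compiled A [compile_schedule()] result whose force grids share
#'   one grid geometry.
#' @param duration Simulated time (s).
#' @param dt Time step (s); default [default_dt()] of the material and
#'   the smallest dwell.
#' @param record_every Record positions every k-th step (0 = none).
#' @param outside_zero Treat positions outside the force grid as
#'   force-free instead of using the nearest edge value (used for
#'   localized sub-grid stages).
#' @return The ensemble with updated positions/velocities; when recording,
#'   `$trajectory` holds `t` (vector) and `x`, `y` (time x particle
#'   matrices).
#' @export
simulate_switched <- function(ensemble, compiled, duration, dt = NULL,
                              record_every = 0, outside_zero = FALSE) {
  stopifnot(inherits(compiled, "compiled_schedule"))
  n <- nrow(ensemble$positions)
  if (n == 0 || length(compiled$forces) == 0) {
    if (record_every > 0) ensemble$trajectory <- list(
      t = numeric(0), x = matrix(0, 0, n), y = matrix(0, 0, n))
    return(ensemble)
  }
  mat <- ensemble$material
  med <- mat$medium
  if (is.null(dt)) dt <- default_dt(mat, min(compiled$dwell))
  tau <- viscous_relaxation_time(mat, med)
  if (dt > tau / 5) {
    stop(sprintf("dt = %.3g s exceeds the stability bound tau/5 = %.3g s",
                 dt, tau / 5), call. = FALSE)
  }
  ref <- compiled$forces[[1]]
  res <- cpp_simulate_schedule(
    ensemble$positions, ensemble$velocities,
    lapply(compiled$forces, `[[`, "fx"),
    lapply(compiled$forces, `[[`, "fy"),
    ref$x[1], ref$y[1], ref$spacing, length(ref$x), length(ref$y),
    seq_along(compiled$forces) - 1L, compiled$dwell,
    duration, dt,
    virtual_mass(mat, med), 6 * pi * med$mu0 * mat$radius,
    (3 / 16) * 2 * mat$radius * med$rho0 / med$mu0,
    ensemble$chamber_radius - mat$radius, outside_zero,
    as.integer(record_every)
  )
  ensemble$positions <- res$pos
  ensemble$velocities <- res$vel
  if (record_every > 0) {
    ensemble$trajectory <- list(t = res$t, x = res$traj_x, y = res$traj_y)
  }
  ensemble
}

#' Motion per switching cycle of a recorded 1D trajectory
#'
#' Range (max minus min) of the position over each full schedule cycle,
#' averaged over the measurement window after discarding the settling
#' fraction. A static particle gives 0; a pure two-state oscillation of
#' amplitude d gives d.
#'
#' @param t Sample times (s).
#' @param x Sampled positions along the motion axis (m).
#' @param cycle_period Full schedule period (s).
#' @param settle_frac Leading fraction of the record to discard.
#' @return Mean per-cycle position range (m).
#' @export
motion_per_cycle <- function(t, x, cycle_period, settle_frac = 0.2) {
  keep <- t > settle_frac * max(t)
  t <- t[keep]; x <- x[keep]
  cyc <- floor((t - t[1]) / cycle_period)
  if (max(cyc) > 0) {  # drop the trailing incomplete cycle
    full <- cyc < max(cyc)
    x <- x[full]; cyc <- cyc[full]
  }
  rng <- tapply(x, cyc, function(z) diff(range(z)))
  mean(rng)
}

#' One point of the 1D two-state impulse bench
#'
#' Ideal standing-wave bench: two 1D force fields
#' `F_q(x) = -f_max * sin(2k (x - s_q))` whose stable equilibria are
#' separated by `pattern_shift` (default lambda/8, the node shift of two
#' ideal counter-propagating-source standing waves a quarter period out
#' of phase). The particle starts at the first state's equilibrium and
#' the two states alternate with equal dwell `dt_s` for `n_cycles`
#' cycles; the per-cycle motion is measured after settling.
#'
#' @param f_max State maximum force (N).
#' @param dt_s Switching (dwell) time per state (s).
#' @param geometry Array geometry (supplies the wavelength).
#' @param mat A [particle_material()].
#' @param pattern_shift Equilibria separation d (m).
#' @param n_cycles Number of full switching cycles simulated.
#' @param settle_frac Fraction of the record discarded before measuring.
#' @return List: `motion` (m), `separation` d (m), `i_app` (N s),
#'   `f_max`, `dt_s`, `regime` label.
#' @export
two_state_bench <- function(f_max, dt_s, geometry = build_circular_array(),
                            mat = particle_material(),
                            pattern_shift = geometry$wavelength / 8,
                            n_cycles = 100, settle_frac = 0.2) {
  med <- mat$medium
  kk <- 2 * geometry$k
  dt <- default_dt(mat, dt_s)
  n_steps <- 2 * n_cycles * round(dt_s / dt)
  rec_every <- max(1L, as.integer(floor(n_steps / 50000)))
  res <- cpp_simulate_two_state_1d(
    0, 0, f_max, 0, pattern_shift, kk, dt_s, n_cycles, dt,
    virtual_mass(mat, med), 6 * pi * med$mu0 * mat$radius,
    (3 / 16) * 2 * mat$radius * med$rho0 / med$mu0, rec_every
  )
  motion <- motion_per_cycle(res$t_rec, res$x_rec, 2 * dt_s, settle_frac)
  list(motion = motion, separation = pattern_shift,
       i_app = applied_impulse(f_max, dt_s), f_max = f_max, dt_s = dt_s,
       regime = classify_regime(motion, pattern_shift))
}

#' Classify the switching regime from the per-cycle motion
#'
#' Low: the particle stays at the summed-field equilibrium (motion below
#' `low_frac` of the two-state equilibria separation). High: it reaches
#' both state equilibria every cycle (motion above `high_frac` of the
#' separation). Anything between is the intermediate regime.
#'
#' @param motion Per-cycle motion (m).
#' @param separation Equilibria separation d (m).
#' @param low_frac,high_frac Classification thresholds (fractions of d).
#' @return One of "low", "intermediate", "high".
#' @export
classify_regime <- function(motion, separation, low_frac = 0.05,
                            high_frac = 0.95) {
  ifelse(motion < low_frac * separation, "low",
         ifelse(motion > high_frac * separation, "high", "intermediate"))
}

#' Sweep the applied impulse on the 1D two-state bench
#'
#' Runs [two_state_bench()] over all combinations of `f_max` and `dt_s`
#' and reports motion per cycle, applied impulse and regime label,
#' sorted by applied impulse. Curves for different `f_max` values plotted
#' against `i_app` collapse onto one another: the impulse is the
#' controlling variable.
#'
#' @param f_max_values Maximum forces (N).
#' @param dt_s_values Switching times (s).
#' @param ... Passed to [two_state_bench()].
#' @return data.frame with columns f_max, dt_s, i_app, motion,
#'   separation, regime.
#' @export
regime_sweep <- function(f_max_values = c(7.1e-9, 1e-8, 1.41e-8),
                         dt_s_values = 10^seq(-4, -1, length.out = 13),
                         ...) {
  grid <- expand.grid(f_max = f_max_values, dt_s = dt_s_values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    b <- two_state_bench(grid$f_max[i], grid$dt_s[i], ...)
    data.frame(f_max = b$f_max, dt_s = b$dt_s, i_app = b$i_app,
               motion = b$motion, separation = b$separation,
               regime = b$regime)
  })
  out <- do.call(rbind, rows)
  out[order(out$i_app), ]
}
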