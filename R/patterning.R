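#' Impulse setting for a named regime
#'
#' Simulation (F_max, dwell) pairs realizing the three switching regimes
#' for the default 90 um polystyrene particle, whose viscous response
#' time to a 10 nN trap is a few milliseconds: low = 1 ms dwells (the
#' particle feels the time-averaged field), intermediate = 8 ms (it moves
#' toward but does not reach each state's equilibrium), high = 40 ms (it
#' settles in every state).
#'
#' @param regime "low", "intermediate" or "high".
#' @param f_max Maximum per-state force (N).
#' @return List with `f_max`, `dwell` (s), `regime`, `i_app`.
#' @export
impulse_setting <- function(regime = c("low", "intermediate", "high"),
                            f_max = 1e-8) {
  regime <- match.arg(regime)
  dwell <- switch(regime, low = 1e-3, intermediate = 8e-3, high = 40e-3)
  list(f_max = f_max, dwell = dwell, regime = regime,
       i_app = applied_impulse(f_max, dwell))
}

#' Map an experimental drive voltage to a simulation force ceiling
#'
#' Source pressure is proportional to drive voltage and radiation force
#' to pressure squared, so `F = f_ref * (V / v_ref)^2`. The reference is
#' calibrated so the experimental maximum of 20 V maps to the simulation
#' ceiling of 10 nN.
#'
#' @param volts Drive voltage (V).
#' @param v_ref Reference voltage (V).
#' @param f_ref Force at the reference voltage (N).
#' @return Force (N).
#' @export
voltage_to_force <- function(volts, v_ref = 20, f_ref = 1e-8) {
  f_ref * (volts / v_ref)^2
}

#' Number of twin traps for a line
#'
#' Trap-count rule `N_TT = round(3 L / lambda) + 1` (nearest-integer
#' rounding), which keeps the equally-distributed trap spacing at or
#' below lambda/3, the maximum spacing for clean line formation. A 2 mm
#' line at lambda = 0.644 mm takes 10 traps; 1.5 mm takes 8.
#'
#' @param line_length Line length (m), >= 0.
#' @param wavelength Operating wavelength (m).
#' @return Integer trap count (>= 1).
#' @export
n_twin_traps <- function(line_length, wavelength) {
  if (any(line_length < 0)) stop("line length must be non-negative",
                                 call. = FALSE)
  as.integer(floor(3 * line_length / wavelength + 0.5)) + 1L
}

#' Line of twin traps
#'
#' Switching schedule of twin traps equally distributed from `start` to
#' `end` (inclusive), with the cancellation axis aligned with the line so
#' the summed field forms a continuous low-force valley along it. Trap
#' count follows [n_twin_traps()]; the spacing therefore never exceeds
#' lambda/3.
#'
#' @param start,end Line endpoints, length-2 (m).
#' @param geometry An [build_circular_array()] geometry.
#' @param dwell Per-state dwell (s); low-impulse default.
#' @param order Trap ordering along the line: +1 start-to-end, -1
#'   end-to-start (the sweep direction of the switching sequence).
#' @return A [switching_schedule()].
#' @export
line_of_twin_traps <- function(start, end, geometry,
                               dwell = impulse_setting("low")$dwell,
                               order = 1) {
  len <- sqrt(sum((end - start)^2))
  n <- n_twin_traps(len, geometry$wavelength)
  if (n == 1) {
    pts <- matrix(start, 1, 2)
  } else {
    tt <- seq(0, 1, length.out = n)
    pts <- cbind(start[1] + tt * (end[1] - start[1]),
                 start[2] + tt * (end[2] - start[2]))
  }
  if (!all(inside_chamber(geometry, pts))) {
    stop("line extends outside the chamber", call. = FALSE)
  }
  axis <- if (len > 0) atan2(end[2] - start[2], end[1] - start[1]) else 0
  idx <- if (order >= 0) seq_len(n) else rev(seq_len(n))
  states <- lapply(idx, function(i) {
    twin_trap_drive(geometry, pts[i, ], axis_angle = axis)
  })
  switching_schedule(states, dwell,
                     label = sprintf("twin-trap line (%d traps)", n))
}

#' Standing-wave conveyor-belt schedule
#'
#' Looped progression of the three standing-wave steps (phase offset
#' 2*pi/3 per step, added on one side of the array and subtracted on the
#' other), applied in the high impulse regime. Each step translates the
#' pressure-node lattice by lambda/6 along the axis, so one full loop
#' carries trapped particles half a wavelength; repeated loops sweep a
#' strip of particles to the edge of the aperture.
#'
#' @param geometry An [build_circular_array()] geometry.
#' @param axis_angle Transport axis (radians).
#' @param aperture_half_count Elements per sub-aperture.
#' @param n_loops Number of 3-step loops (0 gives an empty schedule).
#' @param offset_sign +1 or -1; reverses the transport direction.
#' @param dwell Per-step dwell (s); high-impulse default.
#' @return A [switching_schedule()].
#' @export
conveyor_schedule <- function(geometry, axis_angle = 0,
                              aperture_half_count = 11, n_loops = 1,
                              offset_sign = 1,
                              dwell = impulse_setting("high")$dwell) {
  if (n_loops < 0) stop("n_loops must be non-negative", call. = FALSE)
  states <- list()
  for (l in seq_len(n_loops)) {
    for (s in 0:2) {
      states[[length(states) + 1]] <-
        standing_wave_drive(geometry, aperture_half_count, axis_angle,
                            step_index = s, offset_sign = offset_sign)
    }
  }
  switching_schedule(states, dwell,
                     label = sprintf("conveyor axis %.2f (%d loops)",
                                     axis_angle, n_loops))
}

#' Focused-point sweep schedule
#'
#' Unidirectional raster of order-0 focus states over a rectangular
#' region: points spaced `step` along each line and lines spaced `step`
#' apart, applied in the intermediate impulse regime so each focus pushes
#' nearby particles away without drawing cleared particles back. The
#' default step is 0.1 mm. The sweep direction is constant along every
#' line.
#'
#' @param geometry An [build_circular_array()] geometry.
#' @param region Length-4 rectangle `c(xmin, xmax, ymin, ymax)` (m).
#' @param step Point and line spacing (m).
#' @param direction +1 sweeps +x, -1 sweeps -x (lines advance in +y).
#' @param dwell Per-state dwell (s); intermediate default.
#' @return A [switching_schedule()] (empty for a degenerate region).
#' @export
focus_sweep_schedule <- function(geometry, region, step = 1e-4,
                                 direction = 1,
                                 dwell = impulse_setting("intermediate")$dwell) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  xs <- seq(region[1], region[2], by = step)
  ys <- seq(region[3], region[4], by = step)
  if (region[2] <= region[1] || region[4] <= region[3]) {
    return(switching_schedule(list(), numeric(0), label = "focus sweep (empty)"))
  }
  if (direction < 0) xs <- rev(xs)
  states <- list()
  for (y in ys) {
    for (x in xs) {
      states[[length(states) + 1]] <-
        bessel_drive(geometry, order = 0, focus = c(x, y))
    }
  }
  switching_schedule(states, dwell,
                     label = sprintf("focus sweep %d points", length(states)))
}

#' Bessel-order cycling schedule
#'
#' Ordered sequence of Bessel (vortex) drive states stepping the angular
#' order from `order_from` to `order_to`, applied in the high impulse
#' regime. Increasing cycles (e.g. 9 up to 20) grow the low-intensity
#' core and clear a central disc of particles outward; decreasing cycles
#' shrink it and agglomerate particles inward. When
#' `chirality_alternation` is set the vortex handedness flips between
#' repetitions, which evens out the transport azimuthally.
#'
#' @param geometry An [build_circular_array()] geometry.
#' @param origin Common focus of the cycle (m).
#' @param order_from,order_to First and last angular order (>= 0).
#' @param chirality_alternation Flip handedness each repetition.
#' @param repetitions Number of passes through the order ramp.
#' @param dwell Per-state dwell (s). Default 300 ms: far from the first
#'   ring the normalized field is weak, so particles need long dwells to
#'   track the ring motion (deep in the high impulse regime).
#' @return A [switching_schedule()].
#' @export
bessel_cycle_schedule <- function(geometry, origin = c(0, 0),
                                  order_from = 9, order_to = 20,
                                  chirality_alternation = TRUE,
                                  repetitions = 1,
                                  dwell = 0.3) {
  if (order_from < 0 || order_to < 0) stop("orders must be non-negative",
                                           call. = FALSE)
  orders <- seq(order_from, order_to)
  states <- list()
  chi <- 1
  for (r in seq_len(repetitions)) {
    for (m in orders) {
      states[[length(states) + 1]] <-
        bessel_drive(geometry, order = m, chirality = chi, focus = origin)
    }
    if (chirality_alternation) chi <- -chi
  }
  switching_schedule(states, dwell,
                     label = sprintf("bessel cycle %d->%d x%d", order_from,
                                     order_to, repetitions))
}

#' First-ring radius of an order-m Bessel field
#'
#' Radius of the first intensity maximum of an order-`m` vortex focused
#' at the array centre, `r = (m + 0.8086 m^(1/3)) / k` (the first-maximum
#' location of the Bessel function J_m). The low-intensity core inside it
#' is force-free: Bessel-order cycling transports particles between the
#' first rings of the starting and ending orders and leaves the core
#' untouched.
#'
#' @param geometry An [build_circular_array()] geometry.
#' @param order Angular order m (> 0).
#' @return Radius (m).
#' @export
bessel_ring_radius <- function(geometry, order) {
  (order + 0.8086 * order^(1 / 3)) / geometry$k
}

#' Incremental reshaping of a formed line
#'
#' Builds a low-impulse recipe that morphs a previously formed line by
#' small increments, so the net force field moves slowly enough to carry
#' the particles with it: 0.1 mm per translation step, 5 degrees per
#' rotation step, and arc-radius steps of 0.5 mm (radius 5 to 3 mm),
#' 0.25 mm (3 to 1 mm) and 0.12 mm (below 1 mm). The twin-trap sweep
#' direction alternates between consecutive steps (a constant sweep
#' direction gradually drags the whole pattern along it). The `circle`
#' operation ends with low-impulse switching of a 2nd and 6th order
#' Bessel-shaped field; `split_rotate` rotates the two half-lines about
#' their own centres in opposite senses.
#'
#' @param start,end Current line endpoints (m).
#' @param geometry An [build_circular_array()] geometry.
#' @param operation One of "translate", "rotate", "arc", "circle",
#'   "split_rotate".
#' @param distance Translation distance (m), perpendicular to the line.
#' @param angle Total rotation (radians).
#' @param target_radius Final arc radius (m) for "arc"/"circle".
#' @param step_translate,step_rotate Increment sizes; warnings are issued
#'   if they exceed the fidelity defaults.
#' @param repetitions_per_step Schedule repetitions applied per increment.
#' @return A `recipe` (ordered list of stages).
#' @export
reshape_line <- function(start, end, geometry,
                         operation = c("translate", "rotate", "arc",
                                       "circle", "split_rotate"),
                         distance = 0, angle = 0, target_radius = 1e-3,
                         step_translate = 1e-4, step_rotate = 5 * pi / 180,
                         repetitions_per_step = 3) {
  operation <- match.arg(operation)
  if (step_translate > 1e-4 + 1e-12) {
    warning("translation increment exceeds the 0.1 mm fidelity default")
  }
  if (step_rotate > 5 * pi / 180 + 1e-12) {
    warning("rotation increment exceeds the 5 degree fidelity default")
  }
  setting <- impulse_setting("low")
  mid <- (start + end) / 2
  stages <- list()
  sweep_dir <- 1
  add_line_stage <- function(stages, s, e, label) {
    sched <- line_of_twin_traps(s, e, geometry, dwell = setting$dwell,
                                order = sweep_dir)
    stages[[length(stages) + 1]] <- recipe_stage(
      label, sched, setting,
      duration = repetitions_per_step * sum(sched$dwell))
    stages
  }
  if (operation == "translate") {
    if (distance > 0) {
      u <- (end - start) / sqrt(sum((end - start)^2))
      nrm <- c(-u[2], u[1])
      n_st <- ceiling(distance / step_translate)
      for (i in seq_len(n_st)) {
        off <- nrm * min(i * step_translate, distance)
        stages <- add_line_stage(stages, start + off, end + off,
                                 sprintf("translate step %d", i))
        sweep_dir <- -sweep_dir
      }
    }
  } else if (operation %in% c("rotate", "split_rotate")) {
    if (angle != 0) {
      n_st <- ceiling(abs(angle) / step_rotate)
      for (i in seq_len(n_st)) {
        a <- sign(angle) * min(i * step_rotate, abs(angle))
        rot <- function(p, c0, th) {
          d <- p - c0
          c0 + c(cos(th) * d[1] - sin(th) * d[2],
                 sin(th) * d[1] + cos(th) * d[2])
        }
        if (operation == "rotate") {
          stages <- add_line_stage(stages, rot(start, mid, a),
                                   rot(end, mid, a),
                                   sprintf("rotate step %d", i))
        } else {
          c1 <- (start + mid) / 2
          c2 <- (mid + end) / 2
          s1 <- line_of_twin_traps(rot(start, c1, a), rot(mid, c1, a),
                                   geometry, setting$dwell, order = sweep_dir)
          s2 <- line_of_twin_traps(rot(mid, c2, -a), rot(end, c2, -a),
                                   geometry, setting$dwell, order = -sweep_dir)
          sched <- switching_schedule(c(s1$states, s2$states), setting$dwell,
                                      label = sprintf("split rotate %d", i))
          stages[[length(stages) + 1]] <- recipe_stage(
            sprintf("split rotate step %d", i), sched, setting,
            duration = repetitions_per_step * sum(sched$dwell))
        }
        sweep_dir <- -sweep_dir
      }
    }
  } else {  # arc / circle
    len <- sqrt(sum((end - start)^2))
    radii <- arc_radius_steps(target_radius)
    for (i in seq_along(radii)) {
      pts <- arc_points(mid, start, end, radii[i], geometry)
      sched <- arc_of_twin_traps(pts, geometry, setting$dwell,
                                 order = sweep_dir)
      stages[[length(stages) + 1]] <- recipe_stage(
        sprintf("arc radius %.2f mm", radii[i] * 1e3), sched, setting,
        duration = repetitions_per_step * sum(sched$dwell))
      sweep_dir <- -sweep_dir
    }
    if (operation == "circle") {
      chi <- 1
      bs <- list()
      for (m in c(2, 6, 2, 6)) {
        bs[[length(bs) + 1]] <- bessel_drive(geometry, order = m,
                                             chirality = chi, focus = mid)
        chi <- -chi
      }
      sched <- switching_schedule(bs, setting$dwell, "bessel 2/6 circle")
      stages[[length(stages) + 1]] <- recipe_stage(
        "circle finale (bessel 2/6 switching)", sched, setting,
        duration = 50 * sum(sched$dwell))
    }
  }
  structure(list(stages = stages, label = paste("reshape:", operation)),
            class = "recipe")
}

# Printed radius ramp for deforming a 2 mm line into an arc: 0.5 mm/step
# from 5 to 3 mm, 0.25 mm/step from 3 to 1 mm, 0.12 mm/step below 1 mm.
arc_radius_steps <- function(target_radius) {
  r <- 5e-3
  out <- numeric(0)
  while (r > target_radius + 1e-12) {
    step <- if (r > 3e-3 + 1e-12) 0.5e-3 else if (r > 1e-3 + 1e-12) 0.25e-3
            else 0.12e-3
    r <- max(r - step, target_radius)
    out <- c(out, r)
  }
  out
}

# Arc through the line centre with the given radius: the arc centre sits
# at distance `radius` from the line midpoint (perpendicular), the arc
# length equals the line length, and the midpoint stays in place.
arc_points <- function(mid, start, end, radius, geometry) {
  len <- sqrt(sum((end - start)^2))
  u <- (end - start) / len
  nrm <- c(-u[2], u[1])
  centre <- mid + nrm * radius
  half_sweep <- (len / 2) / radius
  base <- atan2(mid[2] - centre[2], mid[1] - centre[1])
  n <- n_twin_traps(len, geometry$wavelength)
  th <- base + seq(-half_sweep, half_sweep, length.out = n)
  cbind(centre[1] + radius * cos(th), centre[2] + radius * sin(th))
}

# Twin traps along a polyline of points with locally tangent axes.
arc_of_twin_traps <- function(pts, geometry, dwell, order = 1) {
  n <- nrow(pts)
  idx <- if (order >= 0) seq_len(n) else rev(seq_len(n))
  states <- lapply(idx, function(i) {
    j <- min(i + 1, n); j0 <- max(i - 1, 1)
    axis <- atan2(pts[j, 2] - pts[j0, 2], pts[j, 1] - pts[j0, 1])
    twin_trap_drive(geometry, pts[i, ], axis_angle = axis)
  })
  switching_schedule(states, dwell, label = sprintf("arc (%d traps)", n))
}
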