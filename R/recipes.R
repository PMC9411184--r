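#' One stage of a patterning recipe
#'
#' @param label Stage label.
#' @param schedule A [switching_schedule()], or `NULL` for special tools.
#' @param setting An [impulse_setting()].
#' @param duration Simulated time for the stage (s); default one pass
#'   through the schedule.
#' @param tool "schedule" (default) or "remove_stragglers".
#' @param params Extra parameters for special tools.
#' @return A `recipe_stage` list.
#' @export
recipe_stage <- function(label, schedule, setting,
                         duration = NULL, tool = "schedule",
                         params = list()) {
  if (is.null(duration) && !is.null(schedule)) duration <- sum(schedule$dwell)
  structure(list(label = label, schedule = schedule, setting = setting,
                 duration = duration, tool = tool, params = params),
            class = "recipe_stage")
}

new_recipe <- function(stages, label) {
  structure(list(stages = stages, label = label), class = "recipe")
}

#' @export
print.recipe <- function(x, ...) {
  cat(sprintf("recipe '%s' (%d stages):\n", x$label, length(x$stages)))
  for (st in x$stages) {
    cat(sprintf("  [%-12s] %s (%.3g s)\n", st$setting$regime, st$label,
                st$duration))
  }
  invisible(x)
}

# Twin traps resampled equidistantly along a polyline (vertex matrix),
# with locally tangent cancellation axes.
polyline_trap_points <- function(vertices, geometry) {
  seg <- diff(vertices)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  n <- n_twin_traps(total, geometry$wavelength)
  s_targets <- if (n == 1) 0 else seq(0, total, length.out = n)
  cum <- c(0, cumsum(seg_len))
  pts <- matrix(0, n, 2)
  ang <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, min(findInterval(s_targets[i], cum, rightmost.closed = TRUE),
                    nrow(seg)))
    f <- if (seg_len[j] > 0) (s_targets[i] - cum[j]) / seg_len[j] else 0
    pts[i, ] <- vertices[j, ] + f * seg[j, ]
    ang[i] <- atan2(seg[j, 2], seg[j, 1])
  }
  list(points = pts, angles = ang)
}

# Low-impulse twin-trap schedule tracing a whole skeleton (list of
# polylines), sweep direction controlled by `order`.
skeleton_trap_schedule <- function(skeleton, geometry,
                                   dwell = impulse_setting("low")$dwell,
                                   order = 1) {
  pts <- list(); ang <- list()
  for (pl in skeleton) {
    tp <- polyline_trap_points(pl, geometry)
    pts[[length(pts) + 1]] <- tp$points
    ang[[length(ang) + 1]] <- tp$angles
  }
  pts <- do.call(rbind, pts)
  ang <- unlist(ang)
  idx <- if (order >= 0) seq_len(nrow(pts)) else rev(seq_len(nrow(pts)))
  states <- lapply(idx, function(i) {
    twin_trap_drive(geometry, pts[i, ], axis_angle = ang[i])
  })
  switching_schedule(states, dwell,
                     label = sprintf("skeleton traps (%d)", length(states)))
}

#' Letter skeletons
#'
#' Polyline skeletons for the letters 'A', 'B' and 'C', centred on the
#' array centre. These are documented approximations drawn for this
#' simulator; contrast metrics are always reported against these
#' skeletons.
#'
#' @param letter "A", "B" or "C".
#' @param height Letter height (m).
#' @return List of polylines (vertex matrices, metres).
#' @export
letter_skeleton <- function(letter, height = 2.2e-3) {
  if (!nzchar(letter)) stop("empty target shape", call. = FALSE)
  s <- height / 2.2e-3 * 1e-3  # per-unit scale (1 unit = 1 mm at default)
  arc <- function(cx, cy, r, from, to, n = 16) {
    th <- seq(from, to, length.out = n)
    cbind(cx + r * cos(th), cy + r * sin(th)) * s
  }
  switch(toupper(letter),
    A = list(
      rbind(c(-0.8, -1.1), c(0, 1.1)) * s,
      rbind(c(0.8, -1.1), c(0, 1.1)) * s,
      rbind(c(-0.44, -0.1), c(0.44, -0.1)) * s
    ),
    B = list(
      rbind(c(-0.6, -1.1), c(-0.6, 1.1)) * s,
      rbind(rbind(c(-0.6, 1.1)) * s, arc(0, 0.55, 0.55, pi / 2, -pi / 2),
            rbind(c(-0.6, 0)) * s),
      rbind(rbind(c(-0.6, 0)) * s, arc(0, -0.55, 0.55, pi / 2, -pi / 2),
            rbind(c(-0.6, -1.1)) * s)
    ),
    C = list(arc(0, 0, 1.1, pi / 4, 7 * pi / 4, n = 24)),
    stop("unknown letter (available: A, B, C)", call. = FALSE)
  )
}

#' Recipe: isolated line in a cleared workspace
#'
#' Staged sequence forming a single high-contrast line: focus-sweep
#' clearing below the line, two sweep passes above it, counter-swept
#' intermediate-impulse twin traps, increasing-order Bessel clearing
#' (orders 9 up to 20, chirality alternating) interleaved with twin-trap
#' reinforcement, a final low-impulse twin-trap line, and a static
#' standing wave whose node line reinforces the particle line.
#'
#' @param geometry An [build_circular_array()] geometry.
#' @param start,end Line endpoints (m).
#' @return A `recipe`.
#' @export
form_isolated_line <- function(geometry, start = c(-1e-3, 0),
                               end = c(1e-3, 0)) {
  low <- impulse_setting("low")
  mid <- impulse_setting("intermediate")
  high <- impulse_setting("high")
  lam <- geometry$wavelength
  x0 <- min(start[1], end[1]) - 2 * lam
  x1 <- max(start[1], end[1]) + 2 * lam
  yl <- min(start[2], end[2]); yh <- max(start[2], end[2])
  stages <- list()
  sw_below <- focus_sweep_schedule(geometry,
                                   c(x0, x1, yl - 1.2e-3, yl - 0.3e-3),
                                   dwell = mid$dwell)
  stages[[1]] <- recipe_stage("sweep below", sw_below, mid)
  sw_above <- focus_sweep_schedule(geometry,
                                   c(x0, x1, yh + 0.3e-3, yh + 1.2e-3),
                                   dwell = mid$dwell)
  stages[[2]] <- recipe_stage("sweep above (x2)", sw_above, mid,
                              duration = 2 * sum(sw_above$dwell))
  traps_mid <- line_of_twin_traps(start, end, geometry, dwell = mid$dwell,
                                  order = -1)
  stages[[3]] <- recipe_stage("counter-swept twin traps", traps_mid, mid,
                              duration = 3 * sum(traps_mid$dwell))
  chunks <- list(9:12, 13:16, 17:20)
  chi <- 1
  for (ci in seq_along(chunks)) {
    orders <- chunks[[ci]]
    bs <- lapply(orders, function(m) {
      bessel_drive(geometry, order = m, chirality = chi)
    })
    chi <- -chi
    bsched <- switching_schedule(bs, 0.3,
                                 sprintf("bessel up %d-%d", min(orders),
                                         max(orders)))
    stages[[length(stages) + 1]] <- recipe_stage(
      sprintf("bessel up %d-%d", min(orders), max(orders)), bsched, high)
    reinf <- line_of_twin_traps(start, end, geometry, dwell = mid$dwell,
                                order = if (ci %% 2) 1 else -1)
    stages[[length(stages) + 1]] <- recipe_stage(
      "twin-trap reinforcement", reinf, mid,
      duration = 2 * sum(reinf$dwell))
  }
  traps_low <- line_of_twin_traps(start, end, geometry, dwell = low$dwell)
  stages[[length(stages) + 1]] <- recipe_stage(
    "twin traps", traps_low, low, duration = 0.3)
  axis <- atan2(end[2] - start[2], end[1] - start[1]) + pi / 2
  sw <- switching_schedule(
    list(standing_wave_drive(geometry, axis_angle = axis)), high$dwell,
    "static standing wave")
  stages[[length(stages) + 1]] <- recipe_stage(
    "static standing wave", sw, high, duration = 0.2)
  new_recipe(stages, "isolated line")
}

#' Recipe: circle
#'
#' High-impulse decreasing-order Bessel cycling agglomerates the
#' particles into an approximately circular ring; the circle is then
#' held in the low impulse regime by switching between 5th and 9th order
#' Bessel-shaped fields (chirality alternating).
#'
#' @param geometry An [build_circular_array()] geometry.
#' @param center Circle centre (m).
#' @return A `recipe`.
#' @export
form_circle <- function(geometry, center = c(0, 0)) {
  low <- impulse_setting("low")
  high <- impulse_setting("high")
  stages <- list()
  agg <- bessel_cycle_schedule(geometry, center, order_from = 20,
                               order_to = 9, repetitions = 2,
                               dwell = high$dwell)
  stages[[1]] <- recipe_stage("bessel agglomeration 20->9", agg, high)
  states <- list(); chi <- 1
  for (m in c(5, 9, 5, 9)) {
    states[[length(states) + 1]] <- bessel_drive(geometry, order = m,
                                                 chirality = chi,
                                                 focus = center)
    chi <- -chi
  }
  hold <- switching_schedule(states, low$dwell, "bessel 5/9 switching")
  stages[[2]] <- recipe_stage("bessel 5/9 switching", hold, low,
                              duration = 0.3)
  new_recipe(stages, "circle")
}

#' Recipe: C shape
#'
#' Bessel cycling forms an approximate circle, an offset increasing-order
#' cycle clears the gap on the right-hand side, and the C is then held by
#' a low-impulse collection of twin traps along the arc.
#'
#' @param geometry An [build_circular_array()] geometry.
#' @param radius Arc radius (m).
#' @return A `recipe`.
#' @export
form_C <- function(geometry, radius = 1.1e-3) {
  low <- impulse_setting("low")
  high <- impulse_setting("high")
  stages <- list()
  agg <- bessel_cycle_schedule(geometry, c(0, 0), order_from = 20,
                               order_to = 9, repetitions = 2,
                               dwell = high$dwell)
  stages[[1]] <- recipe_stage("bessel agglomeration 20->9", agg, high)
  gap <- bessel_cycle_schedule(geometry, c(radius, 0), order_from = 1,
                               order_to = 6, repetitions = 2,
                               dwell = high$dwell)
  stages[[2]] <- recipe_stage("gap clearing (offset bessel up)", gap, high)
  arcpts <- letter_skeleton("C", height = 2 * radius)[[1]]
  traps <- skeleton_trap_schedule(list(arcpts), geometry, dwell = low$dwell)
  stages[[3]] <- recipe_stage("C twin traps", traps, low, duration = 0.3)
  new_recipe(stages, "C shape")
}

#' Recipe: letter pattern with full clearing
#'
#' Staged letter formation on a random ensemble: low-impulse twin traps
#' tracing the skeleton, increasing-order Bessel clearing (9 up to 20,
#' chirality alternating) interleaved with skeleton reinforcement, a
#' final low-impulse reinforcement, and per-particle removal of the
#' remaining stragglers with a translated vortex trap (see
#' [remove_stragglers()]). With `clearing = FALSE` only the first
#' patterning stage is kept, which leaves the stray background in place.
#'
#' @param geometry An [build_circular_array()] geometry.
#' @param letter "A", "B" or "C".
#' @param height Letter height (m).
#' @param clearing Include the clearing and removal stages.
#' @param mask Optional [shape_mask()] used by the removal stage;
#'   defaults to the skeleton mask with standard tolerances.
#' @return A `recipe`.
#' @export
form_letter <- function(geometry, letter = "A", height = 2.2e-3,
                        clearing = TRUE, mask = NULL) {
  skel <- letter_skeleton(letter, height)
  low <- impulse_setting("low")
  mid <- impulse_setting("intermediate")
  high <- impulse_setting("high")
  if (is.null(mask)) mask <- skeleton_mask(skel, geometry)
  stages <- list()
  base <- skeleton_trap_schedule(skel, geometry, dwell = low$dwell)
  stages[[1]] <- recipe_stage("skeleton traps (low impulse)", base, low,
                              duration = 0.5)
  if (clearing) {
    chunks <- list(9:14, 15:20)
    chi <- 1
    for (rep in 1:2) {
      for (orders in chunks) {
        bs <- lapply(orders, function(m) {
          bessel_drive(geometry, order = m, chirality = chi)
        })
        chi <- -chi
        # 300 ms per order: away from the first ring the normalized field
        # is weak, so particles need long dwells to track the ring motion
        bsched <- switching_schedule(bs, 0.3, "bessel up")
        stages[[length(stages) + 1]] <- recipe_stage(
          sprintf("bessel up %d-%d (rep %d)", min(orders), max(orders), rep),
          bsched, high)
        reinf <- skeleton_trap_schedule(skel, geometry, dwell = low$dwell,
                                        order = if (chi > 0) 1 else -1)
        stages[[length(stages) + 1]] <- recipe_stage(
          "skeleton reinforcement", reinf, low, duration = 0.15)
      }
    }
    stages[[length(stages) + 1]] <- recipe_stage(
      "conveyor clearing to edge", NULL, high, duration = 0,
      tool = "conveyor_clear", params = list(r_inner = 1.8e-3))
    final <- skeleton_trap_schedule(skel, geometry, dwell = low$dwell)
    stages[[length(stages) + 1]] <- recipe_stage(
      "final skeleton traps", final, low, duration = 0.3)
    stages[[length(stages) + 1]] <- recipe_stage(
      "remove stragglers", NULL, mid, duration = 0,
      tool = "remove_stragglers", params = list(mask = mask))
  }
  new_recipe(stages, sprintf("letter %s", toupper(letter)))
}

#' Shape mask of a skeleton
#'
#' Convenience wrapper building a [shape_mask()] from a list of polylines
#' with the standard tolerances (lambda/4 inclusion, 2 lambda edge
#' margin) of the given geometry.
#'
#' @param skeleton List of polyline vertex matrices (m).
#' @param geometry An [build_circular_array()] geometry.
#' @param ... Overrides passed to [shape_mask()].
#' @return A [shape_mask()].
#' @export
skeleton_mask <- function(skeleton, geometry, ...) {
  segs <- do.call(rbind, lapply(skeleton, function(v) {
    cbind(v[-nrow(v), , drop = FALSE], v[-1, , drop = FALSE])
  }))
  defaults <- list(tolerance = geometry$wavelength / 4,
                   edge_margin = 2 * geometry$wavelength,
                   chamber_radius = geometry$chamber_radius)
  args <- utils::modifyList(defaults, list(...))
  do.call(shape_mask, c(list(segments = segs), args))
}

#' Execute a recipe on an ensemble
#'
#' Compiles and simulates each stage in order on a full-chamber grid
#' (shared transfer matrix), applying special tools where present, and
#' logs a per-stage summary.
#'
#' @param recipe A `recipe`.
#' @param ensemble An [random_ensemble()].
#' @param geometry An [build_circular_array()] geometry.
#' @param grid Optional [field_grid()]; default covers the full chamber.
#' @param f_max Per-state maximum force (N).
#' @param verbose Print stage progress.
#' @return List with the final `ensemble` and a `log` data.frame
#'   (stage, regime, i_app, mean_displacement).
#' @export
run_recipe <- function(recipe, ensemble, geometry, grid = NULL,
                       f_max = 1e-8, verbose = FALSE) {
  stopifnot(inherits(recipe, "recipe"), inherits(ensemble, "ensemble"))
  if (is.null(grid)) {
    grid <- field_grid(geometry, extent = geometry$chamber_diameter)
  }
  h <- transfer_matrix(geometry, grid)
  log <- list()
  for (st in recipe$stages) {
    before <- ensemble$positions
    if (st$tool == "remove_stragglers") {
      ensemble <- remove_stragglers(ensemble, st$params$mask, geometry,
                                    f_max = f_max)
    } else if (st$tool == "conveyor_clear") {
      ensemble <- conveyor_clear_sectors(
        ensemble, geometry, r_inner = st$params$r_inner %||% 1.8e-3,
        f_max = f_max)
    } else if (length(st$schedule$states) > 0 && st$duration > 0) {
      compiled <- compile_schedule(st$schedule, geometry, grid,
                                   ensemble$material, f_max = f_max, h = h)
      ensemble <- simulate_switched(ensemble, compiled, st$duration)
    }
    disp <- mean(sqrt(rowSums((ensemble$positions - before)^2)))
    log[[length(log) + 1]] <- data.frame(
      stage = st$label, regime = st$setting$regime,
      i_app = applied_impulse(f_max, st$setting$dwell),
      mean_displacement = disp)
    if (verbose) {
      message(sprintf("stage %-32s mean displacement %.3g mm",
                      st$label, disp * 1e3))
    }
  }
  list(ensemble = ensemble, log = do.call(rbind, log))
}

#' Sector-wise conveyor clearing to the chamber edge
#'
#' Systematic bulk clearing of the mid-field: the chamber outside
#' `r_inner` is divided into angular sectors, and for each sector a
#' localized standing-wave conveyor belt (three phase-stepped states,
#' high impulse) is run along the sector's radial axis, carrying every
#' particle in its strip half a wavelength outward per loop until it
#' reaches the chamber edge. Fields are synthesized on a per-sector
#' sub-grid and are zero elsewhere, so the pattern inside `r_inner` is
#' untouched.
#'
#' @param ensemble An [random_ensemble()].
#' @param geometry An [build_circular_array()] geometry.
#' @param r_inner Inner protection radius (m); the conveyor strips start
#'   outside it.
#' @param n_sectors Number of angular sectors.
#' @param n_loops 3-step loops per sector (enough to cover the strip).
#' @param dwell Per-step dwell (s).
#' @param half_width Lateral half-width of each strip (m).
#' @param f_max Force ceiling (N).
#' @param sectors Optional subset of sector indices to run.
#' @return The updated ensemble.
#' @export
conveyor_clear_sectors <- function(ensemble, geometry, r_inner = 1.8e-3,
                                   n_sectors = 12, n_loops = NULL,
                                   dwell = impulse_setting("high")$dwell,
                                   half_width = 1.2e-3, f_max = 1e-8,
                                   sectors = seq_len(n_sectors)) {
  lam <- geometry$wavelength
  r_outer <- geometry$chamber_radius - 0.3e-3
  if (is.null(n_loops)) {
    n_loops <- ceiling((r_outer - r_inner) / (lam / 2)) + 2
  }
  for (k in sectors) {
    theta <- 2 * pi * (k - 1) / n_sectors
    u <- c(cos(theta), sin(theta))
    # strip sub-grid along the sector axis
    ends <- rbind(r_inner * u, r_outer * u)
    nvec <- c(-u[2], u[1])
    corners <- rbind(ends[1, ] + half_width * nvec,
                     ends[1, ] - half_width * nvec,
                     ends[2, ] + half_width * nvec,
                     ends[2, ] - half_width * nvec)
    sub <- field_grid_rect(geometry, range(corners[, 1]), range(corners[, 2]))
    # particles inside the strip (axis-aligned coordinates)
    rel <- sweep(ensemble$positions, 2, c(0, 0))
    along <- rel %*% u
    across <- rel %*% nvec
    in_strip <- along > r_inner & along < r_outer & abs(across) < half_width
    if (!any(in_strip)) next
    hs <- transfer_matrix(geometry, sub)
    states <- lapply(0:2, function(s) {
      standing_wave_drive(geometry, axis_angle = theta, step_index = s,
                          offset_sign = -1)
    })
    sched <- switching_schedule(states, dwell, "sector conveyor")
    compiled <- compile_schedule(sched, geometry, sub, ensemble$material,
                                 f_max = f_max, h = hs,
                                 norm_radius = geometry$chamber_radius - 0.7e-3)
    idx <- which(in_strip)
    sub_ens <- ensemble
    sub_ens$positions <- ensemble$positions[idx, , drop = FALSE]
    sub_ens$velocities <- ensemble$velocities[idx, , drop = FALSE]
    sub_ens <- simulate_switched(sub_ens, compiled, 3 * n_loops * dwell,
                                 outside_zero = TRUE)
    ensemble$positions[idx, ] <- sub_ens$positions
    ensemble$velocities[idx, ] <- sub_ens$velocities
  }
  ensemble
}

#' Remove remaining stragglers (vortex pickup plus conveyor)
#'
#' Per-particle removal of the off-pattern background left after bulk
#' clearing. Interior stragglers (inside `handoff_radius`, where the
#' vortex trap is well formed) are each picked up by an order-1 vortex
#' trap stepped radially outward in 0.15 mm increments
#' (upper-intermediate impulse) until past the handoff radius; a
#' sector-wise localized standing-wave conveyor then carries everything
#' outside the handoff radius to the chamber edge. Fields are
#' synthesized on localized sub-grids and are zero elsewhere, keeping
#' disturbance of the pattern minimal; repeated passes catch particles
#' dislodged along the way.
#'
#' @param ensemble An [random_ensemble()].
#' @param mask A [shape_mask()] defining on-pattern and edge bands.
#' @param geometry An [build_circular_array()] geometry.
#' @param f_max Trap force ceiling (N).
#' @param dwell Per-step vortex dwell (s).
#' @param step Vortex translation per step (m).
#' @param pad Sub-grid padding around the extraction path (m).
#' @param handoff_radius Radius at which the conveyor takes over (m);
#'   beyond about 3 mm an off-centre vortex core fills in and stops
#'   trapping, so extraction hands off well before that.
#' @param max_passes Straggler identification passes.
#' @return The updated ensemble.
#' @export
remove_stragglers <- function(ensemble, mask, geometry, f_max = 1e-8,
                              dwell = 20e-3, step = 0.15e-3, pad = 0.7e-3,
                              handoff_radius = 2.2e-3, max_passes = 3) {
  n_sectors <- 12
  for (pass in seq_len(max_passes)) {
    pos <- ensemble$positions
    d_skel <- dist_to_segments(pos, mask$segments)
    r <- sqrt(rowSums(pos^2))
    straggler <- d_skel > mask$tolerance &
                 r < mask$chamber_radius - mask$edge_margin
    if (!any(straggler)) break
    inner <- which(straggler & r < handoff_radius)
    for (i in inner) {
      p0 <- ensemble$positions[i, ]
      rr <- sqrt(sum(p0^2))
      u <- if (rr > 1e-9) p0 / rr else c(1, 0)
      path_r <- seq(rr, handoff_radius + 0.4e-3, by = step)
      if (length(path_r) < 2) next
      pts <- cbind(path_r * u[1], path_r * u[2])
      xlim <- range(pts[, 1]) + c(-pad, pad)
      ylim <- range(pts[, 2]) + c(-pad, pad)
      sub <- field_grid_rect(geometry, xlim, ylim)
      hs <- transfer_matrix(geometry, sub)
      states <- lapply(seq_len(nrow(pts)), function(j) {
        bessel_drive(geometry, order = 1, focus = pts[j, ])
      })
      sched <- switching_schedule(states, dwell, "straggler vortex")
      compiled <- compile_schedule(sched, geometry, sub, ensemble$material,
                                   f_max = f_max, h = hs)
      in_box <- ensemble$positions[, 1] >= xlim[1] &
                ensemble$positions[, 1] <= xlim[2] &
                ensemble$positions[, 2] >= ylim[1] &
                ensemble$positions[, 2] <= ylim[2]
      idx <- which(in_box)
      sub_ens <- ensemble
      sub_ens$positions <- ensemble$positions[idx, , drop = FALSE]
      sub_ens$velocities <- ensemble$velocities[idx, , drop = FALSE]
      sub_ens <- simulate_switched(sub_ens, compiled,
                                   duration = nrow(pts) * dwell,
                                   outside_zero = TRUE)
      ensemble$positions[idx, ] <- sub_ens$positions
      ensemble$velocities[idx, ] <- sub_ens$velocities
    }
    # conveyor pass for everything parked outside the handoff radius
    pos <- ensemble$positions
    d_skel <- dist_to_segments(pos, mask$segments)
    r <- sqrt(rowSums(pos^2))
    out_str <- d_skel > mask$tolerance & r >= handoff_radius - 0.3e-3 &
               r < mask$chamber_radius - mask$edge_margin
    if (any(out_str)) {
      ang <- atan2(pos[out_str, 2], pos[out_str, 1]) %% (2 * pi)
      secs <- sort(unique(round(ang / (2 * pi / n_sectors)) %% n_sectors + 1))
      ensemble <- conveyor_clear_sectors(
        ensemble, geometry, r_inner = handoff_radius - 0.4e-3,
        n_sectors = n_sectors, f_max = f_max, sectors = secs)
    }
  }
  ensemble
}
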