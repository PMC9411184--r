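test_that("circular array geometry has uniform spacing and inward normals", {
  g4 <- build_circular_array(4, 2e-3, 0.2e-3, 2.35e6)
  expect_equal(g4$element_positions,
               cbind(c(1, 0, -1, 0), c(0, 1, 0, -1)) * 1e-3,
               tolerance = 1e-12)
  # normals point at the array centre: angle off normal is zero there
  for (g in list(g4, dev_geom)) {
    to_centre <- -g$element_positions /
      sqrt(rowSums(g$element_positions^2))
    expect_equal(g$element_normals, to_centre, tolerance = 1e-12)
  }
  expect_equal(diff(dev_geom$element_angles),
               rep(2 * pi / 64, 63), tolerance = 1e-12)
  expect_equal(dev_geom$k, 2 * pi / dev_geom$wavelength)
  # wavelength falls back to c0/frequency when not overridden
  g <- build_circular_array(wavelength = NULL)
  expect_equal(g$wavelength, 1500 / 2.35e6)
  expect_error(build_circular_array(n_elements = 2), "invalid geometry")
  expect_error(build_circular_array(chamber_diameter = -1), "invalid geometry")
})

test_that("transfer matrix matches a direct scalar evaluation", {
  # single field point at known r and theta from element 1
  g <- dev_geom
  el <- g$element_positions[1, ]     # (R, 0), normal (-1, 0)
  r <- 1e-3
  theta <- 0.3
  pt <- el + r * c(-cos(theta), sin(theta))
  grid <- structure(list(x = pt[1], y = pt[2], spacing = g$wavelength / 20,
                         nx = 1L, ny = 1L, geometry = g),
                    class = "field_grid_spec")
  h <- transfer_matrix(g, grid)
  arg <- g$element_width * pi^2 * sin(theta) / g$wavelength
  expected <- exp(-1i * g$k * r) / (2 * pi * sqrt(r)) * sin(arg) / arg
  expect_equal(h[1, 1], expected, tolerance = 1e-12)
  # on the normal the directivity factor is exactly 1
  pt0 <- el + r * c(-1, 0)
  grid0 <- structure(list(x = pt0[1], y = pt0[2], spacing = g$wavelength / 20,
                          nx = 1L, ny = 1L, geometry = g),
                     class = "field_grid_spec")
  h0 <- transfer_matrix(g, grid0)
  expect_equal(h0[1, 1], exp(-1i * g$k * r) / (2 * pi * sqrt(r)),
               tolerance = 1e-12)
  # 1/sqrt(r) spreading: fixed theta = 0, r vs 4r
  pt4 <- el + 4 * r * c(-1, 0)
  grid4 <- structure(list(x = pt4[1], y = pt4[2], spacing = g$wavelength / 20,
                          nx = 1L, ny = 1L, geometry = g),
                     class = "field_grid_spec")
  h4 <- transfer_matrix(g, grid4)
  expect_equal(Mod(h0[1, 1]) / Mod(h4[1, 1]), 2, tolerance = 1e-12)
})

test_that("pressure synthesis is linear and superposes", {
  n <- dev_geom$n_elements
  d0 <- drive_state(rep(0, n), rep(0, n))
  expect_equal(max(Mod(synthesize_pressure(central_h, d0)$p)), 0)
  set.seed(4)
  amps <- runif(n)
  phis <- runif(n, -pi, pi)
  d1 <- drive_state(amps, phis)
  d2 <- drive_state(2 * amps, phis)
  f1 <- synthesize_pressure(central_h, d1)
  expect_equal(synthesize_pressure(central_h, d2)$p, 2 * f1$p,
               tolerance = 1e-12)
  # superposition of two single-element drives
  e1 <- drive_state(c(1, rep(0, n - 1)), rep(0, n))
  e2 <- drive_state(c(0, 1, rep(0, n - 2)), rep(0, n))
  e12 <- drive_state(c(1, 1, rep(0, n - 2)), rep(0, n))
  expect_equal(synthesize_pressure(central_h, e12)$p,
               synthesize_pressure(central_h, e1)$p +
                 synthesize_pressure(central_h, e2)$p,
               tolerance = 1e-12)
  expect_error(synthesize_pressure(central_h, drive_state(1, 0)),
               "dimension mismatch")
})

test_that("bessel drive phase law: winding, focus and bounds", {
  n <- dev_geom$n_elements
  # m = 0 at the centre: all phases equal (equal element-focus distance)
  b0 <- bessel_drive(dev_geom, 0, focus = c(0, 0))
  expect_equal(diff(b0$phases), rep(0, n - 1), tolerance = 1e-12)
  # phase winding around the ring is 2*pi*m*chirality
  for (m in c(1, 5)) {
    for (chi in c(1, -1)) {
      b <- bessel_drive(dev_geom, m, chirality = chi)
      steps <- wrap_phase(diff(c(b$phases, b$phases[1])))
      expect_equal(sum(steps), 2 * pi * m * chi, tolerance = 1e-9)
    }
  }
  # m = 0 off-centre: synthesized |p| peaks at the focus
  focus <- c(0.8e-3, -0.5e-3)
  f <- synthesize_pressure(central_h, bessel_drive(dev_geom, 0, focus = focus))
  xx <- rep(central_grid$x, each = central_grid$ny)
  yy <- rep(central_grid$y, times = central_grid$nx)
  near <- sqrt((xx - focus[1])^2 + (yy - focus[2])^2) <= dev_geom$wavelength
  imax <- which.max(Mod(f$p) * near)
  expect_lt(sqrt((xx[imax] - focus[1])^2 + (yy[imax] - focus[2])^2),
            dev_geom$wavelength / 4)
  expect_error(bessel_drive(dev_geom, 0, focus = c(6e-3, 0)),
               "outside chamber")
})

test_that("twin trap: pi inversion across the axis and central cancellation", {
  n <- dev_geom$n_elements
  tt <- twin_trap_drive(dev_geom, c(0, 0), axis_angle = 0)
  # opposing elements across the x-axis are pi apart (active ones)
  for (i in 2:(n / 2)) {
    j <- n + 2 - i  # mirror of element i across the x-axis
    if (tt$amplitudes[i] > 0 && tt$amplitudes[j] > 0) {
      expect_equal(abs(wrap_phase(tt$phases[i] - tt$phases[j])), pi,
                   tolerance = 1e-9)
    }
  }
  # on-axis elements are switched off
  expect_equal(tt$amplitudes[c(1, n / 2 + 1)], c(0, 0))
  # two high-pressure lobes flank a low-pressure centre
  f <- synthesize_pressure(central_h, tt)
  i0 <- which.min(abs(central_grid$x))
  j0 <- which.min(abs(central_grid$y))
  jl <- which.min(abs(central_grid$y - dev_geom$wavelength / 2))
  expect_lt(Mod(f$p[j0, i0]), Mod(f$p[jl, i0]))
  # cancellation holds across the central patterning region
  xx <- rep(central_grid$x, each = central_grid$ny)
  yy <- rep(central_grid$y, times = central_grid$nx)
  foci <- rbind(c(0, 0), c(1e-3, 0.5e-3), c(-1.5e-3, 1e-3), c(0, 1.9e-3))
  for (k in seq_len(nrow(foci))) {
    fc <- foci[k, ]
    tk <- twin_trap_drive(dev_geom, fc, axis_angle = 0.7 * k)
    fk <- synthesize_pressure(central_h, tk)
    i <- which.min(abs(central_grid$x - fc[1]))
    j <- which.min(abs(central_grid$y - fc[2]))
    near <- sqrt((xx - fc[1])^2 + (yy - fc[2])^2) <= dev_geom$wavelength
    expect_lt(Mod(fk$p[j, i]) / max(Mod(fk$p)[near]), 0.2)
  }
  # rotating the axis by pi flips the global sign only
  t2 <- twin_trap_drive(dev_geom, c(0, 0), axis_angle = pi)
  z1 <- tt$amplitudes * exp(1i * tt$phases)
  z2 <- t2$amplitudes * exp(1i * t2$phases)
  expect_equal(z2, -z1, tolerance = 1e-12)
})

test_that("standing-wave conveyor: aperture, 3-cycle and lambda/6 node steps", {
  d <- standing_wave_drive(dev_geom, 11, 0, 0, 1)
  expect_equal(sum(d$amplitudes > 0), 22)
  expect_error(standing_wave_drive(dev_geom, 40), "invalid aperture")
  # step 3 wraps to step 0 exactly
  d3 <- standing_wave_drive(dev_geom, 11, 0, 3, 1)
  expect_identical(d$phases, d3$phases)
  expect_identical(d$amplitudes, d3$amplitudes)
  # advancing the step displaces the node lattice by lambda/6
  lam <- dev_geom$wavelength
  iy0 <- which.min(abs(central_grid$y))
  node_near <- function(step, ref) {
    f <- synthesize_pressure(
      central_h, standing_wave_drive(dev_geom, 11, 0, step, 1))
    prof <- Mod(f$p[iy0, ])
    sel <- which(abs(central_grid$x - ref) < lam / 4 + 1e-9)
    i <- sel[which.min(prof[sel])]
    # parabolic refinement of the minimum
    num <- prof[i - 1] - prof[i + 1]
    den <- prof[i - 1] - 2 * prof[i] + prof[i + 1]
    central_grid$x[i] + 0.5 * num / den * central_grid$spacing
  }
  ref <- node_near(0, 0)
  shifts <- sapply(1:3, function(s) node_near(s, ref - s * lam / 6))
  expect_lt(max(abs(diff(c(ref, shifts)) + lam / 6)), lam / 60)
})
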