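test_that("material bundles satisfy their defining relations", {
  expect_equal(water$kappa0 * water$rho0 * water$c0^2, 1, tolerance = 1e-12)
  expect_equal(poly90$kappa_p * poly90$density * poly90$sound_speed^2, 1,
               tolerance = 1e-12)
  # contrast factors of 90 um polystyrene in water, from the definitions
  expect_equal(poly90$f1, 1 - (1 / (1050 * 2047^2)) / (1 / (997 * 1500^2)),
               tolerance = 1e-12)
  expect_equal(poly90$f1, 0.49015, tolerance = 1e-4)
  expect_equal(poly90$f2, 2 * (1050 - 997) / (2 * 1050 + 997),
               tolerance = 1e-12)
  expect_equal(poly90$f2, 0.03423, tolerance = 1e-4)
  expect_error(medium(c0 = -1), "positive")
})

test_that("virtual mass follows the entrained-flow formula", {
  expect_equal(virtual_mass(poly90), 5.910679e-10, tolerance = 1e-6)
  # rho0 -> 0 limit: the plain sphere mass
  vac <- particle_material(med = medium(rho0 = 1e-30))
  expect_equal(virtual_mass(vac), (4 / 3) * pi * 45e-6^3 * 1050,
               tolerance = 1e-9)
  # cubic scaling in the radius
  big <- particle_material(radius = 90e-6)
  expect_equal(virtual_mass(big) / virtual_mass(poly90), 8, tolerance = 1e-12)
})

test_that("acoustic velocity closure is linear and plane-wave consistent", {
  # spatially uniform pressure: zero velocity
  f <- analytic_standing_wave()
  fu <- f
  fu$p <- matrix(1e5 + 0i, nrow(f$p), ncol(f$p))
  v <- acoustic_velocity(fu)
  expect_equal(max(Mod(v$vx)), 0)
  expect_equal(max(Mod(v$vy)), 0)
  # linearity in p
  v1 <- acoustic_velocity(f)
  f3 <- f
  f3$p <- 3 * f$p
  expect_equal(acoustic_velocity(f3)$vx, 3 * v1$vx, tolerance = 1e-12)
  # single-element far field: |v| ~ |p| / (rho0 c)
  n <- dev_geom$n_elements
  fe <- synthesize_pressure(central_h,
                            drive_state(c(1, rep(0, n - 1)), rep(0, n)))
  ve <- acoustic_velocity(fe)
  j <- which.min(abs(fe$y))
  i <- which.min(abs(fe$x - 1e-3))
  speed <- sqrt(Mod(ve$vx[j, i])^2 + Mod(ve$vy[j, i])^2)
  expect_equal(speed, Mod(fe$p[j, i]) / (water$rho0 * water$c0),
               tolerance = 0.05)
})

test_that("Gor'kov potential matches the 1D standing-wave closed form", {
  fz <- analytic_standing_wave()
  fz$p <- fz$p * 0
  expect_equal(max(abs(gorkov_potential(fz, poly90))), 0)
  amp <- 1e5
  f <- analytic_standing_wave(amp)
  u <- gorkov_potential(f, poly90)
  k <- dev_geom$k
  omega <- 2 * pi * dev_geom$frequency
  pref <- 4 * poly90$radius^3 / 3
  closed <- pref * (poly90$f1 * 0.5 * water$kappa0 * amp^2 *
                      cos(k * f$x)^2 / 2 -
                    poly90$f2 * 0.75 * water$rho0 *
                      (amp * k / (omega * water$rho0))^2 *
                      sin(k * f$x)^2 / 2)
  interior <- 3:(length(f$x) - 2)
  expect_equal(u[3, interior], closed[interior],
               tolerance = 1e-3)
  # radiation force vanishes at nodes and antinodes
  fg <- radiation_force(u, grid = structure(
    list(x = f$x, y = f$y, spacing = f$spacing,
         nx = length(f$x), ny = length(f$y), geometry = dev_geom),
    class = "field_grid_spec"))
  at_extrema <- abs(sin(2 * k * f$x)) < 1e-6
  at_extrema[c(1, length(f$x))] <- FALSE  # one-sided borders excluded
  expect_lt(max(abs(fg$fx[3, at_extrema])),
            1e-6 * max(abs(fg$fx)))
})

test_that("radiation force equals an independent finite-difference oracle", {
  # uniform potential: zero force; linear ramp: constant force
  g <- structure(list(x = seq(0, 1e-3, 5e-5), y = seq(0, 5e-4, 5e-5),
                      spacing = 5e-5, geometry = dev_geom),
                 class = "field_grid_spec")
  g$nx <- length(g$x); g$ny <- length(g$y)
  u_unif <- matrix(3.7, g$ny, g$nx)
  expect_equal(max(abs(radiation_force(u_unif, g)$fx)), 0)
  alpha <- 2.5e-12
  u_ramp <- matrix(rep(alpha * g$x, each = g$ny), g$ny, g$nx)
  fr <- radiation_force(u_ramp, g)
  expect_equal(fr$fx, matrix(-alpha, g$ny, g$nx), tolerance = 1e-9)
  expect_equal(max(abs(fr$fy)), 0, tolerance = 1e-25)
  # synthesized twin-trap potential vs a brute-force gradient at random nodes
  tt <- twin_trap_drive(dev_geom, c(0.5e-3, 0), 0.4)
  field <- synthesize_pressure(central_h, tt)
  u <- gorkov_potential(field, poly90)
  fg <- radiation_force(field, mat = poly90)
  h <- field$spacing
  set.seed(11)
  for (rep in 1:25) {
    i <- sample(2:(ncol(u) - 1), 1)
    j <- sample(2:(nrow(u) - 1), 1)
    expect_equal(fg$fx[j, i], -(u[j, i + 1] - u[j, i - 1]) / (2 * h),
                 tolerance = 1e-9)
    expect_equal(fg$fy[j, i], -(u[j + 1, i] - u[j - 1, i]) / (2 * h),
                 tolerance = 1e-9)
  }
})

test_that("force normalization hits the ceiling and is idempotent", {
  tt <- twin_trap_drive(dev_geom, c(0, 0), 0)
  fg <- radiation_force(synthesize_pressure(central_h, tt), mat = poly90)
  n1 <- normalize_force(fg, 1e-8)
  expect_equal(max(sqrt(n1$fx^2 + n1$fy^2)), 1e-8, tolerance = 1e-12)
  n2 <- normalize_force(n1, 1e-8)
  expect_equal(n2$fx, n1$fx, tolerance = 1e-12)
  fg7 <- fg
  fg7$fx <- 7 * fg$fx
  fg7$fy <- 7 * fg$fy
  expect_equal(normalize_force(fg7, 1e-8)$fx, n1$fx, tolerance = 1e-12)
  zero <- fg
  zero$fx <- zero$fx * 0
  zero$fy <- zero$fy * 0
  expect_error(normalize_force(zero), "all-zero")
})

test_that("drag reduces to Stokes at low Reynolds number and opposes motion", {
  expect_equal(drag_force(c(0, 0), poly90), c(0, 0))
  v <- c(1e-6, 0)
  d <- drag_force(v, poly90)
  stokes <- 6 * pi * water$mu0 * poly90$radius * 1e-6
  expect_equal(sqrt(sum(d^2)), stokes, tolerance = 1e-4)
  # deviation from Stokes is bounded by the finite-Re factor
  for (speed in c(1e-4, 1e-3, 1e-2)) {
    re <- 2 * poly90$radius * water$rho0 * speed / water$mu0
    dmag <- sqrt(sum(drag_force(c(speed, 0), poly90)^2))
    s <- 6 * pi * water$mu0 * poly90$radius * speed
    expect_lte(dmag / s - 1, sqrt(1 + 3 * re / 16) - 1 + 1e-12)
    expect_gte(dmag, s)
  }
  # always opposes the velocity, and magnitude is monotone in speed
  set.seed(3)
  vs <- matrix(rnorm(20, sd = 1e-3), ncol = 2)
  dd <- drag_force(vs, poly90)
  expect_true(all(rowSums(dd * vs) <= 0))
  mags <- sqrt(rowSums(drag_force(cbind(10^seq(-7, -1), 0), poly90)^2))
  expect_true(all(diff(mags) > 0))
})

test_that("explicit step: impulse response, stability bound and clamping", {
  zero_f <- function(p) c(0, 0)
  st <- step_particle(c(1e-4, 0), c(0, 0), zero_f, 1e-5, poly90)
  expect_equal(st$position, c(1e-4, 0))
  expect_equal(st$velocity, c(0, 0))
  # constant force from rest, drag off: displacement F dt^2 / m_v
  fconst <- function(p) c(2e-9, 0)
  st <- step_particle(c(0, 0), c(0, 0), fconst, 1e-5, poly90, drag = FALSE)
  expect_equal(st$position[1], 2e-9 * 1e-5^2 / virtual_mass(poly90),
               tolerance = 1e-12)
  expect_error(step_particle(c(0, 0), c(0, 0), zero_f, 1, poly90),
               "stability bound")
  # clamping to the chamber radius zeroes the velocity
  st <- step_particle(c(5.4899e-3, 0), c(1e-3, 0), zero_f, 1e-5, poly90,
                      chamber_radius = 5.49e-3)
  expect_equal(sqrt(sum(st$position^2)), 5.49e-3 - poly90$radius)
  expect_equal(st$velocity, c(0, 0))
})

test_that("integrator matches the damped linear-oscillator closed form", {
  kappa <- 1e-5            # N/m, keeps Re << 1 so drag is linear Stokes
  m_v <- virtual_mass(poly90)
  gam <- 6 * pi * water$mu0 * poly90$radius
  tau <- viscous_relaxation_time(poly90)
  dt <- tau / 50
  n <- round(100 * tau / dt)
  x0 <- 1e-6
  res <- integrate_particle(c(x0, 0), c(0, 0),
                            function(p) -kappa * p, dt, n, poly90,
                            record_every = 50)
  # closed form: m x'' + gam x' + kappa x = 0, x(0) = x0, x'(0) = 0
  lam <- sort(Re(polyroot(c(kappa, gam, m_v))))
  closed <- function(t) {
    x0 * (lam[1] * exp(lam[2] * t) - lam[2] * exp(lam[1] * t)) /
      (lam[1] - lam[2])
  }
  err <- abs(res$trajectory$x - closed(res$trajectory$t)) / x0
  expect_lt(max(err), 0.01)
})

test_that("a positive-contrast particle converges to a pressure node", {
  # analytic standing-wave Gor'kov force; nodes at k x = pi/2 + n pi
  amp <- 2e4
  f <- analytic_standing_wave(amp, nx = 401)
  fg <- radiation_force(gorkov_potential(f, poly90), grid = structure(
    list(x = f$x, y = f$y, spacing = f$spacing,
         nx = length(f$x), ny = length(f$y), geometry = dev_geom),
    class = "field_grid_spec"))
  fg <- normalize_force(fg, 1e-8)
  lam <- dev_geom$wavelength
  res <- integrate_particle(c(0.1 * lam, 0), c(0, 0),
                            function(p) force_at(fg, p)[1, ],
                            viscous_relaxation_time(poly90) / 50,
                            20000, poly90, record_every = 100)
  node <- lam / 4
  expect_equal(res$position[1], node, tolerance = lam / 200)
  # kinetic energy envelope decays once inside the trap basin (near
  # critical damping the instantaneous speed may dip through zero, so
  # the decay is asserted on per-window maxima)
  tr <- res$trajectory
  speed <- sqrt(tr$vx^2 + tr$vy^2)
  late <- speed[tr$t > tr$t[which.max(speed)]]
  win <- split(late, cut(seq_along(late), 5))
  expect_true(all(diff(vapply(win, max, 0)) <= 0))
})
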