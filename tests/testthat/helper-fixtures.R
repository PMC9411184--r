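# Shared fixtures: the default device, medium and particle, plus a small
# central grid reused across field tests (transfer-matrix synthesis is
# the slow part, so build it once).
dev_geom <- build_circular_array()
water <- medium()
poly90 <- particle_material()
central_grid <- field_grid(dev_geom)
central_h <- transfer_matrix(dev_geom, central_grid)

# analytic 1D standing wave p(x) = amp * cos(k x) wrapped as a
# pressure_field on a thin strip, for closed-form Gor'kov oracles
analytic_standing_wave <- function(amp = 1e5, nx = 201, ny = 5,
                                   geometry = dev_geom) {
  h <- geometry$wavelength / 20
  x <- seq(-(nx - 1) / 2, (nx - 1) / 2) * h
  y <- seq(-(ny - 1) / 2, (ny - 1) / 2) * h
  p <- matrix(rep(amp * cos(geometry$k * x), each = ny), ny, nx)
  structure(
    list(x = x, y = y, spacing = h, p = p + 0i, geometry = geometry,
         label = "analytic standing wave"),
    class = "pressure_field"
  )
}

# analytic two-state 1D standing-wave bench as congruent force grids:
# F_q(x) = -f_max * sin(2k (x - shift_q)), uniform in y
two_state_force_grids <- function(f_max = 1e-8, shifts = c(0, NA),
                                  geometry = dev_geom) {
  lam <- geometry$wavelength
  if (is.na(shifts[2])) shifts[2] <- lam / 8
  h <- lam / 20
  x <- seq(0, lam, by = h)
  y <- seq(-2 * h, 2 * h, by = h)
  lapply(shifts, function(s) {
    fx <- matrix(rep(-f_max * sin(2 * geometry$k * (x - s)), each = length(y)),
                 length(y), length(x))
    structure(list(x = x, y = y, spacing = h, fx = fx, fy = fx * 0,
                   potential = fx * 0),
              class = "force_grid")
  })
}
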