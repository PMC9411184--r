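#' Regime-collapse bench
#'
#' Sweeps the applied impulse on the 1D two-state bench over several
#' maximum forces and switching times and summarizes the collapse of the
#' motion-per-cycle curves: when motion is plotted against applied
#' impulse, the curves for different maximum forces overlay. The collapse
#' deviation is the maximum difference between per-force curves
#' interpolated onto a common impulse grid, expressed as a fraction of
#' the equilibria separation.
#'
#' The collapse is exact in the overdamped limit; the particle's inertial
#' dead time `m_v/(6 pi mu r)` (about 0.8 ms for the default particle)
#' shifts the transition with the maximum force, so the deviation grows
#' with the spanned force range. The defaults span a factor of two
#' around the canonical 10 nN ceiling.
#'
#' @param f_max_values Maximum forces (N).
#' @param dt_s_values Switching times (s).
#' @param ... Passed to [two_state_bench()].
#' @return List: `sweep` (data.frame), `collapse_deviation` (fraction of
#'   the separation), `separation` (m).
#' @export
bench_regime_collapse <- function(f_max_values = c(7.1e-9, 1e-8, 1.41e-8),
                                  dt_s_values = 10^seq(-4, -1,
                                                       length.out = 13),
                                  ...) {
  sweep <- regime_sweep(f_max_values, dt_s_values, ...)
  d <- sweep$separation[1]
  li <- log10(sweep$i_app)
  common <- seq(max(tapply(li, sweep$f_max, min)),
                min(tapply(li, sweep$f_max, max)), length.out = 40)
  curves <- lapply(split(sweep, sweep$f_max), function(s) {
    stats::approx(log10(s$i_app), s$motion, xout = common)$y
  })
  cm <- do.call(cbind, curves)
  dev <- max(apply(cm, 1, function(r) diff(range(r)))) / d
  list(sweep = sweep, collapse_deviation = dev, separation = d)
}

#' Switched-versus-summed equivalence bench
#'
#' Low-impulse validation: a random ensemble is simulated twice under a
#' twin-trap line schedule, once with the switched fields (1 ms dwells)
#' and once with the single dwell-weighted summed field (normalized to
#' the same maximum force), both for the same duration. Reports the
#' per-particle end-position discrepancy; in the low impulse regime the
#' two simulations agree to a small fraction of a wavelength.
#'
#' @param n Number of particles.
#' @param seed Ensemble seed.
#' @param geometry An [build_circular_array()] geometry.
#' @param start,end Line endpoints (m).
#' @param f_max Maximum force (N).
#' @param dwell Switching dwell (s).
#' @param duration Simulated time (s).
#' @param mat A [particle_material()].
#' @return List: `mean_discrepancy`, `max_discrepancy` (m),
#'   `discrepancies`, final position matrices `switched` and `summed`,
#'   and the `wavelength`.
#' @export
bench_switched_vs_summed <- function(n = 50, seed = 1,
                                     geometry = build_circular_array(),
                                     start = c(-1e-3, 0), end = c(1e-3, 0),
                                     f_max = 1e-8, dwell = 1e-3,
                                     duration = 0.5,
                                     mat = particle_material()) {
  grid <- field_grid(geometry)
  sched <- line_of_twin_traps(start, end, geometry, dwell = dwell)
  compiled <- compile_schedule(sched, geometry, grid, mat, f_max = f_max)
  # dwell-weighted mean of the (individually normalized) state fields, not
  # renormalized: the equivalence claim compares the switched sequence
  # with exactly the field it time-averages to.
  fsum <- summed_field(compiled)
  sum_compiled <- structure(
    list(forces = list(fsum), dwell = dwell, label = "summed"),
    class = "compiled_schedule")
  ens <- random_ensemble(n, seed, mat = mat)
  sw <- simulate_switched(ens, compiled, duration)
  sm <- simulate_switched(ens, sum_compiled, duration)
  disc <- sqrt(rowSums((sw$positions - sm$positions)^2))
  list(mean_discrepancy = mean(disc), max_discrepancy = max(disc),
       discrepancies = disc, switched = sw$positions,
       summed = sm$positions, wavelength = geometry$wavelength)
}

#' Letter-contrast bench
#'
#' Forms a letter from a random 500-particle ensemble twice per seed:
#' with low-impulse skeleton traps alone, and with the full
#' clearing-plus-patterning recipe, and reports the off-pattern fraction
#' (in percent) for both.
#'
#' @param letter "A", "B" or "C".
#' @param seeds Integer vector of ensemble seeds.
#' @param n Number of particles.
#' @param geometry An [build_circular_array()] geometry.
#' @param height Letter height (m).
#' @param verbose Print stage progress.
#' @return data.frame with one row per seed: `seed`, `pct_outside_traps`
#'   (patterning alone) and `pct_outside_recipe` (full recipe).
#' @export
bench_letter_contrast <- function(letter = "A", seeds = 1, n = 500,
                                  geometry = build_circular_array(),
                                  height = 2.2e-3, verbose = FALSE) {
  skel <- letter_skeleton(letter, height)
  mask <- skeleton_mask(skel, geometry)
  grid <- field_grid(geometry, extent = geometry$chamber_diameter)
  traps_only <- form_letter(geometry, letter, height, clearing = FALSE)
  full <- form_letter(geometry, letter, height, clearing = TRUE, mask = mask)
  rows <- lapply(seeds, function(sd) {
    # the letter study fills the whole chamber with particles; clearing
    # operates chamber-wide
    ens <- random_ensemble(
      n, sd,
      region_radius = geometry$chamber_radius - 2 * particle_material()$radius,
      chamber_radius = geometry$chamber_radius)
    r1 <- run_recipe(traps_only, ens, geometry, grid, verbose = verbose)
    r2 <- run_recipe(full, ens, geometry, grid, verbose = verbose)
    data.frame(seed = sd,
               pct_outside_traps = fraction_outside(r1$ensemble, mask),
               pct_outside_recipe = fraction_outside(r2$ensemble, mask))
  })
  do.call(rbind, rows)
}
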