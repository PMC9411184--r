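#' Seeded random particle ensemble
#'
#' Uniformly distributed particle positions over a disc (by default the
#' central 4 mm patterning region), zero initial velocity. Bit-for-bit
#' reproducible from the seed; the caller's RNG state is left untouched.
#'
#' @param n Particle count (>= 0).
#' @param seed Integer seed.
#' @param region_radius Radius of the seeding disc (m).
#' @param chamber_radius Chamber clamping radius (m).
#' @param mat A [particle_material()] shared by all particles.
#' @return Object of class `ensemble` with `positions`, `velocities`
#'   (n x 2 matrices), `material`, `chamber_radius`, `seed`.
#' @export
random_ensemble <- function(n, seed = 1, region_radius = 2e-3,
                            chamber_radius = 10.98e-3 / 2,
                            mat = particle_material()) {
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  r <- region_radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  structure(
    list(positions = cbind(r * cos(th), r * sin(th)),
         velocities = matrix(0, n, 2),
         material = mat,
         chamber_radius = chamber_radius,
         seed = seed),
    class = "ensemble"
  )
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d particles (seed %s), chamber radius %.2f mm\n",
              nrow(x$positions), x$seed, x$chamber_radius * 1e3))
  invisible(x)
}

#' Trajectory as a tidy data frame
#'
#' Converts the recorded trajectory of a simulated ensemble into long
#' format with columns t, particle_id, x, y.
#'
#' @param ensemble A [simulate_switched()] result with a recorded
#'   trajectory.
#' @return A data.frame.
#' @export
trajectory_as_data_frame <- function(ensemble) {
  tr <- ensemble$trajectory
  if (is.null(tr)) stop("ensemble has no recorded trajectory", call. = FALSE)
  n <- ncol(tr$x)
  data.frame(
    t = rep(tr$t, times = n),
    particle_id = rep(seq_len(n), each = length(tr$t)),
    x = as.vector(tr$x),
    y = as.vector(tr$y)
  )
}

# Minimum distance from each point (n x 2) to a set of segments
# (m x 4 matrix: x1, y1, x2, y2).
dist_to_segments <- function(points, segments) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 2)
  d <- matrix(Inf, nrow(p), nrow(segments))
  for (s in seq_len(nrow(segments))) {
    a <- segments[s, 1:2]
    b <- segments[s, 3:4]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d[, s] <- sqrt((p[, 1] - a[1])^2 + (p[, 2] - a[2])^2)
    } else {
      t0 <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / len2
      t0 <- pmin(1, pmax(0, t0))
      d[, s] <- sqrt((p[, 1] - (a[1] + t0 * ab[1]))^2 +
                     (p[, 2] - (a[2] + t0 * ab[2]))^2)
    }
  }
  apply(d, 1, min)
}

#' Target-shape mask for contrast metrics
#'
#' A polyline skeleton plus an inclusion tolerance and an edge margin. A
#' particle counts as "on pattern" if it is within `tolerance` of the
#' skeleton, and as "at the edge" if it is within `edge_margin` of the
#' chamber boundary; everything else is off-pattern background.
#'
#' Defaults: tolerance lambda/4 (traps localize particles to within a
#' quarter wavelength of the skeleton) and edge margin 2 lambda.
#'
#' @param segments m x 4 matrix of skeleton segments (x1, y1, x2, y2, m),
#'   or a 2-column matrix of polyline vertices (consecutive rows joined).
#' @param tolerance Inclusion tolerance (m).
#' @param edge_margin Edge band width measured inward from the chamber
#'   boundary (m).
#' @param chamber_radius Chamber radius (m).
#' @return Object of class `shape_mask`.
#' @export
shape_mask <- function(segments, tolerance = 0.644e-3 / 4,
                       edge_margin = 2 * 0.644e-3,
                       chamber_radius = 10.98e-3 / 2) {
  if (ncol(segments) == 2) {
    v <- segments
    segments <- cbind(v[-nrow(v), , drop = FALSE], v[-1, , drop = FALSE])
  }
  if (tolerance <= 0) stop("tolerance must be positive", call. = FALSE)
  structure(
    list(segments = segments, tolerance = tolerance,
         edge_margin = edge_margin, chamber_radius = chamber_radius),
    class = "shape_mask"
  )
}

#' Fraction of particles off pattern
#'
#' Percentage of particles that are neither within the mask tolerance of
#' the target skeleton nor within the edge margin of the chamber
#' boundary: the stray background that lowers pattern contrast.
#'
#' @param ensemble An [random_ensemble()] (or an n x 2 position matrix).
#' @param mask A [shape_mask()].
#' @return Percentage in [0, 100].
#' @export
fraction_outside <- function(ensemble, mask) {
  stopifnot(inherits(mask, "shape_mask"))
  pos <- if (inherits(ensemble, "ensemble")) ensemble$positions else ensemble
  if (nrow(pos) == 0) stop("fraction_outside is undefined for an empty ensemble",
                           call. = FALSE)
  on_shape <- dist_to_segments(pos, mask$segments) <= mask$tolerance
  at_edge <- sqrt(rowSums(pos^2)) >= mask$chamber_radius - mask$edge_margin
  100 * mean(!on_shape & !at_edge)
}
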