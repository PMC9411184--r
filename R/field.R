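#' Define a uniform Cartesian field grid
#'
#' Square sampling grid for pressure and force fields, centred on the
#' array centre by default and covering the central 4 mm patterning
#' region. Spacing defaults to lambda/20 and must not exceed lambda/10
#' (the finite-difference resolution floor).
#'
#' @param geometry An [build_circular_array()] geometry.
#' @param extent Side length of the square region covered (m); use
#'   `geometry$chamber_diameter` for full-chamber grids.
#' @param spacing Grid spacing (m).
#' @param center Grid centre, length-2 (m).
#' @return Object of class `field_grid_spec` with coordinate vectors `x`,
#'   `y` (metres) and scalars `spacing`, `nx`, `ny`.
#' @export
field_grid <- function(geometry, extent = 4e-3,
                       spacing = geometry$wavelength / 20,
                       center = c(0, 0)) {
  stopifnot(inherits(geometry, "array_geometry"))
  if (spacing > geometry$wavelength / 10 + 1e-15) {
    stop("grid spacing must be <= lambda/10", call. = FALSE)
  }
  half <- extent / 2
  x <- seq(center[1] - half, center[1] + half, by = spacing)
  y <- seq(center[2] - half, center[2] + half, by = spacing)
  structure(
    list(x = x, y = y, spacing = spacing,
         nx = length(x), ny = length(y), geometry = geometry),
    class = "field_grid_spec"
  )
}

# Rectangular (non-square) grid covering [xlim] x [ylim]; used for the
# localized sub-grids of per-particle manipulation stages.
field_grid_rect <- function(geometry, xlim, ylim,
                            spacing = geometry$wavelength / 20) {
  if (spacing > geometry$wavelength / 10 + 1e-15) {
    stop("grid spacing must be <= lambda/10", call. = FALSE)
  }
  x <- seq(xlim[1], xlim[2], by = spacing)
  y <- seq(ylim[1], ylim[2], by = spacing)
  structure(
    list(x = x, y = y, spacing = spacing,
         nx = length(x), ny = length(y), geometry = geometry),
    class = "field_grid_spec"
  )
}

#' Huygens propagation operator (transfer matrix)
#'
#' Complex matrix H (grid nodes x elements) propagating the per-element
#' source terms to the grid. The entry for field point r and element s is
#' \deqn{H_{rs} = \frac{S_w e^{-i k r_{rs}}}{2\pi\sqrt{r_{rs}}}
#'   \,\mathrm{sinc}\!\left[\frac{a \pi^2 \sin\theta_{rs}}{\lambda}\right]}
#' with `r_rs` the element-to-point distance, `theta_rs` the angle off the
#' element normal, `a` the element width and `sinc(x) = sin(x)/x`
#' (unnormalized, `sinc(0) = 1`). The time-harmonic convention is
#' `exp(+i omega t)`, so `exp(-i k r)` is an outgoing wave; the
#' `1/sqrt(r)` spreading corresponds to 2D (line-source) propagation.
#' `S_w` is a free hydrophone-calibration scale and defaults to 1; all
#' patterning runs normalize the force amplitude downstream instead.
#'
#' Nodes are ordered column-major over (y, x), matching
#' `matrix(ny, nx)` storage of the synthesized field.
#'
#' @param geometry An [build_circular_array()] geometry.
#' @param grid A [field_grid()] spec.
#' @param s_w Source scaling factor.
#' @return Complex matrix of dimension `(ny*nx) x n_elements`, with the
#'   grid spec attached as attribute `grid`.
#' @export
transfer_matrix <- function(geometry, grid, s_w = 1) {
  stopifnot(inherits(geometry, "array_geometry"),
            inherits(grid, "field_grid_spec"))
  pts <- cbind(rep(grid$x, each = grid$ny), rep(grid$y, times = grid$nx))
  n_nodes <- nrow(pts)
  h <- matrix(0i, n_nodes, geometry$n_elements)
  lam <- geometry$wavelength
  a <- geometry$element_width
  for (s in seq_len(geometry$n_elements)) {
    d <- cbind(pts[, 1] - geometry$element_positions[s, 1],
               pts[, 2] - geometry$element_positions[s, 2])
    r <- sqrt(d[, 1]^2 + d[, 2]^2)
    if (any(r == 0)) {
      stop("singular distance: grid node coincides with an element",
           call. = FALSE)
    }
    cos_t <- pmin(1, pmax(-1, (d[, 1] * geometry$element_normals[s, 1] +
                               d[, 2] * geometry$element_normals[s, 2]) / r))
    sin_t <- sqrt(1 - cos_t^2)
    arg <- a * pi^2 * sin_t / lam
    dirv <- ifelse(arg == 0, 1, sin(arg) / ifelse(arg == 0, 1, arg))
    h[, s] <- s_w * exp(-1i * geometry$k * r) / (2 * pi * sqrt(r)) * dirv
  }
  attr(h, "grid") <- grid
  h
}

#' Synthesize a complex pressure field
#'
#' Applies the propagation operator to a drive state:
#' `p = H %*% (amplitude * exp(i phase))`. Synthesis is linear in the
#' drive, so fields superpose.
#'
#' @param h A [transfer_matrix()] operator.
#' @param drive A [drive_state()] with one entry per element.
#' @return Object of class `pressure_field`: the grid coordinates plus a
#'   complex `ny x nx` pressure matrix `p` (Pa) and the geometry.
#' @export
synthesize_pressure <- function(h, drive) {
  grid <- attr(h, "grid")
  if (is.null(grid)) stop("operator is missing its grid attribute", call. = FALSE)
  if (ncol(h) != length(drive$amplitudes)) {
    stop("dimension mismatch between operator and drive", call. = FALSE)
  }
  p <- matrix(as.vector(h %*% drive_complex(drive)), grid$ny, grid$nx)
  structure(
    list(x = grid$x, y = grid$y, spacing = grid$spacing,
         p = p, geometry = grid$geometry, label = drive$label),
    class = "pressure_field"
  )
}

#' @export
print.pressure_field <- function(x, ...) {
  cat(sprintf("pressure field %dx%d, |p| in [%.3g, %.3g] (%s)\n",
              length(x$y), length(x$x), min(Mod(x$p)), max(Mod(x$p)),
              x$label))
  invisible(x)
}

#' Export a pressure field as a data frame
#'
#' Long-format table with columns x, y (m), re_p, im_p (Pa), suitable for
#' CSV export with [utils::write.csv()].
#'
#' @param field A [synthesize_pressure()] result.
#' @return A data.frame.
#' @export
field_as_data_frame <- function(field) {
  stopifnot(inherits(field, "pressure_field"))
  data.frame(
    x = rep(field$x, each = length(field$y)),
    y = rep(field$y, times = length(field$x)),
    re_p = as.vector(Re(field$p)),
    im_p = as.vector(Im(field$p))
  )
}
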