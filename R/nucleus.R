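#' Regular cell-centered simulation grid
#'
#' The domain \eqn{\Omega = [0, Lx] \times [0, Ly]} discretized into
#' \code{nx * ny} cells with centers at \eqn{(i - 1/2) dx, (j - 1/2) dy}.
#' All volume integrals are midpoint Riemann sums with weight
#' \code{dx * dy}. Default lengths are the non-dimensional 1.2 x 1.8 domain
#' (6 x 9 micrometres at the 5-micrometre length scale).
#'
#' @param nx,ny number of cells along x and y.
#' @param Lx,Ly domain lengths (non-dimensional).
#' @return object of class \code{"sim_grid"}.
#' @export
sim_grid <- function(nx, ny, Lx = 1.2, Ly = 1.8) {
  stopifnot(nx >= 2, ny >= 2, Lx > 0, Ly > 0)
  nx <- as.integer(nx); ny <- as.integer(ny)
  g <- list(nx = nx, ny = ny, Lx = Lx, Ly = Ly,
            dx = Lx / nx, dy = Ly / ny,
            x = (seq_len(nx) - 0.5) * (Lx / nx),
            y = (seq_len(ny) - 0.5) * (Ly / ny))
  class(g) <- "sim_grid"
  g
}

#' Prescribed nucleus geometry
#'
#' A time-parameterized ellipse centered in the domain. The semi-axes
#' interpolate linearly from \code{(axisX0, axisY0)} to
#' \code{(axisX1, axisY1)} over \code{[tShrinkStart, tShrinkEnd]} and are
#' constant outside the window; equal endpoints give a static nucleus.
#' \code{eps0} is the squared interface-width parameter of the nucleus
#' field's tanh profile.
#'
#' @param axisX0,axisY0 initial semi-axes (non-dimensional length).
#' @param axisX1,axisY1 final semi-axes (default: initial, i.e. static).
#' @param tShrinkStart,tShrinkEnd shrink window (non-dimensional time).
#' @param eps0 squared interface-width parameter (default 2e-5).
#' @param center ellipse center; default is the domain center, filled in by
#'   \code{\link{make_phi0}} when \code{NULL}.
#' @return object of class \code{"nucleus_geometry"}.
#' @export
nucleus_geometry <- function(axisX0 = 0.5, axisY0 = 0.8,
                             axisX1 = axisX0, axisY1 = axisY0,
                             tShrinkStart = 0, tShrinkEnd = 0,
                             eps0 = 2e-5, center = NULL) {
  stopifnot(axisX0 > 0, axisY0 > 0, axisX1 > 0, axisY1 > 0, eps0 > 0,
            tShrinkStart <= tShrinkEnd)
  geom <- list(axisX0 = axisX0, axisY0 = axisY0,
               axisX1 = axisX1, axisY1 = axisY1,
               tShrinkStart = tShrinkStart, tShrinkEnd = tShrinkEnd,
               eps0 = eps0, center = center)
  class(geom) <- "nucleus_geometry"
  geom
}

#' Semi-axes of the nucleus at time t
#'
#' Linear interpolation of both semi-axes over the shrink window; constant
#' outside it.
#'
#' @param geom a \code{\link{nucleus_geometry}}.
#' @param t non-dimensional time (>= 0).
#' @return numeric vector \code{c(axisX, axisY)}.
#' @export
geometry_at <- function(geom, t) {
  stopifnot(inherits(geom, "nucleus_geometry"))
  if (t <= geom$tShrinkStart || geom$tShrinkEnd == geom$tShrinkStart) {
    if (t <= geom$tShrinkStart) return(c(geom$axisX0, geom$axisY0))
    return(c(geom$axisX1, geom$axisY1))
  }
  if (t >= geom$tShrinkEnd) return(c(geom$axisX1, geom$axisY1))
  w <- (t - geom$tShrinkStart) / (geom$tShrinkEnd - geom$tShrinkStart)
  c((1 - w) * geom$axisX0 + w * geom$axisX1,
    (1 - w) * geom$axisY0 + w * geom$axisY1)
}

#' Nucleus phase-field phi0
#'
#' Builds the prescribed nucleus field: 0 deep inside the ellipse, 1 deep
#' outside, 1/2 on the boundary, with the equilibrium tanh interface profile
#' \eqn{\phi_0 = [1 + \tanh(s / (2 \sqrt2 \sqrt{eps0}))] / 2} where \eqn{s}
#' is a signed-distance surrogate: the normalized elliptical level-set
#' residual rescaled by its local gradient magnitude (exact signed distance
#' is unnecessary at these interface widths).
#'
#' @param geom a \code{\link{nucleus_geometry}}.
#' @param t time at which to evaluate the semi-axes.
#' @param grid a \code{\link{sim_grid}}.
#' @return \code{nx * ny} matrix with values in \[0, 1\].
#' @export
make_phi0 <- function(geom, t, grid) {
  ax <- geometry_at(geom, t)
  ctr <- geom$center
  if (is.null(ctr)) ctr <- c(grid$Lx / 2, grid$Ly / 2)
  # full 10-90% thickness of the tanh profile, in grid cells
  width <- 4 * sqrt(2) * sqrt(geom$eps0) * atanh(0.8)
  if (width / max(grid$dx, grid$dy) < 4) {
    warning(sprintf(
      "nucleus interface width %.3g spans fewer than 4 cells (grid %.3g)",
      width, max(grid$dx, grid$dy)))
  }
  xr <- (grid$x - ctr[1]) / ax[1]
  yr <- (grid$y - ctr[2]) / ax[2]
  q <- sqrt(outer(xr^2, yr^2, `+`))
  # |grad q| = sqrt(x^2/a^4 + y^2/b^4) / q ; signed distance ~ (q-1)/|grad q|
  gq <- sqrt(outer((xr / ax[1])^2, (yr / ax[2])^2, `+`))
  s <- ifelse(q > 1e-9, (q - 1) * q / pmax(gq, 1e-12), -min(ax))
  0.5 * (1 + tanh(s / (2 * sqrt(2) * sqrt(geom$eps0))))
}

#' Nuclear volume
#'
#' \eqn{\int_\Omega [1 - h(\phi_0)] dx}, the area enclosed by the nucleus
#' field.
#'
#' @param phi0 nucleus field matrix.
#' @param grid a \code{\link{sim_grid}}.
#' @return scalar area.
#' @export
nuclear_volume <- function(phi0, grid) {
  sum(1 - interp_h(phi0)) * grid$dx * grid$dy
}

#' Simulation state
#'
#' Container for the N chromosome fields, the heterochromatin field and the
#' prescribed nucleus field on a shared grid at time \code{t}. The nucleus
#' field is externally prescribed and never updated by the gradient flow.
#'
#' @param phi numeric array of dimension \code{c(nx, ny, N)}.
#' @param psi numeric \code{nx * ny} matrix.
#' @param phi0 numeric \code{nx * ny} matrix.
#' @param t current non-dimensional time.
#' @param grid a \code{\link{sim_grid}}.
#' @return object of class \code{"simulation_state"}.
#' @export
simulation_state <- function(phi, psi, phi0, t, grid) {
  stopifnot(inherits(grid, "sim_grid"))
  if (length(dim(phi)) != 3L) stop("'phi' must be an nx x ny x N array")
  shp <- c(grid$nx, grid$ny)
  if (!identical(dim(phi)[1:2], shp) || !identical(dim(psi), shp) ||
      !identical(dim(phi0), shp)) {
    stop("all fields must share the grid shape ", shp[1], " x ", shp[2])
  }
  st <- list(phi = phi, psi = psi, phi0 = phi0, t = t, grid = grid)
  class(st) <- "simulation_state"
  st
}

# Monitored (not enforced) bound check; returns character(0) when clean.
field_bound_violations <- function(state, lo = -0.05, hi = 1.05) {
  msg <- character(0)
  rphi <- range(state$phi)
  rpsi <- range(state$psi)
  if (rphi[1] < lo || rphi[2] > hi) {
    msg <- c(msg, sprintf("phi range [%.4f, %.4f] outside [%g, %g]",
                          rphi[1], rphi[2], lo, hi))
  }
  if (rpsi[1] < lo || rpsi[2] > hi) {
    msg <- c(msg, sprintf("psi range [%.4f, %.4f] outside [%g, %g]",
                          rpsi[1], rpsi[2], lo, hi))
  }
  msg
}
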