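#' Diffuse-interface (intermingling) width
#'
#' Closed-form thickness of the equilibrium tanh interface of a phase-field
#' with squared gradient coefficient \code{epsSq}:
#' \deqn{\delta = 4 \sqrt2\, \sqrt{epsSq}\, \mathrm{artanh}(1 - 2\lambda),}
#' the width of the region where the field lies in
#' \eqn{[\lambda, 1 - \lambda]}. This is the model's measure of
#' intermingling between chromosome territories (\eqn{\delta_\phi}) or
#' between heterochromatin and euchromatin domains (\eqn{\delta_\psi}).
#'
#' @param epsSq squared gradient coefficient (> 0). Pass a non-dimensional
#'   value with \code{L} set to the length scale for dimensional output, or
#'   a dimensional value (e.g. in square micrometres) with \code{L = 1}.
#' @param lambda interface cutoff in (0, 1/2); default 0.15.
#' @param L length scale multiplier applied to the result (default 1).
#' @return interface width (same length units as \code{sqrt(epsSq) * L}).
#' @examples
#' interface_width(4.5e-3)          # micrometres, when epsSq is in um^2
#' interface_width(1.96e-4, L = 5)  # non-dimensional input, 5 um length scale
#' @export
interface_width <- function(epsSq, lambda = 0.15, L = 1) {
  if (any(epsSq <= 0)) stop("'epsSq' must be positive")
  if (any(lambda <= 0) || any(lambda >= 0.5)) {
    stop("'lambda' must lie strictly between 0 and 1/2")
  }
  4 * sqrt(2) * sqrt(epsSq) * atanh(1 - 2 * lambda) * L
}

#' Measure the interface width of a discrete profile
#'
#' Width of the region \eqn{\lambda \le f \le 1 - \lambda} along a 1-D
#' monotone profile, with linear interpolation of the crossing points.
#'
#' @param f numeric vector, monotone profile from ~0 to ~1.
#' @param x coordinates of the samples.
#' @param lambda interface cutoff (default 0.15).
#' @return scalar width.
#' @export
measure_profile_width <- function(f, x, lambda = 0.15) {
  stopifnot(length(f) == length(x))
  if (f[1] > f[length(f)]) { f <- rev(f); x <- rev(-x) }
  crossing <- function(level) {
    i <- which(f[-length(f)] < level & f[-1] >= level)[1]
    if (is.na(i)) stop("profile does not cross level ", level)
    x[i] + (level - f[i]) * (x[i + 1] - x[i]) / (f[i + 1] - f[i])
  }
  crossing(1 - lambda) - crossing(lambda)
}

#' Count heterochromatin clusters
#'
#' Number of connected components of the thresholded set
#' \eqn{\{\psi \ge threshold\}}; 4-connectivity by default.
#'
#' @param field matrix field (typically \eqn{\psi}).
#' @param threshold threshold in (0, 1); default 0.5.
#' @param connectivity 4 or 8.
#' @return integer count (0 when the set is empty).
#' @export
count_clusters <- function(field, threshold = 0.5, connectivity = 4) {
  stopifnot(threshold > 0, threshold < 1, connectivity %in% c(4, 8))
  lab <- label_components(field >= threshold, connectivity)
  max(lab)
}

#' Label connected components of a binary mask
#'
#' Iterative minimum-label propagation over the 4- or 8-neighborhood until
#' a fixed point, then relabeling to consecutive integers. Background is 0.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels.
#' @export
label_components <- function(mask, connectivity = 4) {
  stopifnot(is.matrix(mask))
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(lab)
  big <- sum(mask) + 1L
  repeat {
    w <- lab
    w[!mask] <- big
    nb <- pmin(w[c(1, 1:(nx - 1)), , drop = FALSE],
               w[c(2:nx, nx), , drop = FALSE],
               w[, c(1, 1:(ny - 1)), drop = FALSE],
               w[, c(2:ny, ny), drop = FALSE])
    if (connectivity == 8) {
      nb <- pmin(nb,
                 w[c(1, 1:(nx - 1)), c(1, 1:(ny - 1)), drop = FALSE],
                 w[c(1, 1:(nx - 1)), c(2:ny, ny), drop = FALSE],
                 w[c(2:nx, nx), c(1, 1:(ny - 1)), drop = FALSE],
                 w[c(2:nx, nx), c(2:ny, ny), drop = FALSE])
    }
    newlab <- pmin(w, nb)
    newlab[!mask] <- 0L
    if (identical(newlab, lab)) break
    lab <- newlab
  }
  ids <- sort(unique(lab[lab > 0L]))
  lab[] <- match(lab, c(0L, ids)) - 1L
  lab
}

# signed distance surrogate recovered from the nucleus field's tanh profile
# (positive outside); saturates deep inside/outside.
phi0_signed_distance <- function(phi0, eps0) {
  u <- pmin(pmax(phi0, 1e-12), 1 - 1e-12)
  2 * sqrt(2) * sqrt(eps0) * atanh(2 * u - 1)
}

#' Envelope contact fraction of heterochromatin
#'
#' Mean of \eqn{h(\psi)} over the envelope-adjacent shell: the nucleus
#' interface annulus \eqn{\{\lambda \le \phi_0 \le 1 - \lambda\}} dilated
#' inward by \code{band}. The shell is recovered from the nucleus field's
#' own tanh profile, so only \code{phi0} and its interface parameter
#' \code{eps0} are needed.
#'
#' @param psi heterochromatin field matrix.
#' @param phi0 nucleus field matrix.
#' @param grid a \code{\link{sim_grid}}.
#' @param band inward dilation depth; at least one interface width. The
#'   default is the intrinsic tanh width \eqn{2\sqrt2\,\varepsilon_\psi} of
#'   the heterochromatin interface for \code{epsPsiSq = 6e-4}: the smallest
#'   admissible band, chosen so that the shell samples envelope-adjacent
#'   heterochromatin without engulfing the diffuse boundary of a large
#'   central cluster.
#' @param eps0 nucleus interface parameter (default 2e-5).
#' @param lambda interface cutoff (default 0.15).
#' @return fraction in \[0, 1\].
#' @export
contact_fraction <- function(psi, phi0, grid,
                             band = 2 * sqrt(2) * sqrt(6e-4),
                             eps0 = 2e-5, lambda = 0.15) {
  s <- phi0_signed_distance(phi0, eps0)
  outer_edge <- 2 * sqrt(2) * sqrt(eps0) * atanh(1 - 2 * lambda)
  shell <- s <= outer_edge & s >= -(outer_edge + band)
  if (!any(shell)) stop("empty envelope shell; check phi0/band")
  mean(interp_h(psi)[shell])
}

#' Radial heterochromatin profile
#'
#' Mean \eqn{\psi} versus normalized elliptical radius \eqn{q \in [0, 1]}
#' inside the nucleus.
#'
#' @param psi heterochromatin field matrix.
#' @param geom a \code{\link{nucleus_geometry}}.
#' @param t time at which to take the nucleus axes.
#' @param grid a \code{\link{sim_grid}}.
#' @param nbins number of radial bins.
#' @return data frame with columns \code{q} (bin midpoints) and
#'   \code{meanPsi}.
#' @export
radial_profile <- function(psi, geom, t, grid, nbins = 20) {
  ax <- geometry_at(geom, t)
  ctr <- geom$center
  if (is.null(ctr)) ctr <- c(grid$Lx / 2, grid$Ly / 2)
  q <- sqrt(outer(((grid$x - ctr[1]) / ax[1])^2,
                  ((grid$y - ctr[2]) / ax[2])^2, `+`))
  inside <- q <= 1
  bin <- pmin(floor(q[inside] * nbins) + 1L, nbins)
  data.frame(q = (seq_len(nbins) - 0.5) / nbins,
             meanPsi = as.numeric(tapply(psi[inside], factor(bin,
               levels = seq_len(nbins)), mean)))
}

#' Classify the nuclear architecture of a state
#'
#' Operational endpoint classification from the heterochromatin cluster
#' count and the envelope contact fraction:
#' \itemize{
#'   \item \code{inverted_single}: one cluster and contact fraction < 0.1;
#'   \item \code{inverted_multi}: several clusters and contact fraction < 0.1;
#'   \item \code{conventional}: contact fraction at least half the
#'     heterochromatin area share of the nucleus;
#'   \item \code{intermediate}: anything else.
#' }
#'
#' @param psi,phi0 field matrices.
#' @param grid a \code{\link{sim_grid}}.
#' @param eps0 nucleus interface parameter.
#' @param epsPsiSq heterochromatin gradient coefficient, used for the
#'   default contact band.
#' @param threshold cluster threshold (default 0.5).
#' @param connectivity cluster connectivity (default 4).
#' @param geom optional \code{\link{nucleus_geometry}} for the radial
#'   profile; omitted from the report when \code{NULL}.
#' @param t time for the radial profile axes.
#' @return object of class \code{"architecture_report"}.
#' @export
classify_architecture <- function(psi, phi0, grid, eps0 = 2e-5,
                                  epsPsiSq = 6e-4, threshold = 0.5,
                                  connectivity = 4, geom = NULL, t = 0) {
  band <- 2 * sqrt(2) * sqrt(epsPsiSq)
  ncl <- count_clusters(psi, threshold, connectivity)
  cf <- contact_fraction(psi, phi0, grid, band = band, eps0 = eps0)
  nucVol <- nuclear_volume(phi0, grid)
  heteroShare <- sum(interp_h(psi)) * grid$dx * grid$dy / nucVol
  label <- if (ncl == 1 && cf < 0.1) {
    "inverted_single"
  } else if (ncl > 1 && cf < 0.1) {
    "inverted_multi"
  } else if (cf >= 0.5 * heteroShare) {
    "conventional"
  } else {
    "intermediate"
  }
  rep <- list(nClusters = ncl, contactFraction = cf,
              heteroShare = heteroShare, label = label,
              deltaPhi = NA_real_, deltaPsi = interface_width(epsPsiSq),
              radialProfile = if (is.null(geom)) NULL else
                radial_profile(psi, geom, t, grid))
  class(rep) <- "architecture_report"
  rep
}

#' @export
print.architecture_report <- function(x, ...) {
  cat("Nuclear architecture report\n")
  cat(sprintf("  label: %s\n", x$label))
  cat(sprintf("  heterochromatin clusters: %d\n", x$nClusters))
  cat(sprintf("  envelope contact fraction: %.3f (hetero share %.3f)\n",
              x$contactFraction, x$heteroShare))
  invisible(x)
}

#' Phase boundary of the single-cluster inverted regime
#'
#' From a set of labeled sweep runs, extracts per group (e.g. nuclear size)
#' the minimal interface width whose run ends \code{inverted_single} when
#' sweeping \eqn{\delta_\psi} upward helps (axis \code{"epsPsiSq"}), or the
#' maximal such width when sweeping \eqn{\delta_\phi} (axis
#' \code{"epsPhiSq"}). Groups with no successful run get \code{NA} and a
#' note; non-monotone label sequences are reported raw via the
#' \code{monotone} column.
#'
#' @param results data frame with columns \code{delta} (interface width),
#'   \code{label} (classification), optionally \code{group}.
#' @param axis \code{"epsPsiSq"} (minimal delta reported) or
#'   \code{"epsPhiSq"} (maximal delta reported).
#' @return data frame with one row per group: \code{group},
#'   \code{boundary}, \code{monotone}, \code{nSuccess}.
#' @export
phase_boundary <- function(results, axis = c("epsPsiSq", "epsPhiSq")) {
  axis <- match.arg(axis)
  stopifnot(all(c("delta", "label") %in% names(results)))
  if (is.null(results$group)) results$group <- "all"
  out <- lapply(split(results, results$group), function(d) {
    d <- d[order(d$delta), ]
    ok <- d$label == "inverted_single"
    boundary <- if (!any(ok)) NA_real_ else if (axis == "epsPsiSq") {
      min(d$delta[ok])
    } else {
      max(d$delta[ok])
    }
    # success region should be an up-set (psi axis) / down-set (phi axis)
    mono <- if (!any(ok)) TRUE else if (axis == "epsPsiSq") {
      all(ok[seq.int(which(ok)[1], length(ok))])
    } else {
      all(ok[seq_len(max(which(ok)))])
    }
    data.frame(group = d$group[1], boundary = boundary, monotone = mono,
               nSuccess = sum(ok))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
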