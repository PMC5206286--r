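#' Solver configuration
#'
#' Explicit forward-Euler finite-difference scheme on a regular grid with
#' zero-flux (mirror) boundaries. The reference resolution follows the
#' model's reference discretization: grid spacing 6e-3 (200 x 300 cells on
#' the 1.2 x 1.8 domain) with time step 6e-4.
#'
#' @param dt time step (non-dimensional).
#' @param nx,ny grid size.
#' @param Lx,Ly domain lengths.
#' @param tEnd integration horizon.
#' @param recordEvery recording stride in steps.
#' @return object of class \code{"solver_config"}.
#' @export
solver_config <- function(dt = 6e-4, nx = 200, ny = 300,
                          Lx = 1.2, Ly = 1.8, tEnd = 1, recordEvery = 100) {
  stopifnot(dt > 0, tEnd >= 0, recordEvery >= 1)
  grid <- sim_grid(nx, ny, Lx, Ly)
  cfg <- list(dt = dt, grid = grid, tEnd = tEnd,
              recordEvery = as.integer(recordEvery), boundary = "zero-flux")
  class(cfg) <- "solver_config"
  cfg
}

#' Diffusion stability factor of the explicit scheme
#'
#' \eqn{\max(\varepsilon_\phi^2, \varepsilon_\psi^2) (dt/dx^2 + dt/dy^2)}.
#' The explicit scheme requires this to be at most 1/2; the solver refuses
#' configurations that exceed the bound.
#'
#' @param cfg a \code{\link{solver_config}}.
#' @param params a \code{\link{model_params}}.
#' @return scalar stability factor.
#' @export
stability_factor <- function(cfg, params) {
  g <- cfg$grid
  max(params$epsPhiSq, params$epsPsiSq) * (cfg$dt / g$dx^2 + cfg$dt / g$dy^2)
}

check_stability <- function(cfg, params) {
  f <- stability_factor(cfg, params)
  if (f > 0.5) {
    stop(sprintf(paste0(
      "explicit scheme unstable: stability factor %.4f > 1/2 ",
      "(dt = %g, dx = %g, dy = %g, max eps^2 = %g); reduce dt below %g"),
      f, cfg$dt, cfg$grid$dx, cfg$grid$dy,
      max(params$epsPhiSq, params$epsPsiSq), cfg$dt * 0.5 / f))
  }
  invisible(f)
}

#' Five-point Laplacian with zero-flux boundaries
#'
#' Central differences applied twice; boundary cells use mirrored neighbors
#' (homogeneous Neumann). Exact for quadratics in the interior.
#'
#' @param f matrix field.
#' @param dx,dy grid spacings.
#' @return matrix of the same shape.
#' @export
laplacian <- function(f, dx, dy) {
  nx <- nrow(f); ny <- ncol(f)
  xm <- f[c(1, 1:(nx - 1)), , drop = FALSE]
  xp <- f[c(2:nx, nx), , drop = FALSE]
  ym <- f[, c(1, 1:(ny - 1)), drop = FALSE]
  yp <- f[, c(2:ny, ny), drop = FALSE]
  (xm + xp - 2 * f) / dx^2 + (ym + yp - 2 * f) / dy^2
}

#' Advance the state by one explicit Euler step (reference implementation)
#'
#' Pure-R forward-Euler update of all chromosome fields and the
#' heterochromatin field:
#' \deqn{\phi_m \mathrel{+}= dt\, \bar\mu_\phi [\varepsilon_\phi^2 \nabla^2 \phi_m
#'  + \phi_m (1 - \phi_m)(\phi_m - 1/2 - A_m \phi_m (1 - \phi_m))]}
#' and the analogous update for \eqn{\psi} with \eqn{B}. The nucleus field
#' is refreshed from the geometry before the reaction fields are assembled.
#' This implementation defines the scheme; the compiled stepper used by
#' \code{\link{run_simulation}} reproduces it to floating-point round-off
#' and exists only for speed.
#'
#' @param state a \code{\link{simulation_state}}.
#' @param params a \code{\link{model_params}}.
#' @param sched a \code{\link{conversion_schedule}}.
#' @param geom a \code{\link{nucleus_geometry}}.
#' @param cfg a \code{\link{solver_config}}.
#' @return the state at \code{t + dt}.
#' @export
step_state <- function(state, params, sched, geom, cfg) {
  check_stability(cfg, params)
  g <- state$grid
  phi0 <- suppressWarnings(make_phi0(geom, state$t, g))
  state$phi0 <- phi0
  h0 <- interp_h(phi0)
  nucVol <- sum(1 - h0) * g$dx * g$dy
  chi <- chi_field(state)
  lapH0 <- laplacian(h0, g$dx, g$dy)

  N <- dim(state$phi)[3]
  newphi <- state$phi
  mobPhi <- params$mobility[2]
  mobPsi <- params$mobility[3]
  for (m in seq_len(N)) {
    A <- reaction_A(m, state, params, sched, chi, nucVol)
    u <- state$phi[, , m]
    rhs <- params$epsPhiSq * laplacian(u, g$dx, g$dy) +
      u * (1 - u) * (u - 0.5 - A * u * (1 - u))
    newphi[, , m] <- u + cfg$dt * mobPhi * rhs
  }
  B <- reaction_B(state, params, sched, chi, lapH0)
  u <- state$psi
  newpsi <- u + cfg$dt * mobPsi *
    (params$epsPsiSq * laplacian(u, g$dx, g$dy) +
       u * (1 - u) * (u - 0.5 - B * u * (1 - u)))

  if (!all(is.finite(newphi)) || !all(is.finite(newpsi))) {
    stop(sprintf("non-finite field update at t = %.6g (dt = %g)",
                 state$t, cfg$dt))
  }
  simulation_state(newphi, newpsi, phi0, state$t + cfg$dt, g)
}

#' Run the reaction-diffusion system
#'
#' Integrates the coupled system from the initial state to \code{tEnd},
#' recording per-chromosome volumes, energy terms, heterochromatin cluster
#' count, envelope contact fraction and nuclear volume every
#' \code{recordEvery} steps. Deterministic given configuration and initial
#' state. Field bounds are monitored (not enforced): excursions outside
#' \[-0.05, 1.05\] are collected in the result's \code{boundViolations}.
#'
#' @inheritParams step_state
#' @param use_compiled use the compiled stepper (default) or the pure-R
#'   reference stepper.
#' @param progress print progress lines every record.
#' @return object of class \code{"chromsim"}: a list with \code{record}
#'   (data frame of the time series), \code{final}
#'   (\code{\link{simulation_state}}), the configuration objects, and
#'   \code{boundViolations}.
#' @export
run_simulation <- function(state, params, sched, geom, cfg,
                           use_compiled = TRUE, progress = FALSE) {
  check_stability(cfg, params)
  stopifnot(identical(state$grid$nx, cfg$grid$nx),
            identical(state$grid$ny, cfg$grid$ny))
  nsteps_total <- max(0L, as.integer(round((cfg$tEnd - state$t) / cfg$dt)))
  stride <- cfg$recordEvery
  band <- 2 * sqrt(2) * sqrt(params$epsPsiSq)

  rec <- list()
  violations <- character(0)
  record_row <- function(st) {
    vols <- volumes(st)
    en <- total_energy(st, params, sched)
    ncl <- count_clusters(st$psi, 0.5)
    cf <- tryCatch(
      contact_fraction(st$psi, st$phi0, st$grid, band = band,
                       eps0 = geom$eps0),
      error = function(e) NA_real_)
    c(t = st$t, stats::setNames(vols$V, paste0("V", seq_along(vols$V))),
      stats::setNames(vols$v, paste0("v", seq_along(vols$v))),
      en, nClusters = ncl, contactFraction = cf,
      nuclearVolume = nuclear_volume(st$phi0, st$grid))
  }

  st <- state
  st$phi0 <- suppressWarnings(make_phi0(geom, st$t, st$grid))
  rec[[1]] <- record_row(st)
  done <- 0L
  while (done < nsteps_total) {
    chunk <- min(stride, nsteps_total - done)
    if (use_compiled) {
      st <- advance_compiled(st, params, sched, geom, cfg, chunk)
    } else {
      for (k in seq_len(chunk)) st <- step_state(st, params, sched, geom, cfg)
    }
    done <- done + chunk
    rec[[length(rec) + 1L]] <- record_row(st)
    v <- field_bound_violations(st)
    if (length(v)) {
      violations <- c(violations,
                      sprintf("t = %.5g: %s", st$t, paste(v, collapse = "; ")))
    }
    if (progress) {
      message(sprintf("t = %.5g / %.5g  clusters = %d", st$t, cfg$tEnd,
                      rec[[length(rec)]][["nClusters"]]))
    }
  }
  record <- as.data.frame(do.call(rbind, rec))
  out <- list(record = record, final = st, params = params, sched = sched,
              geom = geom, cfg = cfg, boundViolations = violations)
  class(out) <- "chromsim"
  out
}

# thin wrapper around the C++ stepper; keeps argument marshalling in one place
advance_compiled <- function(state, params, sched, geom, cfg, nsteps) {
  g <- state$grid
  ctr <- geom$center
  if (is.null(ctr)) ctr <- c(g$Lx / 2, g$Ly / 2)
  schedC <- list(
    regime = if (sched$regime == "inverted") 1L else 0L,
    VbarM = sched$VbarM,
    vbarM = if (is.null(sched$vbarM)) numeric(sched$N) else sched$vbarM,
    r = sched$r,
    rhoM0 = if (is.null(sched$rhoM0)) numeric(sched$N) else sched$rhoM0,
    rhoBarM = if (is.null(sched$rhoBarM)) numeric(sched$N) else sched$rhoBarM,
    alpha1 = sched$alpha1, alpha2 = sched$alpha2, tStar = sched$tStar,
    variant = if (sched$variant == "saturating") 1L else 0L)
  geomC <- list(ax0 = geom$axisX0, ay0 = geom$axisY0,
                ax1 = geom$axisX1, ay1 = geom$axisY1,
                ts0 = geom$tShrinkStart, ts1 = geom$tShrinkEnd,
                eps0 = geom$eps0, cx = ctr[1], cy = ctr[2])
  res <- pf_advance(state$phi, state$psi, state$t, as.integer(nsteps),
                    unclass(params), schedC, geomC,
                    list(dt = cfg$dt, dx = g$dx, dy = g$dy,
                         nx = g$nx, ny = g$ny))
  if (!res$finite) {
    stop(sprintf("non-finite field update at t = %.6g (dt = %g)",
                 res$t, cfg$dt))
  }
  simulation_state(res$phi, res$psi, res$phi0, res$t, g)
}

#' @export
print.chromsim <- function(x, ...) {
  n <- nrow(x$record)
  fin <- x$record[n, ]
  cat("Multi-phase-field chromatin simulation\n")
  cat(sprintf("  regime: %s, N = %d chromosomes, grid %d x %d, dt = %g\n",
              x$sched$regime, dim(x$final$phi)[3],
              x$final$grid$nx, x$final$grid$ny, x$cfg$dt))
  cat(sprintf("  integrated to t = %.4g (%d records)\n", x$final$t, n))
  cat(sprintf("  final: E = %.5g, clusters = %d, contact fraction = %.3f\n",
              fin$E, fin$nClusters, fin$contactFraction))
  if (length(x$boundViolations)) {
    cat(sprintf("  %d field-bound excursions logged\n",
                length(x$boundViolations)))
  }
  invisible(x)
}

#' @export
summary.chromsim <- function(object, ...) {
  rep <- classify_architecture(object$final$psi, object$final$phi0,
                               object$final$grid, eps0 = object$geom$eps0,
                               epsPsiSq = object$params$epsPsiSq)
  n <- nrow(object$record)
  structure(list(report = rep,
                 tFinal = object$final$t,
                 energyDrop = object$record$E[1] - object$record$E[n],
                 record = object$record,
                 boundViolations = object$boundViolations),
            class = "summary.chromsim")
}

#' @export
print.summary.chromsim <- function(x, ...) {
  print(x$report)
  cat(sprintf("Total energy decreased by %.5g over [0, %.4g]\n",
              x$energyDrop, x$tFinal))
  invisible(x)
}

#' Composite field image of a simulation state
#'
#' Renders the standard composite: nucleus interior in blue, chromosome
#' territories in green, heterochromatin in red.
#'
#' @param x a \code{"chromsim"} object.
#' @param state optional state to render (default: the final state).
#' @param ... unused.
#' @export
plot.chromsim <- function(x, state = x$final, ...) {
  render_state(state, main = sprintf("t = %.4g", state$t))
  invisible(x)
}

#' @rdname plot.chromsim
#' @param main plot title.
#' @export
render_state <- function(state, main = NULL) {
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  chi <- clamp01(chi_field(state))
  red <- clamp01(interp_h(state$psi))
  blue <- clamp01(1 - interp_h(state$phi0))
  green <- clamp01(chi - red)
  img <- grDevices::rgb(red, green, 0.45 * blue)
  dim(img) <- dim(red)
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(0, state$grid$Lx), ylim = c(0, state$grid$Ly),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::rasterImage(t(img)[state$grid$ny:1, , drop = FALSE],
                        0, 0, state$grid$Lx, state$grid$Ly,
                        interpolate = FALSE)
  invisible(NULL)
}
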