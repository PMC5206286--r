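# Seeded initial conditions and the scenario preset library.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Angular-sector initial condition
#'
#' Partitions the nucleus interior into N angular sectors ("slices of
#' pizza") with a seeded random angular offset, sets each chromosome field
#' to a smoothed indicator of its sector, and places each chromosome's
#' heterochromatin as a smoothed band at the nuclear-periphery end of the
#' sector covering approximately \code{heteroFraction} of the sector area.
#' Sector and band boundaries carry the equilibrium tanh profile of the
#' corresponding field so that early steps are not dominated by interface
#' relaxation. Inside the nucleus the territory occupancies sum to ~1.
#'
#' @param N number of chromosomes (>= 1).
#' @param geom a \code{\link{nucleus_geometry}}.
#' @param grid a \code{\link{sim_grid}}.
#' @param seed integer seed for the angular offset and fraction draws.
#' @param heteroFraction either length-N fractions in \[0, 1\], or a
#'   length-2 range from which one fraction per chromosome is drawn
#'   uniformly (default \code{c(0.23, 0.28)}).
#' @param epsPhiSq,epsPsiSq squared gradient coefficients setting the
#'   smoothing widths of territory and heterochromatin boundaries.
#' @return a \code{\link{simulation_state}} at t = 0.
#' @export
sector_init <- function(N, geom, grid, seed = 101L,
                        heteroFraction = c(0.23, 0.28),
                        epsPhiSq = 2e-4, epsPsiSq = 6e-4) {
  stopifnot(N >= 1)
  draws <- with_seed(seed, {
    theta0 <- stats::runif(1, 0, 2 * pi)
    frac <- if (length(heteroFraction) == N && N != 2) {
      heteroFraction
    } else if (length(heteroFraction) == 2) {
      stats::runif(N, heteroFraction[1], heteroFraction[2])
    } else {
      rep_len(heteroFraction, N)
    }
    list(theta0 = theta0, frac = frac)
  })
  frac <- draws$frac
  if (any(frac < 0) || any(frac > 1)) {
    stop("hetero fractions must lie in [0, 1]")
  }

  ax <- geometry_at(geom, 0)
  ctr <- geom$center
  if (is.null(ctr)) ctr <- c(grid$Lx / 2, grid$Ly / 2)
  phi0 <- make_phi0(geom, 0, grid)
  interior <- 1 - phi0

  X <- matrix(grid$x, grid$nx, grid$ny) - ctr[1]
  Y <- matrix(grid$y, grid$nx, grid$ny, byrow = TRUE) - ctr[2]
  theta <- atan2(Y, X)
  rr <- sqrt(X^2 + Y^2)
  xr <- X / ax[1]; yr <- Y / ax[2]
  q <- sqrt(xr^2 + yr^2)
  gq <- sqrt((xr / ax[1])^2 + (yr / ax[2])^2)

  wphi <- 2 * sqrt(2) * sqrt(epsPhiSq)
  wpsi <- 2 * sqrt(2) * sqrt(epsPsiSq)
  sig <- function(d, w) 0.5 * (1 + tanh(d / w))
  wrap <- function(a) ((a + pi) %% (2 * pi)) - pi

  phi <- array(0, dim = c(grid$nx, grid$ny, N))
  psi <- matrix(0, grid$nx, grid$ny)
  # angular inset of the heterochromatin dome from the sector boundaries
  # (one psi interface arc at the band's typical radius), so that each
  # chromosome carries a distinct peripheral dome rather than all domes
  # joining into one ring; the band deepens to keep the area fraction.
  rbar <- 0.7 * sqrt(ax[1] * ax[2])
  dtheta <- if (N == 1L) 0 else wpsi / rbar
  coverage <- max(1 - dtheta * N / pi, 0.1)
  for (m in seq_len(N)) {
    if (N == 1L) {
      sector <- matrix(1, grid$nx, grid$ny)
      dome <- sector
    } else {
      lo <- draws$theta0 + 2 * pi * (m - 1) / N
      hi <- draws$theta0 + 2 * pi * m / N
      mid <- (lo + hi) / 2
      # arc-length distances to the two sector boundaries
      d1 <- rr * (wrap(theta - mid) + pi / N)
      d2 <- rr * (pi / N - wrap(theta - mid))
      sector <- sig(d1, wphi) * sig(d2, wphi)
      dome <- sig(d1 - rr * dtheta, wpsi) * sig(d2 - rr * dtheta, wpsi)
    }
    phi[, , m] <- interior * sector
    # peripheral band occupying ~frac of the sector area: q >= sqrt(1 - f/c)
    qm <- sqrt(max(1 - frac[m] / coverage, 0))
    sdist <- (q - qm) * q / pmax(gq, 1e-12)
    psi <- psi + interior * dome * sig(sdist, wpsi)
  }
  st <- simulation_state(phi, psi, phi0, 0, grid)
  attr(st, "heteroFraction") <- frac
  st
}

#' Resolution tiers
#'
#' Grid and time-step combinations. \code{"reference"} is the reference
#' discretization (grid spacing 6e-3, dt 6e-4, i.e. 200 x 300 cells);
#' \code{"scaled_down"} halves the resolution (100 x 150) and
#' \code{"coarse"} reduces it further (60 x 90), both with dt rescaled in
#' proportion to the cell area so the diffusion stability factor of the
#' reference scheme is preserved.
#'
#' @param tier one of \code{"reference"}, \code{"scaled_down"},
#'   \code{"coarse"}.
#' @param tEnd integration horizon.
#' @param recordEvery recording stride in steps; default records ~every 2
#'   time units.
#' @param dt optional time-step override (scenarios with a strong
#'   envelope-affinity term need a smaller step than the tier default,
#'   whose reaction terms scale with the inverse square of the nucleus
#'   interface width).
#' @return a \code{\link{solver_config}}.
#' @export
tier_config <- function(tier = c("scaled_down", "reference", "coarse"),
                        tEnd = 1, recordEvery = NULL, dt = NULL) {
  tier <- match.arg(tier)
  spec <- switch(tier,
    reference = list(nx = 200L, ny = 300L, dt = 6e-4),
    scaled_down = list(nx = 100L, ny = 150L, dt = 2.4e-3),
    coarse = list(nx = 60L, ny = 90L, dt = 6e-4 * ((1.2 / 60) / 6e-3)^2))
  if (!is.null(dt)) spec$dt <- dt
  if (is.null(recordEvery)) recordEvery <- max(1L, round(2 / spec$dt))
  solver_config(dt = spec$dt, nx = spec$nx, ny = spec$ny,
                tEnd = tEnd, recordEvery = recordEvery)
}

# reference nucleus: 5 x 8 um diameters at L = 5 um
base_axes <- c(0.5, 0.8)
# circle of 60% of the initial elliptical area
circle60 <- sqrt(0.6 * base_axes[1] * base_axes[2])
# P28 analogue (28 d at T = 5 h): end of the nuclear shrink window
t_p28 <- 134.4
# day-3 analogue: conventional-architecture fixture horizon
t_day3 <- 14.4

shrink_geom <- function(cutoff, shape = c("circle", "ellipse"),
                        tEnd = t_p28) {
  shape <- match.arg(shape)
  if (shape == "circle") {
    rf <- sqrt(cutoff * base_axes[1] * base_axes[2])
    nucleus_geometry(base_axes[1], base_axes[2], rf, rf, 0, tEnd)
  } else {
    nucleus_geometry(base_axes[1], base_axes[2],
                     sqrt(cutoff) * base_axes[1], sqrt(cutoff) * base_axes[2],
                     0, tEnd)
  }
}

static_geom <- function() nucleus_geometry(base_axes[1], base_axes[2])

#' Names of the packaged scenario presets
#' @return character vector.
#' @export
preset_names <- function() {
  c("fig3a", "fig3b", "fig4", "fig5a", "fig5b", "fig5c", "fig5d",
    "fig6a1", "fig6a2", "fig6b1", "fig6b2", "fig6b3", "fig7")
}

#' Scenario presets
#'
#' Frozen parameter sets for the packaged scenarios, transcribed from the
#' corresponding simulation setups: the conventional-architecture runs
#' (\code{fig3a} strong, \code{fig3b} weak territory separation, each with
#' an \code{affinity_pos} and an \code{affinity_zero} arm), the full
#' conventional-to-inverted reorganization (\code{fig4}), the ablation
#' arms of the five reorganization conditions (\code{fig5a}-\code{fig5d}),
#' the nuclear size/shape comparisons (\code{fig6*}) and the
#' intermingling-width study with the saturating conversion variant
#' (\code{fig7}).
#'
#' Inverted-regime presets start from the saved day-3 state of a
#' conventional run (regenerated on demand by
#' \code{\link{conventional_fixture}}, never shipped as data); their
#' per-chromosome volume targets and initial conversion fractions are
#' measured from that state when the run is assembled by
#' \code{\link{build_run}}.
#'
#' @param name one of \code{\link{preset_names}}.
#' @param arm scenario arm where applicable: \code{"affinity_pos"} /
#'   \code{"affinity_zero"} for fig3; \code{"fixed"} / \code{"circle"} /
#'   \code{"ellipse"} for the fig5/fig6 geometry arms.
#' @return object of class \code{"scenario_preset"}.
#' @export
preset <- function(name, arm = NULL) {
  if (!name %in% preset_names()) {
    stop("unknown preset '", name, "'; available: ",
         paste(preset_names(), collapse = ", "))
  }
  ps <- switch(name,
    fig3a = conv_preset(betaPhi = 8 / 3, betaPsi = 8 / 3, arm = arm),
    fig3b = conv_preset(betaPhi = 2, betaPsi = 2 / 3, arm = arm),
    fig4 = inv_preset(
      params = model_params(alpha0 = 25 / 6, alphaV = 10 / 6,
                            alphav = 20 / 3, beta0 = 5 / 3, betaPhi = 1,
                            betaPsi = 2 / 3, gamma = 0,
                            epsPhiSq = 2e-4, epsPsiSq = 6e-4),
      geom = shrink_geom(0.6, "circle"), r = 0.6,
      rhoBarM = c(0.35, 0.4, 0.4, 0.35, 0.15, 0.15, 0.35, 0.35),
      alpha1 = c(rep(120, 6), rep(150, 2)), alpha2 = 0.03,
      tStar = c(rep(120, 6), rep(150, 2))),
    fig5a = {
      p <- preset("fig4"); p$name <- "fig5a"
      p$geom <- static_geom(); p$sched$r <- 1; p
    },
    fig5b = {
      p <- fig5_geom_arm("fig5b", arm, cutoff = 0.8)
      p$sched$rhoBarM <- rep(0, 8); p
    },
    fig5c = {
      p <- fig5_geom_arm("fig5c", arm, cutoff = 0.8)
      p$params$gamma <- 0.022; p
    },
    fig5d = {
      # nuclear area cut BY 40% (final 60%): the nucleus must stay larger
      # than the chromatin target (49% of P0) for unoccupied space to exist
      p <- fig5_geom_arm("fig5d", arm, cutoff = 0.6)
      p$params$alpha0 <- 0; p$sched$r <- 0.49; p
    },
    fig6a1 = {
      p <- preset("fig4"); p$name <- "fig6a1"
      if (identical(arm, "fixed")) { p$geom <- static_geom(); p$sched$r <- 1 }
      p$arm <- if (is.null(arm)) "shrink" else arm; p
    },
    fig6a2 = inv_preset(
      params = model_params(alpha0 = 25 / 6, alphaV = 5 / 3,
                            alphav = 20 / 3, beta0 = 5 / 3, betaPhi = 1,
                            betaPsi = 2 / 3, gamma = 0,
                            epsPhiSq = 3e-4, epsPsiSq = 6e-4),
      geom = shrink_geom(0.6, shape_arm(arm)), r = 0.6,
      rhoBarM = c(0.35, 0.15, 0.2, 0.35, 0.15, 0.15, 0.6, 0.6),
      alpha1 = c(rep(120, 6), rep(80, 2)), alpha2 = 0.03,
      tStar = c(rep(120, 6), rep(80, 2)), name = "fig6a2", arm = arm),
    fig6b1 = { p <- preset("fig4", arm); p$name <- "fig6b1"
      p$geom <- shrink_geom(0.6, shape_arm(arm)); p },
    fig6b2 = { p <- preset("fig6a2", arm); p$name <- "fig6b2"; p },
    fig6b3 = inv_preset(
      params = model_params(alpha0 = 25 / 6, alphaV = 5 / 3,
                            alphav = 20 / 3, beta0 = 5 / 3, betaPhi = 1,
                            betaPsi = 2 / 3, gamma = 0,
                            epsPhiSq = 2e-4, epsPsiSq = 4e-4),
      geom = shrink_geom(0.6, shape_arm(arm)), r = 0.6,
      rhoBarM = c(0.1, 0.1, 0.0, 0.0, 0.2, 0.1, 0.2, 0.2),
      alpha1 = c(rep(150, 6), rep(250, 2)), alpha2 = 0.03,
      tStar = c(rep(150, 6), rep(250, 2)), name = "fig6b3", arm = arm),
    fig7 = inv_preset(
      params = model_params(alpha0 = 25 / 6, alphaV = 5 / 3,
                            alphav = 20 / 3, beta0 = 5 / 3, betaPhi = 1,
                            betaPsi = 2 / 3, gamma = 0,
                            epsPhiSq = 2e-4, epsPsiSq = 7.84e-4),
      geom = shrink_geom(0.6, "circle"), r = 0.6,
      rhoBarM = c(0.05, 0.3, 0.3, 0.05, 0.15, 0.15, 0.3, 0.3),
      variant = "saturating", name = "fig7"))
  if (is.null(ps$name)) ps$name <- name
  class(ps) <- "scenario_preset"
  ps
}

shape_arm <- function(arm) {
  if (identical(arm, "ellipse")) "ellipse" else "circle"
}

conv_preset <- function(betaPhi, betaPsi, arm) {
  arm <- if (is.null(arm)) "affinity_pos" else
    match.arg(arm, c("affinity_pos", "affinity_zero"))
  list(name = NULL, arm = arm,
       params = model_params(alpha0 = 25 / 6, alphaV = 2, alphav = 2,
                             beta0 = 5 / 3, betaPhi = betaPhi,
                             betaPsi = betaPsi,
                             gamma = if (arm == "affinity_pos") 0.0022 / 3
                                     else 0,
                             epsPhiSq = 2e-4, epsPsiSq = 4e-4),
       geom = static_geom(),
       sched = list(regime = "conventional",
                    heteroFraction = c(0.23, 0.28)),
       seed = 101L, tEnd = 28.8, init = "sector")
}

fig5_geom_arm <- function(name, arm, cutoff) {
  arm <- if (is.null(arm)) "fixed" else
    match.arg(arm, c("fixed", "circle", "ellipse"))
  p <- preset("fig4")
  p$name <- name
  p$arm <- arm
  if (arm == "fixed") {
    p$geom <- static_geom()
    p$sched$r <- 1
  } else {
    p$geom <- shrink_geom(cutoff, arm)
    p$sched$r <- cutoff
  }
  p
}

inv_preset <- function(params, geom, r, rhoBarM,
                       alpha1 = 120, alpha2 = 0.03, tStar = 120,
                       variant = "sigmoid", name = NULL, arm = NULL) {
  list(name = name, arm = arm, params = params, geom = geom,
       sched = list(regime = "inverted", r = r, rhoBarM = rhoBarM,
                    alpha1 = alpha1, alpha2 = alpha2, tStar = tStar,
                    variant = variant),
       seed = 101L, tEnd = 1296, init = "conventional_day3")
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat(sprintf("Scenario preset '%s'%s (%s regime, init: %s)\n", x$name,
              if (is.null(x$arm)) "" else paste0(" [", x$arm, "]"),
              x$sched$regime, x$init))
  invisible(x)
}

fixture_cache <- new.env(parent = emptyenv())

#' Conventional-architecture starting state (day-3 analogue)
#'
#' Runs the weak-separation conventional scenario with positive
#' envelope affinity from its angular-sector initial condition to the
#' day-3 time point and returns the state, which the inverted-regime
#' presets use as their starting point. The state is regenerated (and
#' cached per session), never shipped as data.
#'
#' @param cfg a \code{\link{solver_config}} defining the resolution.
#' @param seed integer seed for the sector initial condition.
#' @return a \code{\link{simulation_state}} at the day-3 time point.
#' @export
conventional_fixture <- function(cfg, seed = 101L) {
  key <- sprintf("%d_%d_%g_%d", cfg$grid$nx, cfg$grid$ny, cfg$dt, seed)
  if (!is.null(fixture_cache[[key]])) return(fixture_cache[[key]])
  ps <- preset("fig3b", arm = "affinity_pos")
  run <- build_run(ps, cfg = solver_config(dt = cfg$dt, nx = cfg$grid$nx,
                                           ny = cfg$grid$ny, tEnd = t_day3,
                                           recordEvery = 100000L),
                   tEnd = t_day3, seed = seed)
  sim <- run_simulation(run$state, run$params, run$sched, run$geom, run$cfg)
  st <- sim$final
  st$t <- 0  # the reorganization clock starts at the day-3 state
  fixture_cache[[key]] <- st
  st
}

#' Assemble a runnable configuration from a preset
#'
#' Resolves a \code{\link{preset}} into concrete objects: builds the
#' initial state (angular sectors for conventional presets, the
#' regenerated day-3 conventional state for inverted presets), measures
#' the per-chromosome volume targets and initial conversion fractions
#' where the schedule calls for them, and attaches the solver
#' configuration.
#'
#' @param ps a \code{\link{preset}}.
#' @param tier resolution tier (used when \code{cfg} is missing).
#' @param cfg optional \code{\link{solver_config}} overriding the tier.
#' @param tEnd optional horizon override.
#' @param seed optional seed override.
#' @return list with \code{state}, \code{params}, \code{sched},
#'   \code{geom}, \code{cfg}, \code{preset}.
#' @export
build_run <- function(ps, tier = "scaled_down", cfg = NULL, tEnd = NULL,
                      seed = NULL) {
  stopifnot(inherits(ps, "scenario_preset") || is.list(ps))
  if (is.null(seed)) seed <- ps$seed
  if (is.null(tEnd)) tEnd <- ps$tEnd
  if (is.null(cfg)) cfg <- tier_config(tier, tEnd = tEnd)
  else { cfg$tEnd <- tEnd }

  if (ps$init == "sector") {
    state <- sector_init(ps$params$N, ps$geom, cfg$grid, seed = seed,
                         heteroFraction = ps$sched$heteroFraction,
                         epsPhiSq = ps$params$epsPhiSq,
                         epsPsiSq = ps$params$epsPsiSq)
    vols <- volumes(state)
    nucVol <- nuclear_volume(state$phi0, cfg$grid)
    frac <- attr(state, "heteroFraction")
    sched <- conversion_schedule("conventional",
                                 VbarM = rep(nucVol / ps$params$N,
                                             ps$params$N),
                                 vbarM = frac * vols$V)
  } else {
    state <- conventional_fixture(cfg, seed = seed)
    vols <- volumes(state)
    nucVol <- nuclear_volume(state$phi0, cfg$grid)
    sched <- conversion_schedule("inverted",
                                 VbarM = rep(nucVol / ps$params$N,
                                             ps$params$N),
                                 r = ps$sched$r,
                                 rhoM0 = vols$v / vols$V,
                                 rhoBarM = ps$sched$rhoBarM,
                                 alpha1 = ps$sched$alpha1,
                                 alpha2 = ps$sched$alpha2,
                                 tStar = ps$sched$tStar,
                                 variant = ps$sched$variant)
  }
  list(state = state, params = ps$params, sched = sched, geom = ps$geom,
       cfg = cfg, preset = ps, seed = seed)
}

#' Run a packaged scenario preset
#'
#' Convenience wrapper: \code{\link{preset}} + \code{\link{build_run}} +
#' \code{\link{run_simulation}}.
#'
#' @inheritParams preset
#' @inheritParams build_run
#' @param ... passed to \code{\link{run_simulation}}.
#' @return a \code{"chromsim"} object.
#' @export
run_preset <- function(name, arm = NULL, tier = "scaled_down", tEnd = NULL,
                       cfg = NULL, seed = NULL, ...) {
  run <- build_run(preset(name, arm), tier = tier, cfg = cfg, tEnd = tEnd,
                   seed = seed)
  run_simulation(run$state, run$params, run$sched, run$geom, run$cfg, ...)
}

#' Parameter sweeps over a preset
#'
#' One preset per grid point, identical to the base otherwise. Supports the
#' phase-diagram axes: the squared gradient coefficients and an overall
#' nucleus size scale. Values violating the stability guard at the preset
#' tier's time step are rejected with the required time step; duplicated
#' values are dropped with a warning.
#'
#' @param name base preset name.
#' @param axis \code{"epsPhiSq"}, \code{"epsPsiSq"} or
#'   \code{"nucleusScale"}.
#' @param values numeric grid.
#' @param arm optional preset arm.
#' @param tier tier whose time step the stability guard is checked against.
#' @return list of presets, one per value, each carrying \code{sweepValue}.
#' @export
sweep_presets <- function(name, axis = c("epsPsiSq", "epsPhiSq",
                                         "nucleusScale"),
                          values, arm = NULL, tier = "scaled_down") {
  axis <- match.arg(axis)
  if (anyDuplicated(values)) {
    warning("duplicated sweep values dropped")
    values <- unique(values)
  }
  cfg <- tier_config(tier)
  lapply(values, function(v) {
    ps <- preset(name, arm)
    if (axis %in% c("epsPhiSq", "epsPsiSq")) {
      ps$params[[axis]] <- v
      f <- stability_factor(cfg, ps$params)
      if (f > 0.5) {
        stop(sprintf(
          "sweep value %g violates the stability guard (factor %.3f); dt <= %g required",
          v, f, cfg$dt * 0.5 / f))
      }
    } else {
      stopifnot(v > 0)
      g <- ps$geom
      ps$geom <- nucleus_geometry(g$axisX0 * v, g$axisY0 * v,
                                  g$axisX1 * v, g$axisY1 * v,
                                  g$tShrinkStart, g$tShrinkEnd, g$eps0,
                                  g$center)
    }
    ps$sweepValue <- v
    ps$sweepAxis <- axis
    ps
  })
}
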