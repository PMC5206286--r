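# Run directories, configuration round-tripping, and format writers.

#' Serialize a resolved run configuration
#'
#' Flattens a \code{\link{build_run}} result (minus the fields) into a
#' plain list of numeric/character entries that round-trips through YAML
#' identically: preset name and arm, every model parameter, the schedule,
#' the nucleus geometry, the solver configuration and the seed. Units are
#' non-dimensional throughout (multiply lengths by L = 5 um and times by
#' T = 5 h for physical units).
#'
#' @param run a list from \code{\link{build_run}}.
#' @return a named list safe for \code{yaml::write_yaml}.
#' @export
run_config <- function(run) {
  ps <- run$preset
  g <- run$cfg$grid
  geom <- run$geom
  list(
    preset = ps$name,
    arm = if (is.null(ps$arm)) NA_character_ else ps$arm,
    seed = as.integer(run$seed),
    params = unclass(run$params)[c("alpha0", "alphaV", "alphav", "beta0",
                                   "betaPhi", "betaPsi", "gamma",
                                   "epsPhiSq", "epsPsiSq", "mobility", "N")],
    sched = list(regime = run$sched$regime,
                 VbarM = run$sched$VbarM,
                 vbarM = run$sched$vbarM,
                 r = run$sched$r,
                 rhoM0 = run$sched$rhoM0,
                 rhoBarM = run$sched$rhoBarM,
                 alpha1 = run$sched$alpha1,
                 alpha2 = run$sched$alpha2,
                 tStar = run$sched$tStar,
                 variant = run$sched$variant),
    geom = list(axisX0 = geom$axisX0, axisY0 = geom$axisY0,
                axisX1 = geom$axisX1, axisY1 = geom$axisY1,
                tShrinkStart = geom$tShrinkStart,
                tShrinkEnd = geom$tShrinkEnd, eps0 = geom$eps0),
    solver = list(dt = run$cfg$dt, nx = g$nx, ny = g$ny, Lx = g$Lx,
                  Ly = g$Ly, tEnd = run$cfg$tEnd,
                  recordEvery = run$cfg$recordEvery,
                  boundary = run$cfg$boundary))
}

#' Write / read a run configuration
#'
#' YAML serialization of \code{\link{run_config}}; reading restores the
#' same list (numeric fields identical).
#'
#' @param config a \code{\link{run_config}} list.
#' @param path file path.
#' @return \code{read_run_config} returns the configuration list.
#' @export
write_run_config <- function(config, path) {
  # YAML emitters truncate doubles; format them at full precision so the
  # round trip is the identity on every numeric field
  fmt <- function(x) {
    if (is.list(x)) return(lapply(x, fmt))
    if (is.double(x)) {
      s <- vapply(x, function(v) sprintf("%.17g", v), character(1))
      plain <- !grepl("[.eE]", s)
      s[plain] <- paste0(s[plain], ".0")  # keep the float type on re-read
      return(s)
    }
    x
  }
  txt <- yaml::as.yaml(fmt(config))
  # the emitter quotes numeric-looking strings; strip the quotes so the
  # values re-read as numbers
  txt <- gsub("'(-?(?:[0-9]+\\.[0-9]*(?:[eE][+-]?[0-9]+)?|[0-9.]+[eE][+-]?[0-9]+))'",
              "\\1", txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Rebuild runnable objects from a configuration
#'
#' Inverse of \code{\link{run_config}} up to the initial state: returns
#' \code{params}, \code{sched}, \code{geom} and \code{cfg} objects.
#'
#' @param config a configuration list as returned by
#'   \code{\link{read_run_config}}.
#' @return list with \code{params}, \code{sched}, \code{geom}, \code{cfg}.
#' @export
config_objects <- function(config) {
  p <- config$params
  params <- model_params(p$alpha0, p$alphaV, p$alphav, p$beta0, p$betaPhi,
                         p$betaPsi, p$gamma, p$epsPhiSq, p$epsPsiSq,
                         p$mobility, p$N)
  s <- config$sched
  sched <- if (s$regime == "conventional") {
    conversion_schedule("conventional", VbarM = s$VbarM, vbarM = s$vbarM)
  } else {
    conversion_schedule("inverted", VbarM = s$VbarM, r = s$r,
                        rhoM0 = s$rhoM0, rhoBarM = s$rhoBarM,
                        alpha1 = s$alpha1, alpha2 = s$alpha2,
                        tStar = s$tStar, variant = s$variant)
  }
  g <- config$geom
  geom <- nucleus_geometry(g$axisX0, g$axisY0, g$axisX1, g$axisY1,
                           g$tShrinkStart, g$tShrinkEnd, g$eps0)
  so <- config$solver
  cfg <- solver_config(so$dt, so$nx, so$ny, so$Lx, so$Ly, so$tEnd,
                       so$recordEvery)
  list(params = params, sched = sched, geom = geom, cfg = cfg)
}

#' Save / load a field snapshot
#'
#' Snapshots hold all fields plus metadata in R's native serialization
#' (an array container; written at run time, never shipped with the
#' package sources).
#'
#' @param state a \code{\link{simulation_state}}.
#' @param path file path (conventionally \code{snapshot_final.rds}).
#' @return \code{load_snapshot} returns the state.
#' @export
save_snapshot <- function(state, path) {
  saveRDS(list(phi = state$phi, psi = state$psi, phi0 = state$phi0,
               t = state$t,
               grid = unclass(state$grid)[c("nx", "ny", "Lx", "Ly")]),
          path, version = 2)
  invisible(path)
}

#' @rdname save_snapshot
#' @export
load_snapshot <- function(path) {
  x <- readRDS(path)
  g <- sim_grid(x$grid$nx, x$grid$ny, x$grid$Lx, x$grid$Ly)
  simulation_state(x$phi, x$psi, x$phi0, x$t, g)
}

report_as_list <- function(rep) {
  list(label = rep$label, nClusters = rep$nClusters,
       contactFraction = rep$contactFraction,
       heteroShare = rep$heteroShare, deltaPsi = rep$deltaPsi)
}

#' Execute a preset run and write a run directory
#'
#' Runs a scenario and writes: the resolved configuration
#' (\code{config.yaml}), a manifest with the seed and file checksums
#' (\code{manifest.yaml}), the time series (\code{timeseries.csv}), the
#' final snapshot (\code{snapshot_final.rds}), the architecture report
#' (\code{report.yaml}) and a rendered composite frame
#' (\code{final.png}). Reruns from the same manifest are bit-identical.
#'
#' @param name preset name (see \code{\link{preset_names}}).
#' @param outDir output directory (created if needed).
#' @param arm preset arm, where applicable.
#' @param tier resolution tier.
#' @param tEnd optional horizon override.
#' @param seed optional seed override.
#' @param dt optional time-step override.
#' @param render write the PNG frame (default TRUE).
#' @return the output directory, invisibly.
#' @export
cmd_run <- function(name, outDir, arm = NULL, tier = "scaled_down",
                    tEnd = NULL, seed = NULL, dt = NULL, render = TRUE) {
  ps <- preset(name, arm)
  cfg <- if (is.null(dt)) NULL else
    tier_config(tier, tEnd = if (is.null(tEnd)) ps$tEnd else tEnd, dt = dt)
  run <- build_run(ps, tier = tier, cfg = cfg, tEnd = tEnd, seed = seed)
  sim <- run_simulation(run$state, run$params, run$sched, run$geom, run$cfg)

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  config <- run_config(run)
  write_run_config(config, file.path(outDir, "config.yaml"))
  utils::write.csv(sim$record, file.path(outDir, "timeseries.csv"),
                   row.names = FALSE)
  save_snapshot(sim$final, file.path(outDir, "snapshot_final.rds"))
  rep <- classify_architecture(sim$final$psi, sim$final$phi0,
                               sim$final$grid, eps0 = run$geom$eps0,
                               epsPsiSq = run$params$epsPsiSq)
  yaml::write_yaml(report_as_list(rep), file.path(outDir, "report.yaml"))
  if (render) {
    grDevices::png(file.path(outDir, "final.png"), width = 480,
                   height = 720)
    render_state(sim$final, main = sprintf("%s (t = %.4g)", name,
                                           sim$final$t))
    grDevices::dev.off()
  }
  manifest <- list(
    preset = name,
    arm = if (is.null(arm)) NA_character_ else arm,
    tier = tier, seed = as.integer(run$seed),
    package = as.character(utils::packageVersion("chromarch")),
    checksums = as.list(tools::md5sum(file.path(outDir,
      c("config.yaml", "timeseries.csv")))))
  names(manifest$checksums) <- c("config.yaml", "timeseries.csv")
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(outDir)
}

#' Recompute the architecture report of a run directory
#'
#' Reads the final snapshot, recomputes the metrics and compares them with
#' the stored report; a mismatch (tampered or stale snapshot) raises a
#' warning.
#'
#' @param runDir a directory written by \code{\link{cmd_run}}.
#' @return the recomputed \code{"architecture_report"}.
#' @export
cmd_report <- function(runDir) {
  snap <- file.path(runDir, "snapshot_final.rds")
  if (!file.exists(snap)) {
    stop("no snapshot_final.rds in '", runDir, "'; not a run directory?")
  }
  st <- load_snapshot(snap)
  config <- read_run_config(file.path(runDir, "config.yaml"))
  rep <- classify_architecture(st$psi, st$phi0, st$grid,
                               eps0 = config$geom$eps0,
                               epsPsiSq = config$params$epsPsiSq)
  stored_path <- file.path(runDir, "report.yaml")
  if (file.exists(stored_path)) {
    stored <- yaml::read_yaml(stored_path)
    now <- report_as_list(rep)
    same <- identical(stored$label, now$label) &&
      stored$nClusters == now$nClusters &&
      isTRUE(all.equal(stored$contactFraction, now$contactFraction,
                       tolerance = 1e-6))
    if (!same) {
      warning("recomputed report does not match the stored report in '",
              runDir, "'")
    }
  }
  rep
}

#' Run a parameter sweep and extract the phase boundary
#'
#' Runs \code{\link{sweep_presets}} over the given values, classifies each
#' endpoint, writes per-run report rows (\code{reports.csv}) and the
#' phase-boundary table (\code{boundary.csv}). Individual run failures are
#' recorded and the sweep continues.
#'
#' @param name base preset name.
#' @param axis sweep axis (see \code{\link{sweep_presets}}).
#' @param values numeric grid.
#' @param outDir output directory.
#' @param arm optional preset arm.
#' @param tier resolution tier.
#' @param tEnd horizon override.
#' @param dt time-step override.
#' @return data frame of per-run reports, invisibly.
#' @export
cmd_sweep <- function(name, axis, values, outDir, arm = NULL,
                      tier = "scaled_down", tEnd = NULL, dt = NULL) {
  pss <- sweep_presets(name, axis, values, arm = arm, tier = tier)
  rows <- lapply(pss, function(ps) {
    out <- tryCatch({
      cfg <- if (is.null(dt)) NULL else
        tier_config(tier, tEnd = if (is.null(tEnd)) ps$tEnd else tEnd,
                    dt = dt)
      run <- build_run(ps, tier = tier, cfg = cfg, tEnd = tEnd)
      sim <- run_simulation(run$state, run$params, run$sched, run$geom,
                            run$cfg)
      rep <- classify_architecture(sim$final$psi, sim$final$phi0,
                                   sim$final$grid, eps0 = run$geom$eps0,
                                   epsPsiSq = run$params$epsPsiSq)
      data.frame(value = ps$sweepValue,
                 delta = if (axis == "epsPhiSq")
                   interface_width(ps$params$epsPhiSq) else
                   interface_width(ps$params$epsPsiSq),
                 label = rep$label, nClusters = rep$nClusters,
                 contactFraction = rep$contactFraction, error = "")
    }, error = function(e) {
      data.frame(value = ps$sweepValue, delta = NA_real_,
                 label = NA_character_, nClusters = NA_integer_,
                 contactFraction = NA_real_,
                 error = conditionMessage(e))
    })
    out
  })
  reports <- do.call(rbind, rows)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(reports, file.path(outDir, "reports.csv"),
                   row.names = FALSE)
  ok <- reports[reports$error == "" & !is.na(reports$label), ]
  if (nrow(ok) && axis %in% c("epsPhiSq", "epsPsiSq")) {
    bd <- phase_boundary(ok, axis = axis)
    utils::write.csv(bd, file.path(outDir, "boundary.csv"),
                     row.names = FALSE)
  }
  invisible(reports)
}
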