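# Shared builders and memoized heavy scenario runs (one per session).

.heavy <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (is.null(.heavy[[key]])) assign(key, force(expr), envir = .heavy)
  get(key, envir = .heavy)
}

fig4_scaled <- function() {
  cached_run("fig4_scaled",
             suppressWarnings(run_preset("fig4", tier = "scaled_down",
                                         tEnd = 300)))
}

fig3_run <- function(name, arm) {
  cached_run(paste0(name, "_", arm),
             suppressWarnings(run_preset(name, arm = arm,
                                         tier = "scaled_down",
                                         tEnd = 28.8)))
}

fig5_run <- function(name, arm, dt = NULL) {
  key <- paste0(name, "_", arm, "_", if (is.null(dt)) "tier" else dt)
  cached_run(key, {
    cfg <- if (is.null(dt)) NULL else tier_config("coarse", tEnd = 300,
                                                  dt = dt)
    suppressWarnings(run_preset(name, arm = arm, tier = "coarse",
                                tEnd = 300, cfg = cfg))
  })
}

# zero-coefficient parameters: pure interface (Allen-Cahn) dynamics
pure_interface_params <- function(epsSq = 2e-4, N = 1L) {
  model_params(alpha0 = 0, alphaV = 0, alphav = 0, beta0 = 0, betaPhi = 0,
               betaPsi = 0, gamma = 0, epsPhiSq = epsSq, epsPsiSq = epsSq,
               N = N)
}

dummy_sched <- function(N = 1L) {
  conversion_schedule("conventional", VbarM = rep(1, N),
                      vbarM = rep(0.5, N))
}

# 1-D equilibrium front state on an nx x 2 strip
front_state <- function(nx, epsSq = 2e-4, sharp = FALSE, x0 = 0.6) {
  g <- sim_grid(nx, 2, 1.2, 1.8 * 2 / 300)
  prof <- if (sharp) as.numeric(g$x > x0) else
    0.5 * (1 + tanh((g$x - x0) / (2 * sqrt(2) * sqrt(epsSq))))
  phi <- array(rep(prof, times = g$ny), dim = c(g$nx, g$ny, 1L))
  geom <- nucleus_geometry(0.5, 0.8)
  st <- simulation_state(phi, matrix(0, g$nx, g$ny),
                         suppressWarnings(make_phi0(geom, 0, g)), 0, g)
  list(state = st, grid = g, geom = geom)
}

# random smooth field in [0, 0.9] used by the energy-descent property
smooth_random_field <- function(grid) {
  f <- matrix(stats::runif(grid$nx * grid$ny), grid$nx, grid$ny)
  for (k in 1:8) f <- f + 0.2 * laplacian(f, 1, 1)
  0.9 * (f - min(f)) / (max(f) - min(f))
}

# soft circular blob of radius r centered at (cx, cy)
soft_ball <- function(grid, cx, cy, r, width = 0.02) {
  X <- matrix(grid$x, grid$nx, grid$ny)
  Y <- matrix(grid$y, grid$nx, grid$ny, byrow = TRUE)
  d <- sqrt((X - cx)^2 + (Y - cy)^2) - r
  0.5 * (1 - tanh(d / width))
}
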