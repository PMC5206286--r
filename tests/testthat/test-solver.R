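test_that("five-point Laplacian is exact for constants, linears and quadratics", {
  g <- sim_grid(20, 25, 2, 2.5)
  X <- matrix(g$x, 20, 25)
  expect_equal(laplacian(matrix(3.7, 20, 25), g$dx, g$dy),
               matrix(0, 20, 25))
  inner <- function(M) M[2:19, 2:24]
  expect_equal(inner(laplacian(X, g$dx, g$dy)), inner(matrix(0, 20, 25)))
  expect_equal(inner(laplacian(X^2, g$dx, g$dy)),
               inner(matrix(2, 20, 25)), tolerance = 1e-10)
})

test_that("stability factor reproduces the reference discretization and guards the run", {
  p <- model_params(epsPhiSq = 2e-4, epsPsiSq = 7.84e-4)
  cfg <- solver_config(dt = 6e-4, nx = 200, ny = 300)
  expect_equal(cfg$grid$dx, 6e-3)
  expect_equal(stability_factor(cfg, p), 7.84e-4 * 2 * (6e-4 / 3.6e-5),
               tolerance = 1e-12)
  expect_lt(stability_factor(cfg, p), 0.5)
  # a configuration over the bound is refused, naming the offending values
  bad <- solver_config(dt = 6e-4 * 0.51 / stability_factor(cfg, p),
                       nx = 200, ny = 300, tEnd = 1)
  expect_error(run_simulation(NULL, p, NULL, NULL, bad), "stability factor")
  expect_gt(stability_factor(bad, p), 0.5)
})

test_that("uniform well states are fixed points of the step", {
  g <- sim_grid(10, 10)
  geom <- nucleus_geometry(0.5, 0.8)
  cfg <- solver_config(dt = 6e-4, nx = 10, ny = 10, tEnd = 1)
  p <- pure_interface_params()
  s <- dummy_sched()
  for (val in c(0, 1)) {
    st <- simulation_state(array(val, c(10, 10, 1)),
                           matrix(val, 10, 10), matrix(1, 10, 10), 0, g)
    st2 <- suppressWarnings(step_state(st, p, s, geom, cfg))
    expect_equal(st2$phi, st$phi)
    expect_equal(st2$psi, st$psi)
  }
})

test_that("compiled stepper reproduces the reference R stepper", {
  set.seed(11)
  g <- sim_grid(30, 40)
  geom <- nucleus_geometry(0.5, 0.8, 0.4, 0.4, 0, 0.05)  # moving nucleus
  phi <- array(runif(30 * 40 * 3, 0, 1), c(30, 40, 3))
  psi <- matrix(runif(30 * 40), 30, 40)
  st0 <- simulation_state(phi, psi,
                          suppressWarnings(make_phi0(geom, 0, g)), 0, g)
  p <- model_params(N = 3, gamma = 0.0022 / 3, epsPsiSq = 4e-4)
  vols <- volumes(st0)
  cfg <- solver_config(dt = 2e-3, nx = 30, ny = 40, tEnd = 1,
                       recordEvery = 5)
  for (sched in list(
    conversion_schedule("conventional", VbarM = vols$V * 0.9,
                        vbarM = 0.2 * vols$V),
    conversion_schedule("inverted", VbarM = rep(0.15, 3), r = 0.7,
                        rhoM0 = pmin(vols$v / vols$V, 0.5),
                        rhoBarM = 0.2, alpha1 = 120, alpha2 = 0.03,
                        tStar = 120),
    conversion_schedule("inverted", VbarM = rep(0.15, 3), r = 0.7,
                        rhoM0 = pmin(vols$v / vols$V, 0.5),
                        rhoBarM = 0.2, variant = "saturating"))) {
    stR <- st0
    for (k in 1:4) stR <- suppressWarnings(step_state(stR, p, sched, geom, cfg))
    stC <- chromarch:::advance_compiled(st0, p, sched, geom, cfg, 4L)
    expect_equal(stC$phi, stR$phi, tolerance = 1e-12)
    expect_equal(stC$psi, stR$psi, tolerance = 1e-12)
    expect_equal(stC$phi0, stR$phi0, tolerance = 1e-12)
    expect_equal(stC$t, stR$t)
  }
})

test_that("the closed-form tanh front is stationary under the interface dynamics", {
  fs <- front_state(200, epsSq = 2e-4)
  cfg <- solver_config(dt = 6e-4, nx = 200, ny = fs$grid$ny,
                       Lx = 1.2, Ly = fs$grid$Ly, tEnd = 6e-4,
                       recordEvery = 1)
  st2 <- suppressWarnings(step_state(fs$state, pure_interface_params(),
                                     dummy_sched(), fs$geom, cfg))
  expect_lt(max(abs(st2$phi - fs$state$phi)), 1e-6)
})

test_that("runs are deterministic and tEnd = 0 returns the initial state", {
  g <- sim_grid(40, 60)
  geom <- nucleus_geometry(0.5, 0.8)
  st <- suppressWarnings(sector_init(4, geom, g, seed = 3,
                                     epsPsiSq = 4e-4))
  p <- model_params(N = 4, epsPsiSq = 4e-4, gamma = 0.0022 / 3)
  vols <- volumes(st)
  sch <- conversion_schedule("conventional", VbarM = rep(0.3, 4),
                             vbarM = 0.25 * vols$V)
  cfg0 <- solver_config(dt = 2e-3, nx = 40, ny = 60, tEnd = 0)
  sim0 <- run_simulation(st, p, sch, geom, cfg0)
  expect_identical(nrow(sim0$record), 1L)
  expect_equal(sim0$final$phi, st$phi)
  expect_equal(sim0$final$psi, st$psi)
  cfg <- solver_config(dt = 2e-3, nx = 40, ny = 60, tEnd = 0.2,
                       recordEvery = 20)
  simA <- run_simulation(st, p, sch, geom, cfg)
  simB <- run_simulation(st, p, sch, geom, cfg)
  expect_identical(simA$record, simB$record)
  expect_identical(simA$final$phi, simB$final$phi)
})

test_that("a mirror-symmetric initial condition stays symmetric", {
  g <- sim_grid(40, 50)
  geom <- nucleus_geometry(0.5, 0.8)
  mirror <- function(M) M[g$nx:1, , drop = FALSE]
  phi <- array(0, c(40, 50, 2))
  phi[, , 1] <- soft_ball(g, 0.6, 0.7, 0.25)
  phi[, , 2] <- soft_ball(g, 0.6, 1.2, 0.22)
  psi <- 0.8 * soft_ball(g, 0.6, 0.7, 0.12)
  phi[, , 1] <- (phi[, , 1] + mirror(phi[, , 1])) / 2
  phi[, , 2] <- (phi[, , 2] + mirror(phi[, , 2])) / 2
  psi <- (psi + mirror(psi)) / 2
  st <- simulation_state(phi, psi,
                         suppressWarnings(make_phi0(geom, 0, g)), 0, g)
  p <- model_params(N = 2, gamma = 0.0022 / 3, epsPsiSq = 4e-4)
  vols <- volumes(st)
  sch <- conversion_schedule("conventional", VbarM = vols$V * 0.9,
                             vbarM = vols$v * 0.9)
  cfg <- solver_config(dt = 2e-3, nx = 40, ny = 50, tEnd = 1)
  out <- chromarch:::advance_compiled(st, p, sch, geom, cfg, 100L)
  for (m in 1:2) {
    expect_lt(max(abs(out$phi[, , m] - mirror(out$phi[, , m]))), 1e-10)
  }
  expect_lt(max(abs(out$psi - mirror(out$psi))), 1e-10)
})

test_that("total energy descends along trajectories with frozen geometry and targets", {
  set.seed(3)
  g <- sim_grid(30, 40)
  geom <- nucleus_geometry(0.5, 0.8)
  p <- model_params(N = 3, gamma = 0.0022 / 3, epsPsiSq = 4e-4)
  cfg <- solver_config(dt = 6e-4, nx = 30, ny = 40, tEnd = 1,
                       recordEvery = 5)
  scheds <- list(
    conversion_schedule("conventional", VbarM = rep(0.15, 3),
                        vbarM = rep(0.04, 3)),
    # rhoBarM = 0 freezes the conversion fraction at rhoM0
    conversion_schedule("inverted", VbarM = rep(0.15, 3), r = 0.8,
                        rhoM0 = 0.3, rhoBarM = 0))
  for (rep in 1:3) {
    phi <- array(0, c(30, 40, 3))
    for (m in 1:3) phi[, , m] <- smooth_random_field(g)
    st <- simulation_state(phi, smooth_random_field(g),
                           suppressWarnings(make_phi0(geom, 0, g)), 0, g)
    sch <- scheds[[1 + rep %% 2]]
    E <- total_energy(st, p, sch)[["E"]]
    for (k in 1:30) {
      st <- suppressWarnings(step_state(st, p, sch, geom, cfg))
      E2 <- total_energy(st, p, sch)[["E"]]
      expect_lt((E2 - E) / abs(E), 1e-6)
      E <- E2
    }
  }
})
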