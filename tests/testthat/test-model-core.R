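test_that("interpolation function fixes the wells and partitions unity", {
  expect_identical(interp_h(0), 0)
  expect_identical(interp_h(1), 1)
  expect_equal(interp_h(0.5), 0.5)
  expect_equal(interp_h(0.2), 0.05792)
  u <- seq(0, 1, length.out = 1000)
  # partition symmetry h(u) + h(1-u) = 1
  expect_equal(interp_h(u) + interp_h(1 - u), rep(1, 1000), tolerance = 1e-12)
  # monotone on [0, 1], flat derivative at the wells
  expect_true(all(diff(interp_h(u)) >= 0))
  expect_equal(interp_h_prime(c(0, 1)), c(0, 0))
  expect_equal(interp_h_prime(0.3), 30 * (0.3 * 0.7)^2)
})

test_that("double-well potential has zero minima at the wells", {
  expect_identical(doublewell_g(0), 0)
  expect_identical(doublewell_g(1), 0)
  expect_equal(doublewell_g(0.5), 0.015625)
  u <- seq(0, 1, length.out = 201)
  expect_equal(doublewell_g(u), doublewell_g(1 - u))  # symmetric about 1/2
  expect_true(all(doublewell_g(u) >= 0))
  # -g'(u) = u(1-u)(u-1/2): finite-difference check
  h <- 1e-6
  num <- -(doublewell_g(0.3 + h) - doublewell_g(0.3 - h)) / (2 * h)
  expect_equal(num, 0.3 * 0.7 * (0.3 - 0.5), tolerance = 1e-8)
})

test_that("model parameter validation rejects bad coefficients", {
  expect_s3_class(model_params(), "chromatin_params")
  expect_error(model_params(alpha0 = -1), "non-negative")
  expect_error(model_params(epsPhiSq = 0), "positive")
  expect_error(model_params(mobility = c(1, 0, 1)), "mobility")
  expect_error(model_params(N = 0), "N")
})

test_that("conversion schedule enforces its invariants", {
  expect_error(conversion_schedule("conventional", VbarM = c(1, 1)),
               "vbarM")
  expect_error(conversion_schedule("conventional", VbarM = 1, vbarM = 2),
               "vbarM")
  expect_error(conversion_schedule("inverted", VbarM = 1, r = 1.5,
                                   rhoM0 = 0.2, rhoBarM = 0.3), "r")
  expect_error(conversion_schedule("inverted", VbarM = 1, r = 0.5,
                                   rhoM0 = 0.8, rhoBarM = 0.3),
               "rhoM0")
  s <- conversion_schedule("inverted", VbarM = rep(1, 3), r = 0.6,
                           rhoM0 = 0.2, rhoBarM = 0.3)
  expect_length(s$alpha1, 3)
})

test_that("conversion fraction follows the sigmoid and saturating forms", {
  s <- conversion_schedule("inverted", VbarM = 1, r = 0.6, rhoM0 = 0.25,
                           rhoBarM = 0.35, alpha1 = 120, alpha2 = 0.03,
                           tStar = 120)
  expect_equal(rho_m(0, 1, s), 0.25)
  # at t = t* the exponential is 1, denominator 2 t*: midpoint of the rise
  expect_equal(rho_m(120, 1, s), 0.425)
  expect_equal(rho_m(1e9, 1, s), 0.6, tolerance = 1e-6)
  ssat <- conversion_schedule("inverted", VbarM = 1, r = 0.6, rhoM0 = 0.1,
                              rhoBarM = 0.3, variant = "saturating")
  expect_equal(rho_m(10, 1, ssat), 0.25)
  expect_error(rho_m(-1, 1, s), "non-negative")
  expect_error(rho_m(1, 1, dummy_sched()), "inverted")
})

test_that("conversion fraction is monotone for every packaged schedule", {
  tgrid <- seq(0, 600, by = 1)
  for (nm in c("fig4", "fig6a2", "fig6b3", "fig7")) {
    ps <- preset(nm)
    s <- conversion_schedule("inverted", VbarM = rep(1, 8),
                             r = ps$sched$r, rhoM0 = 0.2,
                             rhoBarM = ps$sched$rhoBarM,
                             alpha1 = ps$sched$alpha1,
                             alpha2 = ps$sched$alpha2,
                             tStar = ps$sched$tStar,
                             variant = ps$sched$variant)
    for (m in 1:8) {
      expect_true(all(diff(rho_m(tgrid, m, s)) >= -1e-12),
                  info = sprintf("%s chromosome %d", nm, m))
    }
  }
})

test_that("volumes are Riemann sums of the occupancies", {
  g <- sim_grid(10, 10, 1, 1)  # unit-area domain
  phi <- array(0.5, c(10, 10, 2))
  psi <- matrix(0.5, 10, 10)
  st <- simulation_state(phi, psi, matrix(1, 10, 10), 0, g)
  v <- volumes(st)
  expect_equal(v$V, c(0.5, 0.5))
  expect_equal(v$v, c(0.25, 0.25))
  # sharp region of known area, psi = 0 kills v
  phi[, , 1] <- 0
  phi[1:5, , 1] <- 1
  st2 <- simulation_state(phi, matrix(0, 10, 10), matrix(1, 10, 10), 0, g)
  v2 <- volumes(st2)
  expect_equal(v2$V[1], 0.5)
  expect_equal(v2$v, c(0, 0))
  # non-finite fields are refused with a diagnostic
  phi[1, 1, 1] <- NaN
  st3 <- simulation_state(phi, psi, matrix(1, 10, 10), 0, g)
  expect_error(volumes(st3), "non-finite")
})

test_that("volume bounds hold for arbitrary fields in [0, 1]", {
  set.seed(42)
  g <- sim_grid(15, 20)
  area <- g$Lx * g$Ly
  for (k in 1:10) {
    phi <- array(runif(15 * 20 * 3), c(15, 20, 3))
    psi <- matrix(runif(15 * 20), 15, 20)
    st <- simulation_state(phi, psi, matrix(0, 15, 20), 0, g)
    v <- volumes(st)
    expect_true(all(v$v >= 0))
    expect_true(all(v$v <= v$V))
    expect_true(all(v$V <= area))
  }
})

test_that("reaction field A_m matches hand evaluation", {
  g <- sim_grid(2, 2, 1, 1)
  mk <- function(phi_vals, psi_val = 0, phi0_val = 0) {
    phi <- array(rep(phi_vals, each = 4), c(2, 2, length(phi_vals)))
    simulation_state(phi, matrix(psi_val, 2, 2), matrix(phi0_val, 2, 2),
                     0, g)
  }
  # all coefficients zero -> identically zero field
  st <- mk(c(0.5, 0.5))
  p0 <- pure_interface_params(N = 2)
  s0 <- dummy_sched(2)
  expect_equal(reaction_A(1, st, p0, s0), matrix(0, 2, 2))
  expect_equal(reaction_B(st, p0, s0), matrix(0, 2, 2))
  # only the territory-exclusion term: uniform fields at the symmetry
  # point h(0.5) = 0.5, chi = 1, so A_1 = 30 * betaPhi * (1 - 0.5) = 15
  st2 <- mk(c(0.5, 0.5))
  pB <- model_params(alpha0 = 0, alphaV = 0, alphav = 0, beta0 = 0,
                     betaPhi = 1, betaPsi = 0, gamma = 0, N = 2)
  expect_equal(reaction_A(1, st2, pB, s0), matrix(15, 2, 2),
               tolerance = 1e-10)
  # volume on target kills the alphaV term
  vols <- volumes(st2)
  pV <- model_params(alpha0 = 0, alphaV = 3, alphav = 0, beta0 = 0,
                     betaPhi = 0, betaPsi = 0, gamma = 0, N = 2)
  sV <- conversion_schedule("conventional", VbarM = vols$V,
                            vbarM = 0.5 * vols$V)
  expect_equal(reaction_A(1, st2, pV, sV), matrix(0, 2, 2))
})

test_that("inverted reaction reduces to the conventional volume structure", {
  set.seed(7)
  g <- sim_grid(12, 16)
  phi <- array(runif(12 * 16 * 2, 0.1, 0.9), c(12, 16, 2))
  psi <- matrix(runif(12 * 16, 0.1, 0.9), 12, 16)
  st <- simulation_state(phi, psi, matrix(0, 12, 16), 0, g)
  vols <- volumes(st)
  p <- model_params(alpha0 = 0, alphaV = 2, alphav = 0, beta0 = 0,
                    betaPhi = 0, betaPsi = 0, gamma = 0, N = 2)
  rho0 <- vols$v / vols$V
  sc <- conversion_schedule("conventional", VbarM = c(0.2, 0.3),
                            vbarM = rho0 * c(0.2, 0.3))
  si <- conversion_schedule("inverted", VbarM = c(0.2, 0.3), r = 1,
                            rhoM0 = rho0, rhoBarM = c(0, 0))
  # with r = 1 and rho frozen at v/V, the alphaV terms coincide exactly
  for (m in 1:2) {
    expect_equal(reaction_A(m, st, p, si), reaction_A(m, st, p, sc),
                 tolerance = 1e-12)
  }
  # heterochromatin fraction on target: the alphav term vanishes identically
  pav <- model_params(alpha0 = 0, alphaV = 0, alphav = 5, beta0 = 0,
                      betaPhi = 0, betaPsi = 0, gamma = 0, N = 2)
  expect_equal(reaction_A(1, st, pav, si), matrix(0, 12, 16),
               tolerance = 1e-12)
  expect_equal(reaction_B(st, pav, si), matrix(0, 12, 16),
               tolerance = 1e-12)
})

test_that("reaction field B drops the affinity term for flat phi0", {
  g <- sim_grid(8, 8, 1, 1)
  phi <- array(0.5, c(8, 8, 1))
  st <- simulation_state(phi, matrix(0.3, 8, 8), matrix(0.4, 8, 8), 0, g)
  pg <- model_params(alpha0 = 0, alphaV = 0, alphav = 0, beta0 = 0,
                     betaPhi = 0, betaPsi = 0, gamma = 5, N = 1)
  # Laplacian of a constant nucleus field is zero: no affinity force
  expect_equal(reaction_B(st, pg, dummy_sched()), matrix(0, 8, 8))
})

test_that("diagnostic energy reduces to known values on uniform states", {
  g <- sim_grid(10, 10, 1, 1)
  # empty fields, empty nucleus, zero targets: E = 0
  phi <- array(0, c(10, 10, 2))
  st <- simulation_state(phi, matrix(0, 10, 10), matrix(1, 10, 10), 0, g)
  s0 <- conversion_schedule("conventional", VbarM = c(1e-12, 1e-12),
                            vbarM = c(0, 0))
  en <- total_energy(st, model_params(N = 2), s0)
  expect_equal(en[["E"]], 0, tolerance = 1e-20)
  # uniform fields: gradient terms vanish, E0 = integral of g
  phi[, , 1] <- 0.3
  phi[, , 2] <- 0.3
  st2 <- simulation_state(phi, matrix(0.4, 10, 10), matrix(1, 10, 10), 0, g)
  en2 <- total_energy(st2, pure_interface_params(N = 2), dummy_sched(2))
  expect_equal(en2[["E0"]], 2 * doublewell_g(0.3) + doublewell_g(0.4))
})
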