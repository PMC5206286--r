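test_that("interface width follows the closed form and rejects bad cutoffs", {
  expect_equal(interface_width(2e-4),
               4 * sqrt(2) * sqrt(2e-4) * atanh(0.7))
  # width collapses as the cutoff approaches 1/2
  expect_lt(interface_width(2e-4, lambda = 0.4999), 1e-3)
  expect_error(interface_width(2e-4, lambda = 0.5), "lambda")
  expect_error(interface_width(2e-4, lambda = 0), "lambda")
  expect_error(interface_width(-1), "positive")
  # non-dimensional coefficient with the 5 um length scale: the reference
  # heterochromatin intermingling endpoints
  expect_equal(round(interface_width(1.96e-4, L = 5), 3), 0.343)
  expect_equal(round(interface_width(7.84e-4, L = 5), 3), 0.687)
})

test_that("cluster counting handles empty, single and multiple components", {
  g <- sim_grid(60, 60, 1.2, 1.2)
  expect_identical(count_clusters(matrix(0, 60, 60)), 0L)
  one <- soft_ball(g, 0.6, 0.6, 0.2)
  expect_identical(count_clusters(one), 1L)
  two <- soft_ball(g, 0.3, 0.3, 0.12) + soft_ball(g, 0.9, 0.9, 0.12)
  expect_identical(count_clusters(two), 2L)
  # threshold matters: a faint blob disappears
  faint <- 0.4 * soft_ball(g, 0.6, 0.6, 0.2)
  expect_identical(count_clusters(faint, threshold = 0.5), 0L)
  expect_identical(count_clusters(faint, threshold = 0.3), 1L)
})

test_that("component labeling matches an independent implementation", {
  skip_if_not_installed("EBImage")
  set.seed(5)
  g <- sim_grid(50, 70)
  for (k in 1:5) {
    f <- matrix(0, 50, 70)
    for (b in 1:4) {
      f <- f + soft_ball(g, runif(1, 0.2, 1), runif(1, 0.2, 1.6),
                         runif(1, 0.05, 0.15))
    }
    mask <- f >= 0.5
    ref <- max(EBImage::bwlabel(mask))  # bwlabel uses 4-connectivity
    expect_identical(count_clusters(f, 0.5, connectivity = 4),
                     as.integer(ref))
    # 8-connectivity can only merge components, never split them
    expect_lte(count_clusters(f, 0.5, connectivity = 8),
               count_clusters(f, 0.5, connectivity = 4))
  }
})

test_that("contact fraction separates peripheral from central heterochromatin", {
  g <- sim_grid(100, 150)
  geom <- nucleus_geometry(0.5, 0.8)
  p0 <- suppressWarnings(make_phi0(geom, 0, g))
  expect_equal(contact_fraction(matrix(0, 100, 150), p0, g), 0)
  # psi = 1 everywhere inside the nucleus (the shell includes the diffuse
  # envelope annulus itself, so the mean sits just below 1)
  inside <- 1 - p0
  expect_gt(contact_fraction(inside, p0, g), 0.8)
  # central ball far from the envelope
  ball <- soft_ball(g, 0.6, 0.9, 0.15)
  expect_lt(contact_fraction(ball, p0, g), 0.05)
  expect_error(contact_fraction(matrix(0, 10, 10), matrix(0, 10, 10),
                                sim_grid(10, 10)), "shell")
})

test_that("architecture classification recovers the constructed endpoint states", {
  g <- sim_grid(100, 150)
  geom <- nucleus_geometry(0.5, 0.8)
  p0 <- suppressWarnings(make_phi0(geom, 0, g))
  s <- chromarch:::phi0_signed_distance(p0, 2e-5)
  ring <- interp_h(pmin(pmax((s + 0.1) / 0.04, 0), 1)) * (1 - p0)
  expect_identical(classify_architecture(ring, p0, g)$label, "conventional")
  single <- soft_ball(g, 0.6, 0.9, 0.2)
  rep1 <- classify_architecture(single, p0, g)
  expect_identical(rep1$label, "inverted_single")
  expect_identical(rep1$nClusters, 1L)
  two <- soft_ball(g, 0.6, 0.6, 0.12) + soft_ball(g, 0.6, 1.2, 0.12)
  expect_identical(classify_architecture(two, p0, g)$label,
                   "inverted_multi")
})

test_that("classification is invariant under rotation and mirror", {
  g <- sim_grid(80, 80, 1.2, 1.2)
  geom <- nucleus_geometry(0.45, 0.45, center = c(0.6, 0.6))
  p0 <- suppressWarnings(make_phi0(geom, 0, g))
  psi <- soft_ball(g, 0.6, 0.75, 0.15) + soft_ball(g, 0.45, 0.45, 0.1)
  base <- classify_architecture(psi, p0, g)
  rot90 <- function(M) t(M)[ncol(M):1, , drop = FALSE]
  mirr <- function(M) M[nrow(M):1, , drop = FALSE]
  for (f in list(rot90, mirr)) {
    alt <- classify_architecture(f(psi), f(p0), g)
    expect_identical(alt$label, base$label)
    expect_identical(alt$nClusters, base$nClusters)
    expect_equal(alt$contactFraction, base$contactFraction,
                 tolerance = 1e-12)
  }
})

test_that("radial profile localizes peripheral and central heterochromatin", {
  g <- sim_grid(100, 150)
  geom <- nucleus_geometry(0.5, 0.8)
  central <- soft_ball(g, 0.6, 0.9, 0.15)
  rp <- radial_profile(central, geom, 0, g, nbins = 10)
  expect_identical(nrow(rp), 10L)
  expect_gt(rp$meanPsi[1], 0.9)
  expect_lt(rp$meanPsi[10], 0.01)
})

test_that("phase boundary extraction handles success, failure and mixed sweeps", {
  lab <- function(x) ifelse(x, "inverted_single", "intermediate")
  # all runs succeed: boundary at the sweep minimum for the psi axis
  d <- data.frame(delta = c(0.3, 0.4, 0.5), label = lab(c(TRUE, TRUE, TRUE)))
  expect_equal(phase_boundary(d, "epsPsiSq")$boundary, 0.3)
  # no run succeeds: undefined, flagged
  d2 <- data.frame(delta = c(0.3, 0.4), label = lab(c(FALSE, FALSE)))
  b2 <- phase_boundary(d2, "epsPsiSq")
  expect_true(is.na(b2$boundary))
  expect_identical(b2$nSuccess, 0L)
  # (fail, success, success) ordered by delta: boundary at the middle value
  d3 <- data.frame(delta = c(0.3, 0.4, 0.5),
                   label = lab(c(FALSE, TRUE, TRUE)))
  b3 <- phase_boundary(d3, "epsPsiSq")
  expect_equal(b3$boundary, 0.4)
  expect_true(b3$monotone)
  # phi axis reports the maximal successful width
  d4 <- data.frame(delta = c(0.3, 0.4, 0.5),
                   label = lab(c(TRUE, TRUE, FALSE)))
  expect_equal(phase_boundary(d4, "epsPhiSq")$boundary, 0.4)
  # non-monotone sweeps are reported raw
  d5 <- data.frame(delta = c(0.3, 0.4, 0.5),
                   label = lab(c(TRUE, FALSE, TRUE)))
  expect_false(phase_boundary(d5, "epsPsiSq")$monotone)
})

test_that("profile width measurement inverts the closed form on a pure tanh", {
  eps <- sqrt(3e-4)
  x <- seq(-0.2, 0.2, length.out = 400)
  f <- 0.5 * (1 + tanh(x / (2 * sqrt(2) * eps)))
  expect_equal(measure_profile_width(f, x), interface_width(3e-4),
               tolerance = 1e-4)
  # decreasing profiles are handled by reversal
  expect_equal(measure_profile_width(rev(f), x), interface_width(3e-4),
               tolerance = 1e-4)
})
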