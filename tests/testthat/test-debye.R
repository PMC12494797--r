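# Coarse-graining, hydration layer, and the Debye forward calculator.

test_that("two point beads reproduce the closed-form interference", {
  tp <- bead_model(c(0, 0), c(0, 0), c(0, 10))
  mc <- debye_intensity(tp, c(0.05, 0.25, pi / 10))
  expect_equal(mc$I, 2 * (1 + sin(10 * mc$q) / (10 * mc$q)),
               tolerance = 1e-12)
  expect_equal(mc$I[mc$q == pi / 10], 2)  # sinc vanishes at q d = pi
})

test_that("a uniform bead cloud matches the sphere form factor", {
  sp <- make_model("sphere", radius = 50, n = 5000, seed = 2)
  N <- nrow(sp)
  q <- seq(0.004, 0.9 * sphere_qmin(50), length.out = 60)
  I <- debye_intensity(sp, q, method = "hist", dr = 0.3)$I
  # finite-N oracle for beads drawn uniformly in a ball:
  # E[I] = N (N - 1) |phi|^2 + N (incoherent self term)
  Ia <- N * (N - 1) * sphere_intensity(q, 50) + N
  expect_lt(max(abs(I - Ia) / Ia), 0.02)
})

test_that("forward-scattering sum rule I(0) = (sum b)^2 holds exactly", {
  set.seed(3)
  p <- matrix(rnorm(150) * 12, ncol = 3)
  bm <- bead_model(p[, 1], p[, 2], p[, 3], b = runif(50, 0.5, 3),
                   sigma = runif(50, 0, 2))
  expect_equal(debye_intensity(bm, 0)$I, sum(bm$b)^2, tolerance = 1e-12)
  expect_equal(debye_intensity(bm, 0, "hist")$I, sum(bm$b)^2,
               tolerance = 1e-12)
})

test_that("intensity is nonnegative when scattering lengths share a sign", {
  set.seed(4)
  q <- seq(0.005, 0.6, length.out = 120)
  for (s in 1:5) {
    p <- matrix(rnorm(120) * 20, ncol = 3)
    bm <- bead_model(p[, 1], p[, 2], p[, 3], b = runif(40, 0.1, 2),
                     sigma = runif(40, 0, 1.5))
    expect_gte(min(debye_intensity(bm, q)$I), 0)
  }
})

test_that("I(q) is invariant under rigid transforms", {
  set.seed(1)
  p <- matrix(rnorm(300) * 15, ncol = 3)
  bm <- bead_model(p[, 1], p[, 2], p[, 3], b = 1.5, sigma = 1.2)
  R <- saxsfit:::.rot_matrix(c(1, 2, 3), 0.7)
  p2 <- sweep(p %*% t(R), 2, c(10, -5, 3), "+")
  bm2 <- bead_model(p2[, 1], p2[, 2], p2[, 3], b = 1.5, sigma = 1.2)
  q <- seq(0.01, 0.3, length.out = 50)
  I1 <- debye_intensity(bm, q)$I
  I2 <- debye_intensity(bm2, q)$I
  expect_lt(max(abs(I1 - I2) / I1), 1e-10)
})

test_that("histogram acceleration converges to the exact sum", {
  set.seed(1)
  p <- matrix(rnorm(1500) * 20, ncol = 3)
  bm <- bead_model(p[, 1], p[, 2], p[, 3], b = 2, sigma = 1.5)
  q <- seq(0.01, 0.3, length.out = 50)
  Ie <- debye_intensity(bm, q, "exact")$I
  errs <- vapply(c(2, 1, 0.5, 0.25), function(dr) {
    max(abs(debye_intensity(bm, q, "hist", dr = dr)$I - Ie) / Ie)
  }, 1)
  expect_true(all(diff(errs) < 0))      # monotone decrease
  expect_lt(errs[3], 0.005)             # dr = 0.5 within 0.5%
})

test_that("residue coarse-graining uses the shipped parameter tables", {
  # homopolymer symmetry: identical b and width for every glycine
  pg <- ca_structure(cbind(seq(0, 34, length.out = 10), 0, 0),
                     resname = "GLY")
  cg <- coarse_grain(pg)
  expect_equal(nrow(cg), 10)
  expect_equal(diff(range(cg$b)), 0)
  # hand value for alanine: electrons - rho * volume
  ala <- coarse_grain(ca_structure(cbind(0, 0, 0), resname = "ALA"))
  expect_equal(ala$b, 38 - 0.334 * 88.6, tolerance = 1e-9)
  # one bead per residue on a dimer-sized model
  md <- make_model("multidomain_dimer", seed = 1)
  beads <- coarse_grain(md)
  expect_equal(nrow(beads), nrow(dplyr::distinct(md, chain, resno)))
  # unknown residues fall back with a warning
  odd <- ca_structure(cbind(c(0, 5), 0, 0), resname = c("ALA", "XYZ"))
  expect_warning(coarse_grain(odd), "unknown residue")
})

test_that("hydration shell geometry and contrast behave as documented", {
  # a single bead grows a shell at exactly bead radius + thickness
  b1 <- bead_model(0, 0, 0, b = 10, sigma = 2)
  h <- add_hydration_layer(b1, thickness = 3)
  shell <- h[h$kind == "hydration", ]
  expect_gt(nrow(shell), 10)
  d <- sqrt(shell$x^2 + shell$y^2 + shell$z^2)
  expect_equal(d, rep(2 * sqrt(5) + 3, nrow(shell)), tolerance = 1e-6)
  # zero contrast leaves the intensity unchanged
  q <- seq(0.01, 0.3, length.out = 40)
  h0 <- add_hydration_layer(b1, contrast_fraction = 0)
  expect_equal(debye_intensity(h0, q)$I, debye_intensity(b1, q)$I,
               tolerance = 1e-12)
  expect_error(add_hydration_layer(b1, thickness = -1), "thickness")
  # an extended conformer exposes at least as much surface as a compact one
  cmp <- coarse_grain(make_model(
    "multidomain_dimer", domain_residues = c(80, 50), linker_residues = 3,
    centres = list(c(14, 9, 0), c(10, 8, 22)), seed = 3))
  ext <- coarse_grain(make_model(
    "multidomain_dimer", domain_residues = c(80, 50), linker_residues = 3,
    centres = list(c(30, 20, 0), c(20, 18, 52)), seed = 3))
  expect_gte(sum(add_hydration_layer(ext)$kind == "hydration"),
             sum(add_hydration_layer(cmp)$kind == "hydration"))
})

test_that("scale/background fitting recovers exact linear relations", {
  q <- seq(0.01, 0.3, length.out = 50)
  Im <- sphere_intensity(q, 30, 1000)
  mc <- saxs_curve(q, Im, model = TRUE)
  fit <- fit_scale_background(mc, saxs_curve(q, 3 * Im + 7, rep(1, 50)))
  expect_equal(fit$scale, 3, tolerance = 1e-9)
  expect_equal(fit$background, 7, tolerance = 1e-9)
  expect_lt(fit$chi2_red, 1e-18)
  expect_error(fit_scale_background(mc, saxs_curve(q[1:2], Im[1:2],
                                                   rep(1, 2))), "2 data")
})

test_that("reduced chi-squared is calibrated against injected noise", {
  q <- seq(0.01, 0.3, length.out = 50)
  Im <- sphere_intensity(q, 30, 1000)
  mc <- saxs_curve(q, Im, model = TRUE)
  set.seed(5)
  chis <- replicate(200, {
    fit_scale_background(mc, saxs_curve(q, Im + rnorm(50, 0, 5),
                                        rep(5, 50)))$chi2_red
  })
  expect_equal(mean(chis), 1.0, tolerance = 0.15)
  # an unrelated model cannot fit the data
  bad <- saxs_curve(q, rev(Im), model = TRUE)
  fit <- fit_scale_background(bad, saxs_curve(q, Im, 0.01 * Im))
  expect_gt(fit$chi2_red, 100)
})
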