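# Rigid-body decomposition, restraints, the oligomer structure factor, and
# simulated-annealing refinement.

test_that("decomposition labels bodies and places springs at cuts", {
  md <- make_model("multidomain_dimer", domain_residues = c(60, 40),
                   linker_residues = 4,
                   centres = list(c(14, 9, 0), c(10, 8, 22)), seed = 5)
  ch <- md[md$chain == "A", ]
  class(ch) <- class(md)
  # single body covering everything: K = 1, no springs
  d1 <- decompose_bodies(ch, data.frame(chain = "A", start = 1, end = 104))
  expect_equal(d1$K, 1)
  expect_equal(nrow(d1$springs), 0)
  # two bodies, contiguous cut: one spring with peptide rest length
  d2 <- decompose_bodies(ch, data.frame(chain = "A", start = c(1, 63),
                                        end = c(62, 104)))
  expect_equal(d2$K, 2)
  expect_equal(nrow(d2$springs), 1)
  expect_equal(d2$springs$rest, 3.8)
  expect_equal(d2$springs$slack, 0)
  # overlapping segments error; uncovered residues warn and are assigned
  expect_error(decompose_bodies(ch, data.frame(chain = "A",
                                               start = c(1, 50),
                                               end = c(62, 104))),
               "twice|overlap")
  expect_warning(
    d3 <- decompose_bodies(ch, data.frame(chain = "A", start = c(1, 70),
                                          end = c(62, 104))),
    "uncovered|nearest")
  expect_false(anyNA(d3$beads$body_id))
})

test_that("an eight-body homodimer decomposition has six intra-chain springs", {
  md <- make_model("multidomain_dimer", seed = 1)  # 350/150/210 + two linkers
  # per chain: catalytic split in two, a cut in each linker
  seg1 <- data.frame(chain = "A", start = c(1, 176, 357, 520),
                     end = c(175, 356, 519, 736))
  seg <- rbind(seg1, transform(seg1, chain = "B"))
  dec <- decompose_bodies(md, seg)
  expect_equal(dec$K, 8)
  expect_equal(nrow(dec$springs), 6)
  expect_true(all(dec$beads$body_id %in% 1:8))
  # every spring joins beads of distinct bodies
  expect_true(all(dec$beads$body_id[dec$springs$a] !=
                  dec$beads$body_id[dec$springs$b]))
})

test_that("connectivity and clash penalties have the documented form", {
  dec <- rb_harness(seed = 6)
  q <- seq(0.01, 0.25, length.out = 60)
  I <- debye_intensity(dec$beads, q)$I
  data <- saxs_curve(q, I, lab_sigma(q, I))
  o0 <- rb_objective(dec, data)
  expect_equal(o0$e_conn, 0)
  expect_lt(o0$chi2_red, 1e-6)
  # stretch the spring to exactly 20 A beyond its reach: quadratic penalty
  spring <- dec$springs[1, ]
  pa <- as.numeric(dec$beads[spring$a, c("x", "y", "z")])
  pb <- as.numeric(dec$beads[spring$b, c("x", "y", "z")])
  u <- (pb - pa) / sqrt(sum((pb - pa)^2))
  shift <- (spring$rest + spring$slack - sqrt(sum((pb - pa)^2))) + 20
  dec2 <- dec
  i2 <- dec2$beads$body_id == 2
  dec2$beads$x[i2] <- dec2$beads$x[i2] + shift * u[1]
  dec2$beads$y[i2] <- dec2$beads$y[i2] + shift * u[2]
  dec2$beads$z[i2] <- dec2$beads$z[i2] + shift * u[3]
  o2 <- rb_objective(dec2, data)
  expect_equal(o2$e_conn, 20^2, tolerance = 1e-6)
  # deliberately overlapping bodies: clash energy grows with overlap depth
  ev <- vapply(c(0, 5, 10, 15), function(push) {
    dec3 <- dec
    i2 <- dec3$beads$body_id == 2
    dec3$beads$x[i2] <- dec3$beads$x[i2] - push
    rb_objective(dec3, data)$e_ev
  }, 1)
  expect_true(all(diff(ev) > 0))
})

test_that("the oligomer structure factor follows the documented convention", {
  qn <- pi / 65
  q <- sort(c(seq(0.001, 1.5, length.out = 400), qn))
  I_unit <- rep(1, length(q))
  expect_equal(apply_oligomer(I_unit, q, f = 0, d = 65), I_unit)
  # full pairing doubles the forward scattering
  expect_equal(apply_oligomer(1, 1e-9, f = 1, d = 65), 2, tolerance = 1e-6)
  # first node of the interference term at q = pi / d
  io <- apply_oligomer(I_unit, q, f = 0.65, d = 65)
  expect_equal(io[q == qn], 1, tolerance = 1e-9)
  # decays to the unit intensity at high q
  expect_lt(max(abs(io[q > 1] - 1)), 0.01)
  expect_error(apply_oligomer(I_unit, q, f = 0.5, d = -1), "d must")
  expect_error(apply_oligomer(I_unit, q, f = 1.2, d = 65), "f must")
})

test_that("refinement is a fixed point on self-consistent noise-free data", {
  dec <- rb_harness(seed = 6, n_res = 40, sep = 35)
  q <- seq(0.01, 0.25, length.out = 50)
  I <- debye_intensity(dec$beads, q)$I
  data <- saxs_curve(q, I, 0.01 * I)
  rb <- rb_refine(dec, data, rb_config(n_runs = 2, n_steps = 150, seed = 3))
  expect_lt(rb$runs$chi2_red[rb$best_run], 0.01)
  expect_lt(bead_rmsd(rb$beads, dec$beads), 1)
})

test_that("identical seeds give bit-identical refinements", {
  dec <- rb_harness(seed = 6, n_res = 30, sep = 32)
  q <- seq(0.01, 0.25, length.out = 40)
  I <- debye_intensity(dec$beads, q)$I
  set.seed(1)
  data <- saxs_curve(q, I + rnorm(length(q), 0, 0.01 * I), 0.01 * I)
  cfg <- rb_config(n_runs = 2, n_steps = 100, seed = 7)
  rb1 <- rb_refine(dec, data, cfg)
  rb2 <- rb_refine(dec, data, cfg)
  expect_identical(rb1$runs, rb2$runs)
  expect_identical(rb1$beads$x, rb2$beads$x)
  # the accepted best never exceeds the starting objective
  start_total <- rb_objective(dec, data)$total
  expect_lte(min(rb1$runs$total), start_total + 1e-9)
})

test_that("ten-run refinement recovers a known two-body perturbation", {
  dec <- rb_harness(seed = 21)
  tgt <- rb_target(dec)
  q <- seq(0.008, 0.3, length.out = 80)
  I_t <- debye_intensity(tgt, q)$I
  sig <- lab_sigma(q, I_t)
  set.seed(7)
  data <- saxs_curve(q, I_t + rnorm(length(q), 0, sig), sig)
  rb <- rb_refine(dec, data, rb_config(n_runs = 10, n_steps = 500,
                                       seed = 100))
  expect_equal(rb$runs$run, 1:10)
  # chi2 of the best run is compatible with the injected noise
  expect_lt(rb$runs$chi2_red[rb$best_run], 1.4)
  expect_gt(rb$runs$chi2_red[rb$best_run], 0.6)
  # body placement within 5 A of the target
  expect_lt(placement_rmsd(rb$beads, tgt), 5)
  # tie-break bookkeeping: best run attains the minimum total
  expect_equal(rb$runs$total[rb$best_run], min(rb$runs$total))
})

test_that("the unspecific-oligomer fraction and distance are recovered", {
  md <- make_model("multidomain_dimer", domain_residues = c(110, 70),
                   linker_residues = 4,
                   centres = list(c(20, 12, 0), c(13, 10, 28)), seed = 31)
  data <- simulate_curve(md, q = seq(0.006, 0.25, length.out = 110),
                         oligo = list(f = 0.65, d = 65), hydration = FALSE,
                         seed = 9)
  seg <- data.frame(chain = c("A", "A", "B", "B"),
                    start = c(1, 113, 1, 113), end = c(112, 184, 112, 184))
  dec <- decompose_bodies(md, seg)
  rb <- rb_refine(dec, data,
                  rb_config(n_runs = 3, n_steps = 250, seed = 50,
                            fit_oligomer = TRUE, oligo_refit_every = 80))
  expect_lt(abs(rb$oligo$f - 0.65), 0.10)
  expect_lt(abs(rb$oligo$d - 65), 10)
})
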