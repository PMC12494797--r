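# Structure geometry: SASA, buried interfaces, distances, masses, C2 axes.

test_that("SASA of an isolated atom is the probe-expanded sphere area", {
  s1 <- ca_structure(cbind(0, 0, 0))
  s1$atom <- "C"
  a <- sasa_total(sasa(s1))
  expect_equal(a, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
})

test_that("a fully enclosed atom has (near) zero accessible area", {
  # centre atom caged by a dense shell of neighbours
  sh <- saxsfit:::.sphere_points(60) * 2.4
  xyz <- rbind(c(0, 0, 0), sh)
  s <- ca_structure(xyz)
  s$atom <- "C"
  per_atom_area <- function(st) {
    heavy <- st
    rad <- rep(1.7 + 1.4, nrow(heavy))
    saxsfit:::.sasa_cpp(cbind(heavy$x, heavy$y, heavy$z), rad, 960L)
  }
  expect_lt(per_atom_area(s)[1], 1e-6)
})

test_that("SASA is converged in n_points and rigid-transform invariant", {
  md <- make_globule(50, seed = 12)
  a1 <- sasa_total(sasa(md, n_points = 960))
  a2 <- sasa_total(sasa(md, n_points = 1920))
  expect_lt(abs(a2 - a1) / a1, 0.005)
  R <- saxsfit:::.rot_matrix(c(1, 1, 0), 1.1)
  xyz <- as.matrix(md[, c("x", "y", "z")]) %*% t(R)
  md2 <- md
  md2$x <- xyz[, 1] + 5; md2$y <- xyz[, 2] - 3; md2$z <- xyz[, 3]
  expect_lt(abs(sasa_total(sasa(md2)) - a1) / a1, 0.001)
})

test_that("buried interface area is symmetric, bounded, and zero at distance", {
  md <- make_model("multidomain_dimer", domain_residues = c(60, 40),
                   linker_residues = 3,
                   centres = list(c(10, 7, 0), c(8, 6, 18)), seed = 2)
  b <- buried_interface_area(md, "A", "B")
  b2 <- buried_interface_area(md, "B", "A")
  expect_equal(b$buried_area, b2$buried_area, tolerance = 1e-6)
  expect_equal(b$interface_area, b$buried_area / 2)
  expect_equal(b$pct_buried, 100 * b$buried_area / (b$sasa_A + b$sasa_B))
  expect_gt(b$buried_area, 0)  # the chains touch at the dimer interface
  # pulled far apart: no burial
  far <- md
  iB <- far$chain == "B"
  far$x[iB] <- far$x[iB] + 200
  expect_equal(buried_interface_area(far, "A", "B")$buried_area, 0,
               tolerance = 1e-6)
  expect_error(buried_interface_area(md, "A", "A"), "overlap")
})

test_that("inter-CA distances are plain Euclidean lookups", {
  xyz <- rbind(c(0, 0, 0), c(3, 4, 0))
  s <- ca_structure(xyz, chain = c("A", "B"), resno = c(7, 7))
  expect_equal(inter_ca_distance(s, c("A", 7), c("B", 7)), 5)
  expect_equal(inter_ca_distance(s, c("A", 7), c("A", 7)), 0)
  expect_error(inter_ca_distance(s, c("A", 8), c("B", 7)), "residue 8")
})

test_that("sequence masses use the residue table plus one water per chain", {
  expect_equal(sequence_mass("GGGGGGGGGG") * 1000, 10 * 57.052 + 18.015)
  expect_equal(sequence_mass("G", n_chains = 2) * 1000,
               2 * (57.052 + 18.015))
  expect_error(sequence_mass(""), "unknown|empty")
  expect_error(sequence_mass(character(0)), "empty")
  # structure route: a homodimer weighs twice its chain (plus waters)
  md <- make_model("multidomain_dimer", domain_residues = c(60, 40),
                   linker_residues = 3, seed = 2)
  ch <- md[md$chain == "A", ]
  class(ch) <- class(md)
  expect_equal(sequence_mass(md), 2 * sequence_mass(ch), tolerance = 1e-9)
})

test_that("the two-fold axis of a constructed C2 dimer is found", {
  md <- make_model("multidomain_dimer", domain_residues = c(60, 40),
                   linker_residues = 3, seed = 7)
  ax <- find_c2_axis(md, "A", "B")
  expect_true(ax$two_fold)
  expect_equal(ax$angle, 180, tolerance = 0.01)
  expect_equal(abs(ax$direction[3]), 1, tolerance = 1e-6)
  # 0.5 A coordinate jitter barely moves the axis
  set.seed(3)
  mj <- md
  mj$x <- mj$x + rnorm(nrow(mj), 0, 0.5)
  mj$y <- mj$y + rnorm(nrow(mj), 0, 0.5)
  mj$z <- mj$z + rnorm(nrow(mj), 0, 0.5)
  axj <- find_c2_axis(mj, "A", "B")
  expect_gt(axj$angle, 179)
  expect_lte(axj$angle, 180)
  expect_lt(acos(min(1, abs(sum(axj$direction * c(0, 0, 1))))) * 180 / pi, 2)
  # a translated copy is flagged non-two-fold
  tr <- md
  iB <- tr$chain == "B"
  chA <- md[md$chain == "A", ]
  tr$x[iB] <- chA$x + 40; tr$y[iB] <- chA$y; tr$z[iB] <- chA$z
  axt <- find_c2_axis(tr, "A", "B")
  expect_lt(axt$angle, 10)
  expect_false(axt$two_fold)
  expect_error(find_c2_axis(md[1:4, ], "A", "B"), "3 matched")
})

test_that("axis alignment is exact, and re-detection is idempotent", {
  md <- make_model("multidomain_dimer", domain_residues = c(60, 40),
                   linker_residues = 3, seed = 7)
  ax <- find_c2_axis(md, "A", "B")
  # aligning an axis onto itself with zero spin is the identity
  out <- align_axes(md, ax, ax, spin_deg = 0)
  expect_lt(max(abs(out$x - md$x)), 1e-8)
  # perpendicular target: transformed axis becomes colinear with it
  tgt <- list(point = c(5, -3, 2), direction = c(1, 0, 0))
  out2 <- align_axes(md, ax, tgt)
  ax2 <- find_c2_axis(out2, "A", "B")
  expect_lt(acos(min(1, abs(sum(ax2$direction * tgt$direction)))), 1e-6)
  expect_lt(sqrt(sum((ax2$point - tgt$point)[2:3]^2)), 1e-4)
  # idempotence: a second alignment does nothing
  out3 <- align_axes(out2, ax2, tgt)
  expect_lt(max(abs(out3$x - out2$x)), 1e-4)
})

test_that("hybrid assembly co-locates the two-fold axes of its parts", {
  # a separately built small dimer stands in for an isolated-domain dimer
  core <- make_model("multidomain_dimer", domain_residues = c(60, 40),
                     linker_residues = 3, seed = 7)
  part <- make_model("multidomain_dimer", domain_residues = c(30, 20),
                     linker_residues = 2,
                     centres = list(c(9, 6, 0), c(7, 5, 14)), seed = 8)
  # displace the part arbitrarily, then align its axis onto the core's
  R <- saxsfit:::.rot_matrix(c(2, 1, 1), 1.2)
  xyz <- sweep(as.matrix(part[, c("x", "y", "z")]) %*% t(R), 2,
               c(30, -20, 10), "+")
  moved <- part
  moved$x <- xyz[, 1]; moved$y <- xyz[, 2]; moved$z <- xyz[, 3]
  ax_m <- find_c2_axis(moved, "A", "B")
  ax_c <- find_c2_axis(core, "A", "B")
  # avoid residue-number collisions in the combined model
  moved$resno <- moved$resno + 1000L
  hybrid <- align_axes(moved, ax_m, ax_c, combine_with = core)
  sub <- hybrid[hybrid$resno > 1000, ]
  class(sub) <- class(hybrid)
  ax_h <- find_c2_axis(sub, "A", "B")
  expect_lt(acos(min(1, abs(sum(ax_h$direction * ax_c$direction)))), 1e-6)
})
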