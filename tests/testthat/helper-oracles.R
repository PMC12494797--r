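# Closed-form oracles and fixture builders shared across the suite.

# uniform-sphere form factor intensity
sphere_intensity <- function(q, R, I0 = 1) {
  x <- q * R
  phi <- ifelse(x < 1e-8, 1, 3 * (sin(x) - x * cos(x)) / x^3)
  I0 * phi^2
}

# uniform-sphere pair-distance distribution (unnormalised)
sphere_pr <- function(r, R) {
  ifelse(r >= 0 & r <= 2 * R, r^2 * (1 - 3 * r / (4 * R) + r^3 / (16 * R^3)), 0)
}

# q position of the sphere form factor's first minimum
sphere_qmin <- function(R) 4.493 / R

# a valid measured-style sigma column for a model intensity
lab_sigma <- function(q, I, sigma0 = 0.01, q0 = 0.1, a = 2) {
  sigma0 * abs(I) * (1 + (q / q0)^a)
}

# single compact globule of n residues (chain A of a degenerate dimer)
make_globule <- function(n_res, seed) {
  md <- make_model("multidomain_dimer", domain_residues = c(n_res, 2),
                   linker_residues = 0,
                   centres = list(c(0, 0, 0), c(300, 0, 0)), seed = seed)
  gl <- md[md$chain == "A" & md$resno <= n_res, ]
  class(gl) <- class(md)
  gl
}

# small CA-only structure from explicit coordinates
ca_structure <- function(xyz, chain = "A", resname = "ALA",
                         resno = seq_len(nrow(xyz))) {
  structure_model(data.frame(
    chain = chain, resno = resno, resname = resname, atom = "CA",
    element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0))
}

# two-body single-chain harness with a 10-residue disordered gap at the cut
# (so the connectivity spring leaves room for the prescribed perturbation)
rb_harness <- function(seed = 21, n_res = 90, sep = 40, aspect = 2) {
  md <- make_model("multidomain_dimer", domain_residues = c(n_res, n_res),
                   linker_residues = 0,
                   centres = list(c(0, 0, 0), c(sep, 0, 0)),
                   domain_aspect = aspect, seed = seed)
  ch <- md[md$chain == "A", ]
  class(ch) <- class(md)
  ch$resno[ch$resno > n_res] <- ch$resno[ch$resno > n_res] + 10L
  seg <- data.frame(chain = "A", start = c(1, n_res + 11),
                    end = c(n_res + 10, 2 * n_res + 10))
  decompose_bodies(ch, seg)
}

# target for the recovery harness: body 2 spun 40 deg about its centroid
# and translated 15 A along the inter-domain axis
rb_target <- function(dec, angle_deg = 40, shift = c(15, 0, 0)) {
  tgt <- dec$beads
  i2 <- which(tgt$body_id == 2)
  p2 <- as.matrix(tgt[i2, c("x", "y", "z")])
  ctr <- colMeans(p2)
  R <- saxsfit:::.rot_matrix(c(0, 1, 0), angle_deg * pi / 180)
  p2n <- sweep(sweep(p2, 2, ctr) %*% t(R), 2, ctr + shift, "+")
  tgt$x[i2] <- p2n[, 1]; tgt$y[i2] <- p2n[, 2]; tgt$z[i2] <- p2n[, 3]
  tgt
}

# body-centroid placement RMSD after least-squares superposition of the
# whole refined model onto the target (removes the global rotation and
# translation that leave I(q) unchanged)
placement_rmsd <- function(beads, tgt) {
  A <- as.matrix(beads[, c("x", "y", "z")])
  B <- as.matrix(tgt[, c("x", "y", "z")])
  k <- saxsfit:::.kabsch(A, B)
  Ar <- sweep(A %*% t(k$R), 2, k$t, "+")
  br <- beads
  br$x <- Ar[, 1]; br$y <- Ar[, 2]; br$z <- Ar[, 3]
  body_placement_rmsd(br, tgt)
}

# write the shared minimal model as PDB and mmCIF text (same atoms)
write_fixture_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 10.00           C",
    "ATOM      3  CA AGLY A   2      10.000   5.000  -4.000  0.40 10.00           C",
    "ATOM      4  CA BGLY A   2      10.500   5.100  -4.100  0.60 10.00           C",
    "HETATM    5  O   HOH A 101       1.000   1.000   1.000  1.00 10.00           O",
    "END"), path)
  path
}

write_fixture_cif <- function(path) {
  writeLines(c(
    "data_fixture", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_seq_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "ATOM 1 N N . ALA A 1 11.104 6.134 -6.504 1.00 10.00 1 ALA A",
    "ATOM 2 C CA . ALA A 1 11.639 6.071 -5.147 1.00 10.00 1 ALA A",
    "ATOM 3 C CA A GLY A 2 10.000 5.000 -4.000 0.40 10.00 2 GLY A",
    "ATOM 4 C CA B GLY A 2 10.500 5.100 -4.100 0.60 10.00 2 GLY A",
    "HETATM 5 O O . HOH A . 1.000 1.000 1.000 1.00 10.00 101 HOH A",
    "#"), path)
  path
}
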