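# Seeded generators for synthetic bead models, structures, noisy SAXS
# curves and toy density maps.  These emulate the data regime of a
# laboratory-source solution-SAXS experiment on a flexible multi-domain
# homodimer: q = 0.005-0.35 1/A, relative errors growing with q, and an
# optional fraction of unspecifically paired particles.

#' Generate a synthetic model
#'
#' * `"sphere"`: `n` beads uniformly distributed in a ball of the given
#'   radius (bead model; Rg converges to `sqrt(3/5) * radius`).
#' * `"dumbbell"`: two uniform balls at centre separation `separation`
#'   joined by a string of linker beads; extent `separation + 2 * radius`.
#' * `"multidomain_dimer"`: a residue-typed, C2-symmetric two-chain
#'   structure; each chain is 2-3 globular pseudo-domains joined by
#'   extended pseudo-linkers, so [coarse_grain()], [decompose_bodies()]
#'   and [find_c2_axis()] all apply.
#'
#' @param shape `"sphere"`, `"dumbbell"` or `"multidomain_dimer"`.
#' @param radius Ball radius (A) for sphere/dumbbell.
#' @param n Bead count for the sphere.
#' @param separation Centre-centre distance (A) for the dumbbell.
#' @param n_per_lobe,n_linker Dumbbell bead counts.
#' @param domain_residues Residues per pseudo-domain (per chain; length 2
#'   or 3).
#' @param linker_residues Residues per inter-domain linker.
#' @param centres Optional list of domain-centre coordinates for chain A.
#' @param domain_aspect Prolate axis ratio of the pseudo-domains (1 =
#'   spherical); volume is preserved.
#' @param seed Seed fixing all randomness.
#' @return A `bead_model` (sphere, dumbbell) or `structure_model`
#'   (multidomain dimer).
#' @export
make_model <- function(shape = c("sphere", "dumbbell", "multidomain_dimer"),
                       radius = 50, n = 5000, separation = 100,
                       n_per_lobe = 800, n_linker = 20,
                       domain_residues = c(350, 150, 210),
                       linker_residues = 13, centres = NULL,
                       domain_aspect = 1, seed = 1) {
  shape <- match.arg(shape)
  withr::with_seed(seed, switch(shape,
    sphere = .make_sphere(radius, n),
    dumbbell = .make_dumbbell(radius, separation, n_per_lobe, n_linker),
    multidomain_dimer = .make_dimer(domain_residues, linker_residues, centres,
                                    domain_aspect)
  ))
}

.ball_points <- function(n, radius, centre = c(0, 0, 0)) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- radius * runif(n)^(1 / 3)
  sweep(u * r, 2, centre, "+")
}

# space-filling packing: n points on a jittered cubic lattice at the given
# per-point volume, nearest-to-centre first (protein interiors are packed at
# near-uniform density; independent uniform draws would add unphysical
# density fluctuations that corrupt Porod-type analyses)
.packed_ball_points <- function(n, centre = c(0, 0, 0), v_point = 135,
                                jitter = 0.5, aspect = 1) {
  a <- v_point^(1 / 3)
  m <- ceiling((n * 6 / pi)^(1 / 3) / 2) + 2
  m <- ceiling(m * max(aspect^(1 / 3), 1 / aspect^(2 / 3))) + 1
  g <- as.matrix(expand.grid(x = -m:m, y = -m:m, z = -m:m)) * a
  # volume-preserving prolate stretch along x by the aspect ratio
  sc <- c(aspect^(2 / 3), aspect^(-1 / 3), aspect^(-1 / 3))
  ord <- order(rowSums(sweep(g, 2, sc, "/")^2))
  g <- g[ord[seq_len(n)], , drop = FALSE]
  g <- g + matrix(rnorm(3 * n, 0, jitter), ncol = 3)
  sweep(g, 2, centre, "+")
}

.make_sphere <- function(radius, n) {
  p <- .ball_points(n, radius)
  bead_model(p[, 1], p[, 2], p[, 3], b = 1, sigma = 0)
}

.make_dumbbell <- function(radius, separation, n_per_lobe, n_linker) {
  c1 <- c(-separation / 2, 0, 0)
  c2 <- c(separation / 2, 0, 0)
  p <- rbind(.ball_points(n_per_lobe, radius, c1),
             .ball_points(n_per_lobe, radius, c2))
  if (n_linker > 0 && separation > 2 * radius) {
    tfrac <- seq(0, 1, length.out = n_linker + 2)[-c(1, n_linker + 2)]
    lx <- (-separation / 2 + radius) + tfrac * (separation - 2 * radius)
    p <- rbind(p, cbind(lx, rnorm(n_linker, 0, 1), rnorm(n_linker, 0, 1)))
  }
  bead_model(p[, 1], p[, 2], p[, 3], b = 1, sigma = 0)
}

# per-residue packing volume -> domain radius
.domain_radius <- function(n_res, v_res = 135) (3 * n_res * v_res / (4 * pi))^(1 / 3)

.make_dimer <- function(domain_residues, linker_residues, centres = NULL,
                        domain_aspect = 1) {
  nd <- length(domain_residues)
  stopifnot(nd >= 2, nd <= 3)
  if (is.null(centres)) {
    centres <- list(c(28, 14, 0), c(14, 10, 16), c(20, 6, 44))[seq_len(nd)]
  }
  rads <- .domain_radius(domain_residues)
  freq <- .aa_frequencies()
  rows <- list()
  resno <- 0L
  for (k in seq_len(nd)) {
    p <- .packed_ball_points(domain_residues[k], centres[[k]],
                             aspect = domain_aspect)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      resno = resno + seq_len(domain_residues[k]),
      resname = sample(names(freq), domain_residues[k], TRUE, prob = freq),
      x = p[, 1], y = p[, 2], z = p[, 3])
    resno <- resno + domain_residues[k]
    if (k < nd && linker_residues > 0) {
      a <- centres[[k]]; b <- centres[[k + 1]]
      dvec <- b - a; dl <- sqrt(sum(dvec^2)); dvec <- dvec / dl
      # extended chain geometry: ~3 A per residue, centred in the
      # inter-domain gap, so adjacent linker residues stay within a
      # peptide-bond spring's rest length
      mid <- dl / 2
      tpos <- mid + (seq_len(linker_residues) -
                       (linker_residues + 1) / 2) * 3.0
      p <- t(vapply(tpos, function(s) a + s * dvec, numeric(3))) +
        matrix(rnorm(3 * linker_residues, 0, 0.3), ncol = 3)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        resno = resno + seq_len(linker_residues),
        resname = sample(names(freq), linker_residues, TRUE, prob = freq),
        x = p[, 1], y = p[, 2], z = p[, 3])
      resno <- resno + linker_residues
    }
  }
  chainA <- dplyr::bind_rows(rows)
  chainB <- dplyr::mutate(chainA, x = -.data$x, y = -.data$y)  # Rz(180)
  atoms <- dplyr::bind_rows(
    dplyr::mutate(chainA, chain = "A"),
    dplyr::mutate(chainB, chain = "B")) |>
    dplyr::mutate(atom = "CA", element = "C", occ = 1, b = 0)
  structure_model(atoms)
}

#' Simulate a noisy SAXS curve from a model
#'
#' Computes the exact Debye intensity of the model (structures are
#' coarse-grained at residue level, with a hydration layer by default, as
#' in the forward model used for fitting), optionally applies the
#' unspecific-oligomer structure factor, and adds Gaussian noise with the
#' laboratory-source error model
#' `sigma(q) = sigma0 * I(q) * (1 + (q/q0)^a)`.
#'
#' @param model A `bead_model` or `structure_model`.
#' @param q Scattering vector grid (1/A).
#' @param sigma0 Relative error at q = 0 (default 0.01).
#' @param q0,a_exp Error growth scale (1/A) and exponent.
#' @param oligo Optional `list(f =, d =)` oligomer mixture parameters.
#' @param noise Add noise (`FALSE` returns the exact curve with the model
#'   sigma column).
#' @param hydration Add a hydration layer when coarse-graining a
#'   structure.
#' @param seed Seed for the noise draw.
#' @return A `saxs_curve`; the generating parameters are stored in
#'   `meta$truth`.
#' @export
simulate_curve <- function(model, q = seq(0.005, 0.35, length.out = 120),
                           sigma0 = 0.01, q0 = 0.1, a_exp = 2, oligo = NULL,
                           noise = TRUE, hydration = TRUE, seed = 1) {
  beads <- if (inherits(model, "structure_model")) {
    b <- coarse_grain(model, level = "residue")
    if (hydration) b <- add_hydration_layer(b)
    b
  } else {
    as_bead_model(model)
  }
  method <- if (nrow(beads) > 4000) "hist" else "exact"
  I <- debye_intensity(beads, q, method = method)$I
  if (!is.null(oligo)) I <- apply_oligomer(I, q, oligo$f, oligo$d)
  sig <- sigma0 * I * (1 + (q / q0)^a_exp)
  I_obs <- if (noise) {
    withr::with_seed(seed, I + rnorm(length(q), 0, sig))
  } else I
  saxs_curve(q, I_obs, sig,
             meta = list(truth = list(sigma0 = sigma0, q0 = q0, a_exp = a_exp,
                                      oligo = oligo, seed = seed,
                                      n_beads = nrow(beads))))
}

#' Rasterise a bead model into a toy density map
#'
#' Beads are splatted as isotropic Gaussians of width `blur_sigma` onto a
#' padded voxel grid.
#'
#' @param beads A `bead_model`.
#' @param voxel_size Voxel edge (A, default 3).
#' @param blur_sigma Gaussian splat width (A, default 4).
#' @param pad Padding around the bead bounding box (A; default
#'   `3 * blur_sigma`).
#' @return A `density_map`.
#' @export
make_toy_map <- function(beads, voxel_size = 3, blur_sigma = 4, pad = NULL) {
  if (voxel_size <= 0) abort("voxel_size must be > 0")
  beads <- as_bead_model(beads)
  pad <- pad %||% (3 * blur_sigma)
  pos <- .bead_pos(beads)
  lo <- apply(pos, 2, min) - pad
  hi <- apply(pos, 2, max) + pad
  dims <- pmax(2L, ceiling((hi - lo) / voxel_size))
  grid <- array(0, dim = dims)
  ax <- purrr::map(1:3, function(d) lo[d] + (seq_len(dims[d]) - 0.5) * voxel_size)
  reach <- ceiling(3 * blur_sigma / voxel_size)
  for (i in seq_len(nrow(beads))) {
    ic <- pmin(pmax(ceiling((pos[i, ] - lo) / voxel_size), 1L), dims)
    rng <- purrr::map(1:3, function(d) {
      max(1L, ic[d] - reach):min(dims[d], ic[d] + reach)
    })
    gx <- exp(-(ax[[1]][rng[[1]]] - pos[i, 1])^2 / (2 * blur_sigma^2))
    gy <- exp(-(ax[[2]][rng[[2]]] - pos[i, 2])^2 / (2 * blur_sigma^2))
    gz <- exp(-(ax[[3]][rng[[3]]] - pos[i, 3])^2 / (2 * blur_sigma^2))
    grid[rng[[1]], rng[[2]], rng[[3]]] <-
      grid[rng[[1]], rng[[2]], rng[[3]]] +
      beads$b[i] * outer(outer(gx, gy), gz)
  }
  density_map(grid, voxel_size, lo)
}
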