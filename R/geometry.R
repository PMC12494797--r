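# Structure geometry: solvent-accessible and buried interface areas,
# inter-C-alpha distances, sequence masses, two-fold axis detection and
# axis-aligned hybrid assembly.

.atom_radii <- function(elements) {
  r <- .vdw_radii[toupper(elements)]
  unk <- is.na(r)
  if (any(unk)) {
    warn(sprintf("sasa: unknown element(s) %s; using %.2f A radius",
                 paste(unique(elements[unk]), collapse = ", "), .vdw_default))
    r[unk] <- .vdw_default
  }
  unname(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-sampling SASA with `n_points` quadrature points per atom on a
#' golden-spiral lattice.  Hydrogens are ignored; heavy atoms use standard
#' van der Waals radii.
#'
#' @param structure A `structure_model`.
#' @param probe_radius Probe radius (A, default 1.4).
#' @param n_points Quadrature points per atom (default 960).
#' @return A tibble with per-residue areas (`chain`, `resno`, `resname`,
#'   `area`); the total area is in the `total` attribute (see
#'   [sasa_total()]).
#' @export
sasa <- function(structure, probe_radius = 1.4, n_points = 960) {
  heavy <- dplyr::filter(structure, .data$element != "H")
  if (nrow(heavy) == 0) abort("no heavy atoms")
  rad <- .atom_radii(heavy$element) + probe_radius
  area <- .sasa_cpp(cbind(heavy$x, heavy$y, heavy$z), rad, as.integer(n_points))
  per_res <- heavy |>
    dplyr::mutate(.area = area) |>
    dplyr::group_by(.data$chain, .data$resno) |>
    dplyr::summarise(resname = .data$resname[1], area = sum(.data$.area),
                     .groups = "drop")
  tibble::new_tibble(per_res, total = sum(area), class = "saxs_sasa")
}

#' Total solvent-accessible area of a [sasa()] result
#' @param x A `saxs_sasa` tibble.
#' @return Total area (A^2).
#' @export
sasa_total <- function(x) attr(x, "total")

#' Buried interface area between two selections
#'
#' Computes `SASA(A) + SASA(B) - SASA(A united with B)`, the buried area, and
#' reports both conventions: the PISA-style interface area (half the buried
#' area) and the unhalved buried area with its percentage of the total free
#' surface (`SASA(A) + SASA(B)`).
#'
#' @param structure A `structure_model` containing both selections.
#' @param selA,selB Chain id vectors, or `list(chains =, resno_range =)`
#'   selections.  Must be non-overlapping and non-empty.
#' @inheritParams sasa
#' @return A one-row tibble: `interface_area`, `buried_area`,
#'   `pct_buried`, `sasa_A`, `sasa_B`, `sasa_AB`.
#' @export
buried_interface_area <- function(structure, selA, selB, probe_radius = 1.4,
                                  n_points = 960) {
  pick <- function(sel) {
    if (is.character(sel)) {
      select_atoms(structure, chains = sel)
    } else {
      select_atoms(structure, chains = sel$chains,
                   resno_range = sel$resno_range)
    }
  }
  A <- pick(selA); B <- pick(selB)
  keyA <- paste(A$chain, A$resno, A$atom)
  keyB <- paste(B$chain, B$resno, B$atom)
  if (length(intersect(keyA, keyB))) abort("selections overlap")
  sA <- sasa_total(sasa(A, probe_radius, n_points))
  sB <- sasa_total(sasa(B, probe_radius, n_points))
  AB <- structure_model(dplyr::bind_rows(A, B))
  sAB <- sasa_total(sasa(AB, probe_radius, n_points))
  buried <- max(0, sA + sB - sAB)
  tibble::tibble(interface_area = buried / 2, buried_area = buried,
                 pct_buried = 100 * buried / (sA + sB),
                 sasa_A = sA, sasa_B = sB, sasa_AB = sAB)
}

#' Distance between two C-alpha atoms
#'
#' @param structure A `structure_model`.
#' @param a,b Residue selectors `c(chain, resno)` (chain as character,
#'   residue number coercible to integer).
#' @return Euclidean C-alpha to C-alpha distance (A).
#' @export
inter_ca_distance <- function(structure, a, b) {
  ca <- function(sel) {
    hit <- dplyr::filter(structure, .data$chain == as.character(sel[1]),
                         .data$resno == as.integer(sel[2]),
                         .data$atom == "CA")
    if (nrow(hit) == 0) {
      abort(sprintf("no C-alpha for chain %s residue %s", sel[1], sel[2]))
    }
    c(hit$x[1], hit$y[1], hit$z[1])
  }
  sqrt(sum((ca(a) - ca(b))^2))
}

.aa1_to_3 <- function(seq1) {
  rp <- residue_params()
  m <- match(strsplit(toupper(seq1), "")[[1]], rp$aa1)
  if (anyNA(m)) abort(sprintf("unknown residue code(s): %s",
                              paste(unique(strsplit(toupper(seq1), "")[[1]][is.na(m)]),
                                    collapse = ", ")))
  rp$resname[m]
}

#' Protein mass from a residue sequence or structure
#'
#' Sum of average residue masses plus one water per chain.
#'
#' @param x A one-letter sequence string, a character vector of three-letter
#'   residue names, or a `structure_model` (chains and residues taken from
#'   the model).
#' @param n_chains Number of identical chains when `x` is a sequence
#'   (default 1; use 2 for a homodimer).
#' @return Mass in kDa.
#' @export
sequence_mass <- function(x, n_chains = 1) {
  rp <- residue_params()
  if (inherits(x, "structure_model")) {
    res <- dplyr::distinct(x, .data$chain, .data$resno, .data$resname)
    if (nrow(res) == 0) abort("no residues in structure")
    m <- match(res$resname, rp$resname)
    mass <- numeric(length(m))
    mass[!is.na(m)] <- rp$mass[m[!is.na(m)]]
    if (anyNA(m)) {
      warn(sprintf("sequence_mass: %d non-standard residue(s) use average mass",
                   sum(is.na(m))))
      mass[is.na(m)] <- .average_residue()$mass
    }
    return((sum(mass) + length(unique(res$chain)) * .water_mass) / 1000)
  }
  res3 <- if (length(x) == 1 && !x[1] %in% rp$resname) .aa1_to_3(x) else toupper(x)
  if (length(res3) == 0) abort("empty sequence")
  m <- match(res3, rp$resname)
  if (anyNA(m)) abort(sprintf("unknown residue name(s): %s",
                              paste(unique(res3[is.na(m)]), collapse = ", ")))
  n_chains * (sum(rp$mass[m]) + .water_mass) / 1000
}

# Kabsch superposition: rotation R and translation t with R %*% a + t ~ b
.kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cb - drop(R %*% ca)
  rmsd <- sqrt(mean(rowSums((sweep(A, 2, ca) %*% t(R) -
                             sweep(B, 2, cb))^2)))
  list(R = R, t = t, rmsd = rmsd)
}

#' Detect the two-fold symmetry axis of a homodimer
#'
#' Least-squares superposition of the matched C-alpha atoms of chain A onto
#' chain B; the rotation angle and axis are extracted from the rotation
#' operator and a point on the axis from the screw decomposition.  The
#' result is flagged non-two-fold when the angle deviates from 180 degrees
#' by more than `tol_deg`.
#'
#' @param structure A `structure_model`.
#' @param chainA,chainB Chain ids.
#' @param tol_deg Two-fold tolerance in degrees (default 10).
#' @return An object of class `c2_axis`: `point`, `direction` (unit),
#'   `angle` (degrees, in `[0, 180]`), `rmsd`, `two_fold`.
#' @export
find_c2_axis <- function(structure, chainA, chainB, tol_deg = 10) {
  ca <- dplyr::filter(structure, .data$atom == "CA")
  A <- dplyr::filter(ca, .data$chain == chainA)
  B <- dplyr::filter(ca, .data$chain == chainB)
  common <- intersect(A$resno, B$resno)
  if (length(common) < 3) abort("fewer than 3 matched C-alpha pairs")
  A <- dplyr::arrange(dplyr::filter(A, .data$resno %in% common), .data$resno)
  B <- dplyr::arrange(dplyr::filter(B, .data$resno %in% common), .data$resno)
  pa <- cbind(A$x, A$y, A$z); pb <- cbind(B$x, B$y, B$z)
  k <- .kabsch(pa, pb)
  R <- k$R
  ang <- acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  # rotation axis: eigenvector of R with eigenvalue 1
  e <- eigen(R)
  i1 <- which.min(abs(e$values - 1))
  u <- Re(e$vectors[, i1])
  u <- u / sqrt(sum(u^2))
  # fix sign so rotation about +u by +ang reproduces R (via skew part);
  # at 180 degrees the sign is immaterial
  if (ang < 179) {
    skew <- (R - t(R)) / 2
    v <- c(skew[3, 2], skew[1, 3], skew[2, 1])
    if (sum(v * u) < 0) u <- -u
  }
  # canonical sign: largest-magnitude component positive
  if (u[which.max(abs(u))] < 0) u <- -u
  # axis point: least-squares solution of (I - R) p = t_perp
  IR <- diag(3) - R
  tperp <- k$t - sum(k$t * u) * u
  sv <- svd(IR)
  dinv <- ifelse(sv$d > 1e-8, 1 / sv$d, 0)
  p <- drop(sv$v %*% (dinv * crossprod(sv$u, tperp)))
  # move to the axis point closest to the dimer centroid
  ctr <- colMeans(rbind(pa, pb))
  p <- p + sum((ctr - p) * u) * u
  out <- list(point = p, direction = u, angle = ang, rmsd = k$rmsd,
              two_fold = abs(ang - 180) <= tol_deg)
  class(out) <- "c2_axis"
  out
}

#' @export
print.c2_axis <- function(x, ...) {
  cat(sprintf(
    "C2 axis: angle %.1f deg (%stwo-fold), direction (%.3f, %.3f, %.3f)\n",
    x$angle, if (x$two_fold) "" else "NOT ", x$direction[1], x$direction[2],
    x$direction[3]))
  invisible(x)
}

#' Align a structure's symmetry axis onto a target axis
#'
#' Applies the rigid transform that makes the mobile axis colinear and
#' co-located with the target axis; the residual rotational freedom about
#' the shared axis is set by `spin_deg`.  Optionally returns the hybrid
#' model combining the transformed mobile structure with a partner.
#'
#' @param mobile A `structure_model` to transform.
#' @param mobile_axis,target_axis `c2_axis` objects (or lists with `point`
#'   and `direction`).
#' @param spin_deg Spin about the shared axis (degrees).
#' @param combine_with Optional `structure_model` appended (untransformed)
#'   to form the hybrid model.
#' @return The transformed (optionally combined) `structure_model`; the
#'   applied rotation and translation are stored in the `transform`
#'   attribute.
#' @export
align_axes <- function(mobile, mobile_axis, target_axis, spin_deg = 0,
                       combine_with = NULL) {
  um <- mobile_axis$direction / sqrt(sum(mobile_axis$direction^2))
  ut <- target_axis$direction / sqrt(sum(target_axis$direction^2))
  if (any(!is.finite(um)) || any(!is.finite(ut))) abort("degenerate axis")
  cr <- c(um[2] * ut[3] - um[3] * ut[2], um[3] * ut[1] - um[1] * ut[3],
          um[1] * ut[2] - um[2] * ut[1])
  dt <- sum(um * ut)
  if (sqrt(sum(cr^2)) < 1e-12) {
    R1 <- if (dt > 0) diag(3) else {
      # antiparallel: rotate 180 about any perpendicular
      perp <- if (abs(um[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      perp <- perp - sum(perp * um) * um
      .rot_matrix(perp, pi)
    }
  } else {
    R1 <- .rot_matrix(cr, acos(min(1, max(-1, dt))))
  }
  R <- .rot_matrix(ut, spin_deg * pi / 180) %*% R1
  t <- target_axis$point - drop(R %*% mobile_axis$point)
  pos <- cbind(mobile$x, mobile$y, mobile$z)
  newpos <- sweep(pos %*% t(R), 2, t, "+")
  out <- mobile
  out$x <- newpos[, 1]; out$y <- newpos[, 2]; out$z <- newpos[, 3]
  if (!is.null(combine_with)) {
    out <- structure_model(dplyr::bind_rows(out, combine_with))
  }
  attr(out, "transform") <- list(R = R, t = t)
  out
}
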