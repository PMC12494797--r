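# Coarse-grained bead models and the Debye-equation forward calculator.

#' Construct a bead model
#'
#' A bead model is a tibble of coarse-grained scatterers: positions (A),
#' effective excess scattering length `b` (electrons), Gaussian smearing
#' width `sigma` (A), `kind` (`"protein"` or `"hydration"`) and an integer
#' `body_id` rigid-body label.
#'
#' @param x,y,z Bead coordinates (A).
#' @param b Effective scattering lengths.
#' @param sigma Gaussian form-factor widths (A), `>= 0` (0 = point bead).
#' @param kind Bead kinds.
#' @param body_id Rigid-body labels (0 = unassigned).
#' @return A tibble of class `bead_model`.
#' @export
bead_model <- function(x, y, z, b = 1, sigma = 0, kind = "protein",
                       body_id = 0L) {
  n <- length(x)
  df <- tibble::tibble(
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    b = rep_len(as.numeric(b), n), sigma = rep_len(as.numeric(sigma), n),
    kind = rep_len(as.character(kind), n),
    body_id = rep_len(as.integer(body_id), n))
  if (nrow(df) == 0) abort("empty bead model")
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))) {
    abort("non-finite bead positions")
  }
  if (any(!is.finite(df$b))) abort("non-finite scattering lengths")
  if (any(df$sigma < 0)) abort("gauss widths must be >= 0")
  tibble::new_tibble(df, class = "bead_model")
}

#' @export
tbl_sum.bead_model <- function(x, ...) {
  c("Bead model" = sprintf("%d beads (%d hydration), %d bodies",
                           nrow(x), sum(x$kind == "hydration"),
                           length(setdiff(unique(x$body_id), 0L))))
}

#' Coerce a data frame to a bead model
#' @param df A data frame with at least `x`, `y`, `z` columns.
#' @return A `bead_model`.
#' @export
as_bead_model <- function(df) {
  if (inherits(df, "bead_model")) return(df)
  bead_model(df$x, df$y, df$z, df[["b"]] %||% 1, df[["sigma"]] %||% 0,
             df[["kind"]] %||% "protein", df[["body_id"]] %||% 0L)
}

.bead_pos <- function(beads) cbind(beads$x, beads$y, beads$z)

#' Radius of gyration of a bead model
#'
#' Scattering-length-weighted second moment about the centre of mass.
#' @param beads A `bead_model` (or data frame with x, y, z and optional b).
#' @return Rg in A.
#' @export
bead_rg <- function(beads) {
  w <- abs(beads[["b"]] %||% rep(1, nrow(beads)))
  pos <- .bead_pos(as_bead_model(beads))
  ctr <- colSums(pos * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(pos, 2, ctr)^2)) / sum(w))
}

#' Coarse-grain an atomic model into beads
#'
#' At `level = "residue"` each residue becomes one bead at its heavy-atom
#' centroid with `b = electrons - rho_solvent * V_residue` (tabulated
#' residue volumes) and a Gaussian width whose second moment matches a
#' uniform sphere of the residue volume.  At `level = "atom"` each heavy
#' atom becomes a bead with atomic electron counts and displaced volumes.
#' Unknown residues fall back to average-residue parameters with a warning.
#'
#' @param structure A `structure_model`.
#' @param level `"residue"` or `"atom"`.
#' @param rho_solvent Solvent electron density (e/A^3, default 0.334).
#' @return A `bead_model` (kind `"protein"`, `body_id = 0`).
#' @export
coarse_grain <- function(structure, level = c("residue", "atom"),
                         rho_solvent = .rho_solvent_default) {
  level <- match.arg(level)
  if (nrow(structure) == 0) abort("empty structure")
  if (level == "residue") {
    heavy <- dplyr::filter(structure, .data$element != "H")
    res <- heavy |>
      dplyr::group_by(.data$chain, .data$resno) |>
      dplyr::summarise(resname = .data$resname[1], x = mean(.data$x),
                       y = mean(.data$y), z = mean(.data$z), .groups = "drop")
    rp <- residue_params()
    res <- dplyr::left_join(res, rp, by = "resname")
    unk <- is.na(res$electrons)
    if (any(unk)) {
      avg <- .average_residue()
      warn(sprintf("coarse_grain: %d unknown residue(s) (%s); using average parameters",
                   sum(unk), paste(unique(res$resname[unk]), collapse = ", ")))
      res$electrons[unk] <- avg$electrons
      res$volume[unk] <- avg$volume
    }
    out <- bead_model(res$x, res$y, res$z,
                      b = res$electrons - rho_solvent * res$volume,
                      sigma = .gauss_width(res$volume))
    attr(out, "residues") <- res[c("chain", "resno", "resname")]
    out
  } else {
    heavy <- dplyr::filter(structure, .data$element != "H")
    ap <- .atom_params()
    m <- match(heavy$element, ap$element)
    unk <- is.na(m)
    if (any(unk)) {
      warn(sprintf("coarse_grain: unknown element(s) %s; using carbon parameters",
                   paste(unique(heavy$element[unk]), collapse = ", ")))
      m[unk] <- match("C", ap$element)
    }
    bead_model(heavy$x, heavy$y, heavy$z,
               b = ap$electrons[m] - rho_solvent * ap$volume[m],
               sigma = .gauss_width(ap$volume[m]))
  }
}

# golden-spiral points on the unit sphere
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (3 - sqrt(5)) * (i - 0.5)
  cbind(r * cos(th), r * sin(th), z)
}

#' Add a hydration layer of shell beads
#'
#' Places candidate points at `bead_radius + thickness` outside each
#' protein bead's surface (bead radius `sigma * sqrt(5)`, the
#' uniform-sphere equivalent), rejects points falling inside any other
#' bead's exclusion radius, and thins survivors to about one bead per
#' `area_per_bead` of surface.  Shell beads get
#' `b = contrast_fraction * rho_water * V_shell` with
#' `V_shell = area_per_bead * thickness`.
#'
#' @param beads A `bead_model` with protein beads.
#' @param thickness Shell thickness (A, default 3).
#' @param contrast_fraction Shell contrast as a fraction of the water
#'   electron density (default 0.10).
#' @param area_per_bead Surface area per shell bead (A^2, default 15).
#' @param rho_water Water electron density (e/A^3).
#' @return The input model with hydration beads appended
#'   (kind `"hydration"`).
#' @export
add_hydration_layer <- function(beads, thickness = 3, contrast_fraction = 0.10,
                                area_per_bead = 15,
                                rho_water = .rho_solvent_default) {
  beads <- as_bead_model(beads)
  if (thickness <= 0) abort("thickness must be > 0")
  prot <- dplyr::filter(beads, .data$kind == "protein")
  if (nrow(prot) == 0) abort("no protein beads to hydrate")
  a <- prot$sigma * sqrt(5)          # uniform-sphere-equivalent radius
  a[a <= 0] <- 1.0                   # point beads: nominal 1 A radius
  shell_r <- a + thickness
  pos <- .bead_pos(prot)
  cand <- purrr::map(seq_len(nrow(prot)), function(i) {
    np <- max(8L, ceiling(4 * pi * shell_r[i]^2 / area_per_bead))
    sweep(.sphere_points(np) * shell_r[i], 2, pos[i, ], "+")
  })
  cand <- do.call(rbind, cand)
  # reject candidates inside any bead's exclusion radius
  keep <- rep(TRUE, nrow(cand))
  for (j in seq_len(nrow(prot))) {
    d2 <- rowSums(sweep(cand, 2, pos[j, ])^2)
    keep <- keep & d2 >= (shell_r[j] - 1e-6)^2
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) > 0) {
    # grid thinning at the target surface density
    s <- sqrt(area_per_bead)
    cell <- floor(sweep(cand, 2, apply(cand, 2, min)) / s)
    key <- paste(cell[, 1], cell[, 2], cell[, 3])
    cand <- cand[!duplicated(key), , drop = FALSE]
  }
  v_shell <- area_per_bead * thickness
  shell <- bead_model(cand[, 1], cand[, 2], cand[, 3],
                      b = contrast_fraction * rho_water * v_shell,
                      sigma = .gauss_width(v_shell), kind = "hydration")
  out <- dplyr::bind_rows(beads, shell)
  tibble::new_tibble(out, class = "bead_model")
}

#' SAXS intensity of a bead model via the Debye equation
#'
#' `I(q) = sum_ij f_i(q) f_j(q) sinc(q r_ij)` with per-bead Gaussian form
#' factors `f_i(q) = b_i exp(-q^2 sigma_i^2 / 2)`.  `method = "exact"` is
#' the O(N^2) double sum; `method = "hist"` bins pair distances (bin width
#' `dr`, bin-centre evaluation, one histogram per pair of bead types) and
#' converges to the exact sum as `dr -> 0`.
#'
#' @param beads A `bead_model`.
#' @param q Scattering vector grid (1/A).
#' @param method `"exact"` or `"hist"`.
#' @param dr Histogram bin width (A, default 0.5).
#' @return A model `saxs_curve` (sigma zero-flagged).
#' @export
debye_intensity <- function(beads, q, method = c("exact", "hist"), dr = 0.5) {
  method <- match.arg(method)
  beads <- as_bead_model(beads)
  if (nrow(beads) == 0) abort("empty bead model")
  q <- as.numeric(q)
  pos <- .bead_pos(beads)
  if (method == "exact" || nrow(beads) < 3) {
    I <- .debye_exact_cpp(pos, beads$b, beads$sigma, q)
  } else {
    key <- paste(signif(beads$b, 12), signif(beads$sigma, 12))
    typ <- match(key, unique(key)) - 1L
    first <- !duplicated(key)
    I <- .debye_hist_cpp(pos, typ, beads$b[first], beads$sigma[first], q, dr)
  }
  saxs_curve(q, I, model = TRUE,
             meta = list(source = "debye", method = method, n_beads = nrow(beads)))
}

#' Fit scale and background of a model curve to data
#'
#' Weighted linear least squares for `I_data ~ scale * I_model +
#' background`; the model is first interpolated to the data grid by cubic
#' spline if the grids differ.
#'
#' @param model_curve A model `saxs_curve` (or data frame with q, I).
#' @param data A measured `saxs_curve` with positive sigma.
#' @param background Fit an additive constant (default `TRUE`).
#' @return An object of class `saxs_fit`: `scale`, `background`,
#'   `chi2_red` (`sum(((c Im + b - Id)/sigma)^2) / (N - n_par)`), `n`,
#'   `n_par`, and a `data` tibble with the scaled model.
#' @export
fit_scale_background <- function(model_curve, data, background = TRUE) {
  data <- as_saxs_curve(data)
  n <- nrow(data)
  if (n <= 2) abort("need more than 2 data points")
  mq <- model_curve$q
  mI <- model_curve$I
  Im <- if (length(mq) == n && max(abs(mq - data$q)) < 1e-12) mI else {
    if (min(data$q) < min(mq) - 1e-9 || max(data$q) > max(mq) + 1e-9) {
      warn("fit_scale_background: data q range extends beyond model; spline extrapolating")
    }
    spline(mq, mI, xout = data$q, method = "natural")$y
  }
  sig <- ifelse(data$sigma > 0, data$sigma, 0.01 * abs(data$I))
  w <- 1 / sig^2
  if (background) {
    fit <- lm(data$I ~ Im, weights = w)
    sc <- unname(coef(fit)[2]); bg <- unname(coef(fit)[1]); npar <- 2L
  } else {
    sc <- sum(w * Im * data$I) / sum(w * Im^2); bg <- 0; npar <- 1L
  }
  resid <- data$I - (sc * Im + bg)
  chi2_red <- sum(w * resid^2) / (n - npar)
  out <- list(scale = sc, background = bg, chi2_red = chi2_red, n = n,
              n_par = npar,
              data = tibble::tibble(q = data$q, I = data$I, sigma = sig,
                                    I_model = sc * Im + bg))
  class(out) <- "saxs_fit"
  out
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat(sprintf("scale = %.4g, background = %.4g, reduced chi2 = %.4g (n = %d)\n",
              x$scale, x$background, x$chi2_red, x$n))
  invisible(x)
}
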