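# Rigid-body decomposition and simulated-annealing refinement against SAXS
# data, with soft connectivity / excluded-volume restraints and an
# unspecific-oligomer structure factor.

#' Decompose a structure into rigid bodies
#'
#' Coarse-grains the structure at residue level, labels beads with body ids
#' from the segment definitions, and generates connectivity springs at every
#' sequence-adjacent residue pair split across bodies (rest length
#' `3.8 A * sequence gap`, slack `1.5 A` per missing residue).  Residues not
#' covered by any segment are assigned to the nearest body (by sequence
#' distance within the chain) with a warning; overlapping segments are an
#' error.
#'
#' @param structure A `structure_model`.
#' @param segments Body definitions: a data frame with columns `chain`,
#'   `start`, `end` (one row per body), or a list of
#'   `list(chain =, start =, end =)`.
#' @param slack_per_missing Spring slack per missing residue (A).
#' @return An object of class `rb_decomposition`: `beads` (a
#'   `bead_model` with `body_id`), `springs` (tibble `a`, `b`, `rest`,
#'   `slack`), `K`, `segments`.
#' @export
decompose_bodies <- function(structure, segments, slack_per_missing = 1.5) {
  if (is.data.frame(segments)) {
    seg <- tibble::as_tibble(segments)
  } else {
    seg <- purrr::map_dfr(segments, tibble::as_tibble)
  }
  stopifnot(all(c("chain", "start", "end") %in% names(seg)))
  seg$body <- seq_len(nrow(seg))
  # overlap check within chains
  for (ch in unique(seg$chain)) {
    s <- dplyr::arrange(dplyr::filter(seg, .data$chain == ch), .data$start)
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      abort(sprintf("overlapping segments in chain %s: residue assigned twice", ch))
    }
  }
  beads <- coarse_grain(structure, level = "residue")
  res <- attr(beads, "residues")
  body <- rep(NA_integer_, nrow(beads))
  for (i in seq_len(nrow(seg))) {
    hit <- res$chain == seg$chain[i] & res$resno >= seg$start[i] &
      res$resno <= seg$end[i]
    body[hit] <- seg$body[i]
  }
  if (anyNA(body)) {
    n_un <- sum(is.na(body))
    for (j in which(is.na(body))) {
      cand <- seg[seg$chain == res$chain[j], , drop = FALSE]
      if (nrow(cand) == 0) cand <- seg
      d <- pmin(abs(res$resno[j] - cand$start), abs(res$resno[j] - cand$end))
      body[j] <- cand$body[which.min(d)]
    }
    warn(sprintf("decompose_bodies: %d uncovered residue(s) assigned to nearest body",
                 n_un))
  }
  beads$body_id <- body
  # springs at sequence-adjacent pairs crossing a body boundary
  springs <- list()
  for (ch in unique(res$chain)) {
    idx <- which(res$chain == ch)
    idx <- idx[order(res$resno[idx])]
    if (length(idx) < 2) next
    for (k in seq_len(length(idx) - 1)) {
      a <- idx[k]; b <- idx[k + 1]
      if (body[a] != body[b]) {
        gap <- res$resno[b] - res$resno[a]
        springs[[length(springs) + 1L]] <- tibble::tibble(
          a = a, b = b, rest = 3.8 * gap,
          slack = slack_per_missing * max(0, gap - 1))
      }
    }
  }
  springs <- if (length(springs)) dplyr::bind_rows(springs) else {
    tibble::tibble(a = integer(), b = integer(), rest = numeric(),
                   slack = numeric())
  }
  out <- list(beads = beads, springs = springs, K = nrow(seg),
              segments = seg, residues = res)
  class(out) <- "rb_decomposition"
  out
}

#' @export
print.rb_decomposition <- function(x, ...) {
  cat(sprintf("Rigid-body decomposition: %d beads in %d bodies, %d springs\n",
              nrow(x$beads), x$K, nrow(x$springs)))
  invisible(x)
}

#' Unspecific-oligomer structure factor
#'
#' Interference correction for a mass fraction `f` of scattering units
#' transiently paired (dimers of dimers) at centre-of-mass distance `d`:
#' `I(q) = I_unit(q) * (1 + f * sin(qd)/(qd))`, so the forward scattering
#' scales as `1 + f` and the correction decays to 1 at high q.
#'
#' @param I_unit Intensity of the free unit on grid `q`.
#' @param q Scattering vector grid (1/A).
#' @param f Mass fraction of units engaged in pairs, in `[0, 1]`.
#' @param d Inter-unit centre-of-mass distance (A), `> 0`.
#' @return Corrected intensities.
#' @export
apply_oligomer <- function(I_unit, q, f, d) {
  if (d <= 0) abort("oligomer distance d must be > 0")
  if (f < 0 || f > 1) abort("oligomer fraction f must be in [0, 1]")
  I_unit * (1 + f * .sinc(q * d))
}

# fast weighted linear fit of data ~ scale * model + background
.wls_fit <- function(Im, Id, w, background = TRUE) {
  if (background) {
    s1 <- sum(w); sm <- sum(w * Im); smm <- sum(w * Im^2)
    sy <- sum(w * Id); smy <- sum(w * Im * Id)
    det <- smm * s1 - sm^2
    sc <- (smy * s1 - sm * sy) / det
    bg <- (smm * sy - sm * smy) / det
    npar <- 2L
  } else {
    sc <- sum(w * Im * Id) / sum(w * Im^2); bg <- 0; npar <- 1L
  }
  r <- Id - sc * Im - bg
  list(scale = sc, background = bg,
       chi2_red = sum(w * r^2) / (length(Id) - npar))
}

# spring energy: sum over springs of max(0, dist - (rest + slack))^2
.spring_energy <- function(pos, springs) {
  if (nrow(springs) == 0) return(0)
  d <- sqrt(rowSums((pos[springs$a, , drop = FALSE] -
                     pos[springs$b, , drop = FALSE])^2))
  sum(pmax(0, d - (springs$rest + springs$slack))^2)
}

# clash energy of spring-bonded pairs; bonded neighbours are connectivity,
# not sterics, so this is subtracted from the inter-body clash sum
.spring_clash <- function(pos, springs, r_clash) {
  if (nrow(springs) == 0) return(0)
  d <- sqrt(rowSums((pos[springs$a, , drop = FALSE] -
                     pos[springs$b, , drop = FALSE])^2))
  sum(pmax(0, r_clash - d)^2)
}

#' Penalised rigid-body objective
#'
#' `total = chi2_red + w_conn * E_conn + w_ev * E_ev` where `chi2_red` is
#' the reduced chi-squared of the (oligomer-corrected, scale/background
#' fitted) Debye intensity against the data, `E_conn` the quadratic
#' overstretch energy of the connectivity springs and `E_ev` the quadratic
#' inter-body clash penalty below `r_clash`.
#'
#' @param decomp An `rb_decomposition`.
#' @param data A measured `saxs_curve`.
#' @param oligo Optional `list(f =, d =)` oligomer parameters.
#' @param w_conn,w_ev Restraint weights.
#' @param r_clash Bead-centre clash cutoff (A).
#' @return A list `chi2_red`, `e_conn`, `e_ev`, `total`.
#' @export
rb_objective <- function(decomp, data, oligo = NULL, w_conn = 10, w_ev = 1,
                         r_clash = 3.8) {
  beads <- decomp$beads
  data <- as_saxs_curve(data)
  Iu <- debye_intensity(beads, data$q, method = "exact")$I
  Im <- if (is.null(oligo)) Iu else apply_oligomer(Iu, data$q, oligo$f, oligo$d)
  sig <- ifelse(data$sigma > 0, data$sigma, 0.01 * abs(data$I))
  chi2 <- .wls_fit(Im, data$I, 1 / sig^2)$chi2_red
  pos <- .bead_pos(beads)
  e_conn <- .spring_energy(pos, decomp$springs)
  ids <- sort(unique(beads$body_id))
  e_ev <- 0
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1)) {
      e_ev <- e_ev + .clash_penalty_cpp(
        pos[beads$body_id == ids[i], , drop = FALSE],
        pos[beads$body_id == ids[j], , drop = FALSE], r_clash)
    }
  }
  e_ev <- max(0, e_ev - .spring_clash(pos, decomp$springs, r_clash))
  list(chi2_red = chi2, e_conn = e_conn, e_ev = e_ev,
       total = chi2 + w_conn * e_conn + w_ev * e_ev)
}

#' Rigid-body refinement configuration
#'
#' @param n_runs Independent annealing runs (default 10).
#' @param n_steps Metropolis steps per run.
#' @param rot_sigma Rotation proposal width (degrees).
#' @param trans_sigma Translation proposal width (A).
#' @param w_conn,w_ev Restraint weights.
#' @param r_clash Clash cutoff (A).
#' @param t_start,t_end Geometric annealing temperature schedule.
#' @param seed Base seed; run `r` uses `seed + r - 1`.
#' @param fit_oligomer Jointly fit the unspecific-oligomer structure
#'   factor.
#' @param oligo_refit_every Steps between oligomer re-fits.
#' @param f_grid,d_grid Oligomer grid-search values.
#' @return A list of class `rb_config`.
#' @export
rb_config <- function(n_runs = 10, n_steps = 3000, rot_sigma = 8,
                      trans_sigma = 3, w_conn = 10, w_ev = 1, r_clash = 3.8,
                      t_start = 2, t_end = 0.01, seed = 1,
                      fit_oligomer = FALSE, oligo_refit_every = 250,
                      f_grid = seq(0, 1, 0.05), d_grid = seq(30, 120, 5)) {
  stopifnot(n_runs >= 1, rot_sigma > 0, trans_sigma > 0, n_steps >= 1)
  structure(as.list(environment()), class = "rb_config")
}

# rotation matrix about unit axis u by angle (radians)
.rot_matrix <- function(u, angle) {
  u <- u / sqrt(sum(u^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * c_ + s_ * ux + (1 - c_) * tcrossprod(u)
}

# best oligomer parameters for a given unit intensity: grid + Nelder-Mead
.fit_oligo <- function(Iu, q, Id, w, f_grid, d_grid) {
  obj <- function(par) {
    f <- min(max(par[1], 0), 1); d <- max(par[2], 1)
    .wls_fit(apply_oligomer(Iu, q, f, d), Id, w)$chi2_red
  }
  grid <- expand.grid(f = f_grid, d = d_grid)
  chi <- vapply(seq_len(nrow(grid)),
                function(i) obj(c(grid$f[i], grid$d[i])), 1)
  best <- which.min(chi)
  start <- c(grid$f[best], grid$d[best])
  o <- optim(start, obj, method = "Nelder-Mead",
             control = list(maxit = 200))
  f <- min(max(o$par[1], 0), 1); d <- max(o$par[2], 1)
  list(f = f, d = d, chi2_red = o$value)
}

#' Rigid-body refinement by multi-run simulated annealing
#'
#' Runs `n_runs` independently seeded Metropolis simulated-annealing
#' trajectories.  Each step picks one random body, proposes a rotation
#' about its centroid (random axis, normal angle) plus a normal
#' translation, and accepts on the penalised objective
#' (see [rb_objective()]).  Intra-body Debye terms are rotation-invariant
#' and cached; only cross-body interference terms are recomputed for the
#' moved body.  When `fit_oligomer` is set, the oligomer parameters
#' `(f, d)` are re-fitted periodically by grid search plus Nelder-Mead.
#'
#' @param decomp An `rb_decomposition`.
#' @param data A measured `saxs_curve`.
#' @param config An [rb_config()].
#' @return An object of class `saxs_rb`: `runs` (per-run tibble of
#'   chi2/penalties/oligomer/seed), `best_run`, `beads` (best model),
#'   `fit` (best `saxs_fit`), `oligo`, `config`.
#' @export
rb_refine <- function(decomp, data, config = rb_config()) {
  data <- as_saxs_curve(data)
  q <- data$q
  sig <- ifelse(data$sigma > 0, data$sigma, 0.01 * abs(data$I))
  w <- 1 / sig^2
  beads0 <- decomp$beads
  ids <- sort(unique(beads0$body_id))
  K <- length(ids)
  bi <- purrr::map(ids, function(id) which(beads0$body_id == id))
  bset <- purrr::map(bi, function(ii) {
    list(pos = .bead_pos(beads0)[ii, , drop = FALSE],
         b = beads0$b[ii], sigma = beads0$sigma[ii])
  })
  I_intra <- purrr::map(bset, function(s) {
    .debye_exact_cpp(s$pos, s$b, s$sigma, q)
  })
  cross0 <- function(posl) {
    C <- vector("list", K * K)
    for (i in seq_len(K)) for (j in seq_len(i - 1)) {
      C[[(i - 1) * K + j]] <- .debye_cross_cpp(
        posl[[i]], bset[[i]]$b, bset[[i]]$sigma,
        posl[[j]], bset[[j]]$b, bset[[j]]$sigma, q)
    }
    C
  }
  ev0 <- function(posl) {
    E <- matrix(0, K, K)
    for (i in seq_len(K)) for (j in seq_len(i - 1)) {
      E[i, j] <- .clash_penalty_cpp(posl[[i]], posl[[j]], config$r_clash)
    }
    E
  }
  spring_e <- function(posl) {
    if (nrow(decomp$springs) == 0) return(c(0, 0))
    pos <- matrix(0, nrow(beads0), 3)
    for (k in seq_len(K)) pos[bi[[k]], ] <- posl[[k]]
    c(.spring_energy(pos, decomp$springs),
      .spring_clash(pos, decomp$springs, config$r_clash))
  }
  sumI <- function(Ii, C) {
    tot <- Reduce(`+`, Ii)
    for (i in seq_len(K)) for (j in seq_len(i - 1)) tot <- tot + C[[(i - 1) * K + j]]
    tot
  }
  chi2_of <- function(Iu, oligo) {
    Im <- if (is.null(oligo)) Iu else apply_oligomer(Iu, q, oligo$f, oligo$d)
    .wls_fit(Im, data$I, w)$chi2_red
  }
  temps <- config$t_start *
    (config$t_end / config$t_start)^((seq_len(config$n_steps) - 1) /
                                       max(1, config$n_steps - 1))
  runs <- vector("list", config$n_runs)
  best_states <- vector("list", config$n_runs)
  for (run in seq_len(config$n_runs)) {
    run_seed <- config$seed + run - 1L
    withr::with_seed(run_seed, {
      posl <- purrr::map(bset, "pos")
      C <- cross0(posl)
      E <- ev0(posl)
      Iu <- sumI(I_intra, C)
      oligo <- if (config$fit_oligomer) {
        .fit_oligo(Iu, q, data$I, w, config$f_grid, config$d_grid)
      } else NULL
      chi2 <- chi2_of(Iu, oligo)
      se <- spring_e(posl)
      e_conn <- se[1]
      e_ev <- max(0, sum(E) - se[2])
      total <- chi2 + config$w_conn * e_conn + config$w_ev * e_ev
      if (!is.finite(total)) abort("non-finite objective at start of refinement")
      best <- list(posl = posl, total = total, chi2 = chi2, e_conn = e_conn,
                   e_ev = e_ev, oligo = oligo)
      for (step in seq_len(config$n_steps)) {
        k <- sample.int(K, 1)
        ctr <- colMeans(posl[[k]])
        ax <- rnorm(3)
        ang <- rnorm(1, 0, config$rot_sigma) * pi / 180
        R <- .rot_matrix(ax, ang)
        shift <- rnorm(3, 0, config$trans_sigma)
        newpos <- sweep(sweep(posl[[k]], 2, ctr) %*% t(R), 2, ctr + shift, "+")
        trial <- posl
        trial[[k]] <- newpos
        Cnew <- C
        Enew <- E
        for (j in seq_len(K)) {
          if (j == k) next
          i2 <- max(j, k); j2 <- min(j, k)
          Cnew[[(i2 - 1) * K + j2]] <- .debye_cross_cpp(
            trial[[i2]], bset[[i2]]$b, bset[[i2]]$sigma,
            trial[[j2]], bset[[j2]]$b, bset[[j2]]$sigma, q)
          Enew[i2, j2] <- .clash_penalty_cpp(trial[[i2]], trial[[j2]],
                                             config$r_clash)
        }
        Iu_new <- sumI(I_intra, Cnew)
        chi2_new <- chi2_of(Iu_new, oligo)
        se_new <- spring_e(trial)
        e_conn_new <- se_new[1]
        e_ev_new <- max(0, sum(Enew) - se_new[2])
        total_new <- chi2_new + config$w_conn * e_conn_new +
          config$w_ev * e_ev_new
        if (is.finite(total_new) &&
            (total_new <= total ||
             runif(1) < exp(-(total_new - total) / temps[step]))) {
          posl <- trial; C <- Cnew; E <- Enew; Iu <- Iu_new
          chi2 <- chi2_new; e_conn <- e_conn_new; e_ev <- e_ev_new
          total <- total_new
        }
        if (config$fit_oligomer && step %% config$oligo_refit_every == 0) {
          oligo <- .fit_oligo(Iu, q, data$I, w, config$f_grid, config$d_grid)
          chi2 <- chi2_of(Iu, oligo)
          total <- chi2 + config$w_conn * e_conn + config$w_ev * e_ev
        }
        if (total < best$total) {
          best <- list(posl = posl, total = total, chi2 = chi2,
                       e_conn = e_conn, e_ev = e_ev, oligo = oligo)
        }
      }
      if (config$fit_oligomer) {
        Iu_b <- sumI(I_intra, cross0(best$posl))
        best$oligo <- .fit_oligo(Iu_b, q, data$I, w, config$f_grid,
                                 config$d_grid)
        best$chi2 <- chi2_of(Iu_b, best$oligo)
        best$total <- best$chi2 + config$w_conn * best$e_conn +
          config$w_ev * best$e_ev
      }
      best_states[[run]] <- best
      runs[[run]] <- tibble::tibble(
        run = run, seed = run_seed, chi2_red = best$chi2,
        e_conn = best$e_conn, e_ev = best$e_ev, total = best$total,
        f = if (is.null(best$oligo)) NA_real_ else best$oligo$f,
        d = if (is.null(best$oligo)) NA_real_ else best$oligo$d)
    })
  }
  runs <- dplyr::bind_rows(runs)
  best_run <- with(runs, which(total == min(total)))[1]
  bs <- best_states[[best_run]]
  beads_best <- beads0
  pos <- matrix(0, nrow(beads0), 3)
  for (k in seq_len(K)) pos[bi[[k]], ] <- bs$posl[[k]]
  beads_best$x <- pos[, 1]; beads_best$y <- pos[, 2]; beads_best$z <- pos[, 3]
  Iu_best <- sumI(I_intra, cross0(bs$posl))
  Im_best <- if (is.null(bs$oligo)) Iu_best else {
    apply_oligomer(Iu_best, q, bs$oligo$f, bs$oligo$d)
  }
  fit <- fit_scale_background(saxs_curve(q, Im_best, model = TRUE), data)
  out <- list(runs = runs, best_run = best_run, beads = beads_best,
              fit = fit, oligo = bs$oligo, config = config,
              springs = decomp$springs)
  class(out) <- "saxs_rb"
  out
}

#' @export
print.saxs_rb <- function(x, ...) {
  cat(sprintf("Rigid-body refinement: %d run(s); best run %d, chi2 = %.3g\n",
              nrow(x$runs), x$best_run, x$runs$chi2_red[x$best_run]))
  if (!is.null(x$oligo)) {
    cat(sprintf("  oligomer: f = %.2f, d = %.1f A\n", x$oligo$f, x$oligo$d))
  }
  invisible(x)
}

#' Body-placement RMSD between two decomposed bead models
#'
#' Root-mean-square deviation over per-body centroids (index-matched
#' beads, matched `body_id` labels).  This is the placement metric a
#' rotationally averaged scattering curve can actually constrain for
#' compact bodies; per-bead RMSD additionally counts spins of a body
#' about its own centroid, to which I(q) is largely blind.
#'
#' @param a,b Bead models with identical `body_id` labelling.
#' @return Centroid RMSD (A).
#' @export
body_placement_rmsd <- function(a, b) {
  ca <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(a), .data$body_id),
                         x = mean(.data$x), y = mean(.data$y),
                         z = mean(.data$z))
  cb <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(b), .data$body_id),
                         x = mean(.data$x), y = mean(.data$y),
                         z = mean(.data$z))
  stopifnot(identical(ca$body_id, cb$body_id))
  sqrt(mean(rowSums((as.matrix(ca[c("x", "y", "z")]) -
                     as.matrix(cb[c("x", "y", "z")]))^2)))
}

#' RMSD between two bead models (index-matched)
#'
#' @param a,b Bead models (or data frames) with equal bead counts.
#' @return Root-mean-square coordinate deviation (A).
#' @export
bead_rmsd <- function(a, b) {
  pa <- cbind(a$x, a$y, a$z); pb <- cbind(b$x, b$y, b$z)
  if (nrow(pa) != nrow(pb)) abort("bead counts differ")
  sqrt(mean(rowSums((pa - pb)^2)))
}
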