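# broom-style tidy()/glance() methods for fitted objects.

#' @export
tidy.saxs_guinier <- function(x, ...) {
  tibble::tibble(term = c("Rg", "I0"), estimate = c(x$Rg, x$I0),
                 std.error = c(x$Rg_se, x$I0_se))
}

#' @export
glance.saxs_guinier <- function(x, ...) {
  tibble::tibble(Rg = x$Rg, Rg_se = x$Rg_se, I0 = x$I0, I0_se = x$I0_se,
                 qmin = x$q_range[1], qmax = x$q_range[2],
                 n_points = x$n_points, qmax_rg = x$qmax_rg)
}

#' @export
tidy.saxs_pr <- function(x, ...) {
  tibble::tibble(r = x$r, p = x$p, p_se = x$p_se)
}

#' @export
glance.saxs_pr <- function(x, ...) {
  tibble::tibble(Dmax = x$Dmax, alpha = x$alpha, Rg_pr = x$Rg_pr,
                 I0_pr = x$I0_pr, chi2_fit = x$chi2_fit,
                 evidence = x$evidence, mode = x$mode)
}

#' @export
tidy.saxs_invariants <- function(x, ...) {
  tibble::tibble(
    term = c("porod_Q", "Vp", "Vc", "mass_porod", "mass_vc"),
    estimate = c(x$porod_Q, x$Vp, x$Vc, x$mass_porod, x$mass_vc))
}

#' @export
glance.saxs_invariants <- function(x, ...) {
  tibble::tibble(porod_Q = x$porod_Q, Vp = x$Vp, Vc = x$Vc,
                 mass_porod = x$mass_porod, mass_vc = x$mass_vc,
                 q_cutoff_porod = x$q_cutoff_porod,
                 q_cutoff_vc = x$q_cutoff_vc)
}

#' @export
glance.saxs_fit <- function(x, ...) {
  tibble::tibble(scale = x$scale, background = x$background,
                 chi2_red = x$chi2_red, n = x$n, n_par = x$n_par)
}

#' @export
tidy.saxs_rb <- function(x, ...) x$runs

#' @export
glance.saxs_rb <- function(x, ...) {
  b <- x$runs[x$best_run, ]
  tibble::tibble(best_run = x$best_run, chi2_red = b$chi2_red,
                 e_conn = b$e_conn, e_ev = b$e_ev, total = b$total,
                 f = b$f, d = b$d, scale = x$fit$scale,
                 background = x$fit$background)
}

#' @export
tidy.saxs_mapscan <- function(x, ...) x$profile

#' @export
glance.saxs_mapscan <- function(x, ...) {
  tibble::tibble(best_threshold = x$best_threshold, chi2_red = x$best_chi2,
                 n_beads = nrow(x$best_beads))
}

#' @export
glance.c2_axis <- function(x, ...) {
  tibble::tibble(angle = x$angle, two_fold = x$two_fold, rmsd = x$rmsd,
                 dir_x = x$direction[1], dir_y = x$direction[2],
                 dir_z = x$direction[3])
}
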