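# Guinier analysis and the dimensionless Kratky transform.

#' Guinier fit with automatic low-q range selection
#'
#' Weighted linear regression of `ln I(q)` against `q^2` over the largest
#' low-q window satisfying `qmax * Rg <= qmax_rg`.  The window is found by
#' self-consistent iteration: an initial Rg estimate from the lowest-q
#' points sets the window, the fit updates Rg, and the window is re-derived
#' until stable.  The slope is `-Rg^2 / 3`, the intercept `ln I(0)`.
#' Weights are `(I / sigma)^2`, the propagated precision of `ln I`.
#'
#' After the window is fixed, a validity guard optionally trims it while
#' the quadratic term of a weighted fit of `ln I` in `q^2` is
#' statistically significant (|t| > 3), i.e. while the data visibly curve
#' away from the Guinier law inside the window; this removes the
#' systematic Rg bias that a fixed `qmax * Rg` window incurs on compact
#' particles while leaving noisy windows untouched.
#'
#' @param curve A `saxs_curve`.
#' @param qmax_rg Upper limit on `qmax * Rg` (default 1.3).
#' @param qmin Optional lower q bound (drop beam-stop-contaminated points).
#' @param refine_window Apply the curvature guard (default `TRUE`).
#' @return An object of class `saxs_guinier`: `Rg`, `I0` (with standard
#'   errors), `q_range`, `n_points`, and a `data` tibble with the fitted
#'   line and standardised residuals for the Guinier residual plot.
#' @export
guinier_fit <- function(curve, qmax_rg = 1.3, qmin = NULL,
                        refine_window = TRUE) {
  curve <- as_saxs_curve(curve)
  df <- dplyr::filter(curve, .data$I > 0)
  if (!is.null(qmin)) df <- dplyr::filter(df, .data$q >= qmin)
  if (nrow(df) < 5) abort("need >= 5 points with I > 0 for a Guinier fit")
  sig <- ifelse(df$sigma > 0, df$sigma, 0.01 * df$I)
  w <- (df$I / sig)^2
  lnI <- log(df$I)
  q2 <- df$q^2

  fit_window <- function(n) {
    idx <- seq_len(n)
    fit <- lm(lnI[idx] ~ q2[idx], weights = w[idx])
    slope <- coef(fit)[2]
    list(fit = fit, slope = slope,
         Rg = if (slope < 0) sqrt(-3 * slope) else NA_real_)
  }

  n_all <- nrow(df)
  n <- n_all  # robust initial estimate from the full window, then shrink
  f <- fit_window(n)
  if (!is.finite(f$Rg)) {
    abort("positive Guinier slope (Rg^2 < 0): aggregation or repulsion signature")
  }
  seen <- integer()
  for (iter in 1:50) {
    qlim <- qmax_rg / f$Rg
    n_new <- max(which(df$q <= qlim))
    if (!is.finite(n_new) || n_new < 5) {
      abort(sprintf(
        "no window with >= 5 points satisfies qmax*Rg <= %.3g", qmax_rg))
    }
    n_new <- min(n_new, n_all)
    if (n_new == n) break
    if (n_new %in% seen) {  # oscillation: take the larger stable window
      n_new <- max(n, n_new)
      n <- n_new
      f <- fit_window(n)
      break
    }
    seen <- c(seen, n)
    n <- n_new
    f <- fit_window(n)
    if (!is.finite(f$Rg)) {
      abort("positive Guinier slope (Rg^2 < 0): aggregation or repulsion signature")
    }
  }
  if (refine_window) {
    while (n > 8) {
      idx <- seq_len(n)
      qf <- lm(lnI[idx] ~ q2[idx] + I(q2[idx]^2), weights = w[idx])
      cc <- summary(qf)$coefficients
      if (nrow(cc) < 3 || !is.finite(cc[3, 3]) || abs(cc[3, 3]) <= 3) break
      n <- max(8L, floor(0.9 * n))
      f2 <- fit_window(n)
      if (!is.finite(f2$Rg)) break
      f <- f2
    }
  }
  fit <- f$fit
  cf <- summary(fit)$coefficients
  Rg <- f$Rg
  I0 <- exp(cf[1, 1])
  Rg_se <- if (nrow(cf) >= 2) abs(3 * cf[2, 2] / (2 * sqrt(-3 * cf[2, 1]))) else NA
  idx <- seq_len(n)
  resid_std <- (lnI[idx] - stats::fitted(fit)) * sqrt(w[idx])
  out <- list(
    Rg = unname(Rg), I0 = unname(I0),
    Rg_se = unname(Rg_se), I0_se = unname(I0 * cf[1, 2]),
    q_range = c(df$q[1], df$q[n]), n_points = n,
    qmax_rg = unname(df$q[n] * Rg), qmax_rg_limit = qmax_rg,
    data = tibble::tibble(q = df$q[idx], q2 = q2[idx], lnI = lnI[idx],
                          fitted = stats::fitted(fit), resid_std = resid_std)
  )
  class(out) <- "saxs_guinier"
  out
}

#' @export
print.saxs_guinier <- function(x, ...) {
  cat(sprintf("Guinier fit: Rg = %.2f +/- %.2f A, I(0) = %.4g +/- %.2g\n",
              x$Rg, x$Rg_se, x$I0, x$I0_se))
  cat(sprintf("  q range %.4g-%.4g 1/A (%d points), qmax*Rg = %.2f\n",
              x$q_range[1], x$q_range[2], x$n_points, x$qmax_rg))
  invisible(x)
}

#' Dimensionless Kratky transform
#'
#' Transforms a curve to `(Rg q, (Rg q)^2 I(q) / I(0))`.  Globular
#' particles peak near `(sqrt(3), 3/e)` and decay; flexible chains plateau
#' at high q.  The plateau estimate (mean of the transformed values over
#' the top decile of q) supports that flexibility diagnostic.
#'
#' @param curve A `saxs_curve`.
#' @param guinier A `saxs_guinier` fit of the same curve.
#' @return A tibble of class `saxs_kratky` with columns `x = Rg*q`,
#'   `y = (Rg*q)^2 I/I0`; attributes `plateau`, `Rg`, `I0`.
#' @export
kratky_transform <- function(curve, guinier) {
  curve <- as_saxs_curve(curve)
  if (!inherits(guinier, "saxs_guinier")) abort("guinier must be a saxs_guinier")
  if (guinier$I0 <= 0) abort("I(0) must be positive")
  x <- guinier$Rg * curve$q
  y <- x^2 * curve$I / guinier$I0
  top <- curve$q >= stats::quantile(curve$q, 0.9)
  tibble::new_tibble(
    tibble::tibble(x = x, y = y),
    plateau = mean(y[top]), Rg = guinier$Rg, I0 = guinier$I0,
    class = "saxs_kratky"
  )
}

#' Kratky high-q plateau estimate
#' @param kratky A `saxs_kratky` transform.
#' @return Mean transformed value over the top decile of q.
#' @export
kratky_plateau <- function(kratky) attr(kratky, "plateau")
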