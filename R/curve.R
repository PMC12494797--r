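# ScatteringCurve container and SAXS .dat I/O.

#' Construct a scattering curve
#'
#' A scattering curve is a tibble with columns `q` (scattering-vector
#' modulus, 1/A, strictly increasing), `I` (intensity) and `sigma`
#' (1-sigma uncertainty, same units as `I`).  Free-form provenance lives in
#' the `meta` attribute.  Model curves computed by the Debye engine carry
#' `sigma = 0` and `meta$model = TRUE`; measured curves must have
#' `sigma > 0`.
#'
#' @param q Scattering vector moduli (1/A), non-negative.  Rows are sorted
#'   by `q`.
#' @param I Intensities (absolute scale, 1/cm, or arbitrary units if
#'   flagged in `meta$units`).
#' @param sigma Uncertainties; strictly positive unless `model = TRUE`.
#' @param meta Named list of provenance (sample name, units flag, ...).
#' @param model Logical; `TRUE` for noise-free model curves (allows
#'   `sigma = 0`).
#' @return A tibble of class `saxs_curve`.
#' @export
saxs_curve <- function(q, I, sigma = NULL, meta = list(), model = FALSE) {
  q <- as.numeric(q)
  I <- as.numeric(I)
  if (is.null(sigma)) {
    sigma <- if (model) rep(0, length(q)) else 0.01 * abs(I)
  }
  sigma <- as.numeric(sigma)
  if (length(q) != length(I) || length(q) != length(sigma)) {
    abort("q, I and sigma must have equal length")
  }
  if (any(!is.finite(q)) || any(q < 0)) abort("q must be finite and >= 0")
  ord <- order(q)
  q <- q[ord]; I <- I[ord]; sigma <- sigma[ord]
  if (any(duplicated(q))) abort("q values must be strictly increasing")
  if (!model && any(sigma <= 0)) abort("sigma must be > 0 for measured curves")
  if (model) meta$model <- TRUE
  tibble::new_tibble(
    tibble::tibble(q = q, I = I, sigma = sigma),
    meta = meta, class = "saxs_curve"
  )
}

#' @export
tbl_sum.saxs_curve <- function(x, ...) {
  c("SAXS curve" = sprintf("%d points, q %.4g-%.4g 1/A",
                           nrow(x), min(x$q), max(x$q)))
}

#' Coerce a data frame to a scattering curve
#'
#' @param x A data frame with columns `q`, `I` and optionally `sigma`.
#' @inheritParams saxs_curve
#' @return A `saxs_curve` tibble.
#' @export
as_saxs_curve <- function(x, meta = list(), model = FALSE) {
  if (inherits(x, "saxs_curve")) return(x)
  stopifnot(all(c("q", "I") %in% names(x)))
  saxs_curve(x$q, x$I, x[["sigma"]], meta = meta, model = model)
}

#' Curve metadata
#' @param curve A `saxs_curve`.
#' @return The `meta` attribute (a named list).
#' @export
curve_meta <- function(curve) attr(curve, "meta") %||% list()

#' Read a SAXS curve from a text file
#'
#' Parses whitespace- or comma-separated files with at least three numeric
#' columns (q, I, sigma).  Header and comment lines (any line whose first
#' token is not a number) are skipped.  Rows with non-finite values or
#' non-positive sigma are dropped with a warning.  The reference dialect is
#' the SASBDB 3-column `.dat` file with an optional header block.
#'
#' @param path File path.
#' @param units Units flag recorded in the metadata: `"abs"` (1/cm),
#'   `"arb"`, or `"unknown"`.
#' @param qunit `"A"` for 1/A (default) or `"nm"` to convert 1/nm input to
#'   1/A (divides q by 10).  Never auto-detected.
#' @param allow_two_columns If `TRUE`, accept 2-column (q, I) files and
#'   synthesise `sigma` as 1 percent of `I`.
#' @return A `saxs_curve`.
#' @export
read_saxs <- function(path, units = c("unknown", "abs", "arb"),
                      qunit = c("A", "nm"), allow_two_columns = FALSE) {
  units <- match.arg(units)
  qunit <- match.arg(qunit)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  rows <- list()
  for (ln in lines) {
    toks <- strsplit(gsub(",", " ", ln), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) == 0 || is.na(vals[1])) next  # header/comment
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(rows) == 0) abort(sprintf("no numeric rows in %s", path))
  ncol_min <- min(vapply(rows, length, 1L))
  if (ncol_min < 3 && !(ncol_min == 2 && allow_two_columns)) {
    abort(sprintf(
      "%s has %d numeric columns; need >= 3 (or 2 with allow_two_columns)",
      path, ncol_min))
  }
  m <- do.call(rbind, lapply(rows, function(v) v[seq_len(min(ncol_min, 3))]))
  q <- m[, 1]; I <- m[, 2]
  sigma <- if (ncol_min >= 3) m[, 3] else 0.01 * abs(I)
  keep <- is.finite(q) & is.finite(I) & is.finite(sigma) & sigma > 0 & q >= 0
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    warn(sprintf("read_saxs: dropped %d row(s) with non-finite values or sigma <= 0",
                 n_drop))
  }
  if (!any(keep)) abort(sprintf("no valid rows in %s", path))
  if (qunit == "nm") q <- q / 10
  saxs_curve(q[keep], I[keep], sigma[keep],
             meta = list(path = path, units = units, n_dropped = n_drop))
}

#' Write a scattering curve (and optional model column) to a .dat file
#'
#' @param curve A `saxs_curve`.
#' @param path Output path.
#' @param I_model Optional model intensities on the same q grid; written as
#'   a fourth column.
#' @return `path`, invisibly.
#' @export
write_saxs <- function(curve, path, I_model = NULL) {
  curve <- as_saxs_curve(curve)
  hdr <- "# q(1/A) I sigma"
  cols <- list(curve$q, curve$I, curve$sigma)
  if (!is.null(I_model)) {
    stopifnot(length(I_model) == nrow(curve))
    hdr <- "# q(1/A) I_exp sigma I_model"
    cols <- c(cols, list(I_model))
  }
  body <- do.call(sprintf, c(list(paste(rep("%.8g", length(cols)),
                                        collapse = " ")), cols))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Serialise fit results to a flat text report and JSON
#'
#' Writes a human-readable `key: value` report and a machine-readable JSON
#' file (same stem, `.json` extension).  Any object with a `glance()` method
#' (Guinier fits, p(r) transforms, invariant sets, rigid-body results, ...)
#' can be reported; plain named lists are written as-is.
#'
#' @param results A named list of fitted objects and/or scalars.
#' @param path Output path for the text report.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  flat <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    row <- tryCatch(glance(x), error = function(e) NULL)
    if (!is.null(row) && is.data.frame(row)) {
      for (cn in names(row)) {
        v <- row[[cn]][1]
        if (is.numeric(v) || is.character(v) || is.logical(v)) {
          flat[[paste(nm, cn, sep = ".")]] <- v
        }
      }
    } else if (is.numeric(x) && length(x) == 1) {
      flat[[nm]] <- x
    } else if (is.list(x)) {
      for (cn in names(x)) {
        if (is.numeric(x[[cn]]) && length(x[[cn]]) == 1) {
          flat[[paste(nm, cn, sep = ".")]] <- x[[cn]]
        }
      }
    }
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(sprintf("cannot write report to %s", path))
  })
  on.exit(close(con))
  for (nm in names(flat)) {
    writeLines(sprintf("%s: %s", nm, format(flat[[nm]], digits = 8)), con)
  }
  jsonlite::write_json(flat, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
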