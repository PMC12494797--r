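# StructureModel container and PDB/mmCIF I/O.

#' Construct a structure model
#'
#' A structure model is a tibble of atoms with columns `chain`, `resno`,
#' `resname`, `atom`, `element`, `x`, `y`, `z`, `occ`, `b`.
#' Coordinates are in Angstrom.
#'
#' @param atoms A data frame with the columns above.
#' @return A tibble of class `structure_model`.
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "resno", "resname", "atom", "element",
            "x", "y", "z", "occ", "b")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  atoms <- tibble::as_tibble(atoms)[need]
  if (nrow(atoms) == 0) abort("empty structure model")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("non-finite coordinates")
  }
  tibble::new_tibble(atoms, class = "structure_model")
}

#' @export
tbl_sum.structure_model <- function(x, ...) {
  c("Structure" = sprintf("%d atoms, %d chain(s), %d residues",
                          nrow(x), length(unique(x$chain)),
                          nrow(dplyr::distinct(x, .data$chain, .data$resno))))
}

.water_resnames <- c("HOH", "WAT", "DOD", "H2O")

# resolve alternate locations to the highest occupancy (tie -> first seen)
.resolve_altloc <- function(df) {
  df |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$chain, .data$resno, .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occ), .data$.row, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row")
}

#' Read an atomic model from PDB or mmCIF
#'
#' Loads all ATOM/HETATM records.  Alternate locations are resolved to the
#' highest-occupancy conformer (ties broken by file order); waters are
#' excluded by default.  The format is chosen by file extension
#' (`.cif`/`.mmcif` for mmCIF, anything else is treated as PDB).
#'
#' @param path File path.
#' @param keep_waters Keep water molecules (default `FALSE`).
#' @param keep_hetero Keep non-water HETATM records (default `TRUE`).
#' @return A `structure_model`.
#' @export
read_structure <- function(path, keep_waters = FALSE, keep_hetero = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("cif", "mmcif")) .read_mmcif(path) else .read_pdb(path)
  if (!keep_waters) df <- dplyr::filter(df, !(.data$resname %in% .water_resnames))
  if (!keep_hetero) df <- dplyr::filter(df, !.data$het)
  df <- .resolve_altloc(df)
  df$het <- NULL
  if (nrow(df) == 0) abort(sprintf("no atoms in %s", path))
  structure_model(df)
}

.read_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) abort(sprintf("cannot parse PDB %s: %s",
                                                    path, conditionMessage(e))))
  a <- pdb$atom
  elem <- toupper(trimws(a$elesy))
  guess <- toupper(substr(trimws(a$elety), 1, 1))
  elem[!nzchar(elem)] <- guess[!nzchar(elem)]
  tibble::tibble(
    chain = as.character(a$chain),
    resno = as.integer(a$resno),
    resname = toupper(trimws(a$resid)),
    atom = trimws(a$elety),
    element = elem,
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    het = a$type == "HETATM"
  )
}

# Minimal mmCIF _atom_site loop parser (coordinates only).
.read_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L; n <- length(lines)
  fields <- character(); rows <- list()
  while (i <= n) {
    if (grepl("^\\s*loop_", lines[i])) {
      j <- i + 1L; flds <- character()
      while (j <= n && grepl("^\\s*_", lines[j])) {
        flds <- c(flds, trimws(lines[j])); j <- j + 1L
      }
      if (any(grepl("^_atom_site\\.", flds))) {
        fields <- sub("^_atom_site\\.", "", flds)
        while (j <= n) {
          ln <- trimws(lines[j])
          if (!nzchar(ln) || grepl("^(#|loop_|_|data_)", ln)) break
          toks <- scan(text = ln, what = character(), quiet = TRUE)
          if (length(toks) == length(fields)) {
            rows[[length(rows) + 1L]] <- toks
          }
          j <- j + 1L
        }
        i <- j
        if (length(rows)) break
      } else {
        i <- j
      }
    } else {
      i <- i + 1L
    }
  }
  if (!length(rows)) abort(sprintf("no _atom_site loop in %s", path))
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  getf <- function(...) {
    for (f in c(...)) if (f %in% fields) return(m[, f])
    rep(NA_character_, nrow(m))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  df <- tibble::tibble(
    chain = as.character(getf("auth_asym_id", "label_asym_id")),
    resno = as.integer(num(getf("auth_seq_id", "label_seq_id"))),
    resname = toupper(getf("auth_comp_id", "label_comp_id")),
    atom = gsub('"', "", getf("auth_atom_id", "label_atom_id")),
    element = toupper(getf("type_symbol")),
    x = num(getf("Cartn_x")), y = num(getf("Cartn_y")), z = num(getf("Cartn_z")),
    occ = num(getf("occupancy")), b = num(getf("B_iso_or_equiv")),
    het = getf("group_PDB") == "HETATM"
  )
  df$occ[is.na(df$occ)] <- 1
  df$b[is.na(df$b)] <- 0
  df$het[is.na(df$het)] <- FALSE
  if (any(!is.finite(df$x))) abort(sprintf("unparseable coordinates in %s", path))
  df
}

#' Write a structure model (or bead model) as PDB
#'
#' Bead models are written as pseudo-atom CA records (one residue per bead).
#'
#' @param x A `structure_model` or `bead_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "bead_model")) {
    xyz <- .bead_pos(x)
    x <- structure_model(tibble::tibble(
      chain = "A", resno = seq_len(nrow(xyz)), resname = "DUM", atom = "CA",
      element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
      b = 0))
  }
  rec <- sprintf(
    "ATOM  %5d %-4s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    (seq_len(nrow(x)) - 1L) %% 99999L + 1L,
    substr(ifelse(nchar(x$atom) >= 4, x$atom, paste0(" ", x$atom)), 1, 4),
    substr(x$resname, 1, 4),
    substr(x$chain, 1, 1),
    x$resno %% 10000L,
    x$x, x$y, x$z, x$occ, x$b, substr(x$element, 1, 2))
  writeLines(c(rec, "END"), path)
  invisible(path)
}

#' Select atoms by chain and residue range
#'
#' @param structure A `structure_model`.
#' @param chains Character vector of chain ids (or `NULL` for all).
#' @param resno_range Optional `c(lo, hi)` residue-number window.
#' @return A `structure_model` subset.
#' @export
select_atoms <- function(structure, chains = NULL, resno_range = NULL) {
  df <- structure
  if (!is.null(chains)) df <- dplyr::filter(df, .data$chain %in% chains)
  if (!is.null(resno_range)) {
    df <- dplyr::filter(df, .data$resno >= resno_range[1],
                        .data$resno <= resno_range[2])
  }
  if (nrow(df) == 0) abort("empty selection")
  structure_model(df)
}
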