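# DensityMap container and MRC/CCP4 2014 I/O.

#' Construct a density map
#'
#' @param grid 3-D numeric array of density values, axis order (x, y, z).
#' @param voxel_size Voxel edge length(s) in Angstrom; scalar or length 3.
#' @param origin Position (A) of the corner of the first voxel, length 3.
#' @return A list of class `density_map` with elements `grid`,
#'   `voxel_size`, `origin`.
#' @export
density_map <- function(grid, voxel_size, origin = c(0, 0, 0)) {
  if (length(dim(grid)) != 3) abort("grid must be a 3-D array")
  if (any(dim(grid) < 2)) abort("grid must have >= 2 voxels per axis")
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(voxel_size <= 0)) abort("voxel_size must be > 0")
  structure(list(grid = grid, voxel_size = voxel_size,
                 origin = as.numeric(rep_len(origin, 3))),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<density_map> %d x %d x %d voxels, %.3g x %.3g x %.3g A/voxel\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3]))
  if (all(x$grid == 0)) cat("  (empty: all values zero)\n")
  invisible(x)
}

#' Is a density map empty (all zero)?
#' @param map A `density_map`.
#' @return Logical scalar.
#' @export
map_is_empty <- function(map) all(map$grid == 0)

#' Read an MRC/CCP4 2014 density map
#'
#' Supports modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16).  The axis
#' order is normalised to (x, y, z) from the `mapc`/`mapr`/`maps` header
#' words; the origin record is honoured, falling back to
#' `nstart * voxel_size` when zero.
#'
#' @param path File path.
#' @return A `density_map`.
#' @export
read_density_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  h_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nxyz <- h_int[1:3]; mode <- h_int[4]; nstart <- h_int[5:7]; mxyz <- h_int[8:10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")  # cellb
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")  # dmin/dmax/dmean
  ispg_nsymbt <- readBin(con, "integer", n = 2, size = 4, endian = "little")
  nsymbt <- max(0L, ispg_nsymbt[2])
  seek(con, 96)
  readBin(con, "integer", n = 25, size = 4, endian = "little")  # extra
  seek(con, 196)
  origin <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  stamp <- rawToChar(readBin(con, "raw", n = 4))
  seek(con, 1024 + nsymbt)
  nvox <- prod(nxyz)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = nvox, size = 2, signed = FALSE,
                             endian = "little")),
    abort(sprintf("unsupported MRC mode %d in %s", mode, path))
  )
  if (length(vals) != nvox) abort(sprintf("truncated map data in %s", path))
  arr <- array(vals, dim = nxyz)  # (columns, rows, sections)
  if (any(!mapcrs %in% 1:3) || anyDuplicated(mapcrs)) mapcrs <- 1:3
  # permute so out[x, y, z]; file axis i holds physical axis mapcrs[i]
  perm <- match(1:3, mapcrs)
  arr <- aperm(arr, perm)
  nstart_xyz <- nstart[perm]
  voxel <- cella / mxyz
  voxel <- voxel[1:3]
  if (any(!is.finite(voxel)) || any(voxel <= 0)) voxel <- rep(1, 3)
  if (all(origin == 0) && any(nstart_xyz != 0)) origin <- nstart_xyz * voxel
  m <- density_map(arr, voxel, origin)
  if (map_is_empty(m)) inform(sprintf("map %s is empty (all zero)", path))
  m
}

#' Write a density map as MRC 2014 (mode 2, float32)
#'
#' @param map A `density_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_map <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(map$grid)
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4,
           endian = "little")
  writeBin(as.numeric(c(d * map$voxel_size, 90, 90, 90)), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(map$grid), max(map$grid), mean(map$grid))), con,
           size = 4, endian = "little")
  writeBin(as.integer(c(1L, 0L)), con, size = 4, endian = "little")  # ispg, nsymbt
  writeBin(raw(100), con)                      # extra (words 26-49)
  writeBin(as.numeric(map$origin), con, size = 4, endian = "little")
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  writeBin(as.numeric(stats::sd(map$grid)), con, size = 4, endian = "little")
  writeBin(as.integer(0L), con, size = 4, endian = "little")  # nlabl
  writeBin(raw(800), con)
  writeBin(as.numeric(map$grid), con, size = 4, endian = "little")
  invisible(path)
}

#' Trilinear interpolation of map density at physical points
#'
#' @param map A `density_map`.
#' @param points n x 3 matrix of coordinates (A).
#' @return Numeric vector of interpolated densities (0 outside the grid).
#' @export
map_interpolate <- function(map, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  d <- dim(map$grid)
  # voxel centres at origin + (i - 0.5) * voxel
  u <- sweep(sweep(points, 2, map$origin), 2, map$voxel_size, "/") + 0.5
  out <- numeric(nrow(points))
  for (p in seq_len(nrow(points))) {
    i0 <- floor(u[p, ])
    fr <- u[p, ] - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ii <- i0 + c(dx, dy, dz)
      if (any(ii < 1) || any(ii > d)) next
      w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
      acc <- acc + w * map$grid[ii[1], ii[2], ii[3]]
    }
    out[p] <- acc
  }
  out
}

# physical centres of all voxels (n x 3) -- internal
.voxel_centres <- function(map, idx = NULL) {
  d <- dim(map$grid)
  if (is.null(idx)) {
    idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  }
  sweep(sweep(idx - 0.5, 2, map$voxel_size, "*"), 2, map$origin, "+")
}
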