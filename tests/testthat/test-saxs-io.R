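test_that("SAXS .dat parsing handles headers, comments and bad rows", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.01 100 1", "0.02 90 1", "0.03 80 1"), f)
  cu <- read_saxs(f)
  expect_s3_class(cu, "saxs_curve")
  expect_equal(cu$q, c(0.01, 0.02, 0.03))
  expect_equal(cu$I, c(100, 90, 80))

  # a header line and a text line give an identical curve
  f2 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# q I err", "Sample: hOGA-like dimer",
               "0.01 100 1", "0.02 90 1", "0.03 80 1"), f2)
  cu2 <- read_saxs(f2)
  expect_equal(cu2$q, cu$q)
  expect_equal(cu2$I, cu$I)

  # rows with non-positive sigma are dropped with a warning
  f3 <- withr::local_tempfile(fileext = ".dat")
  rows <- sprintf("%.3f %.1f 1", seq(0.01, 0.10, 0.01), 100 - seq(10))
  rows[5] <- "0.05 50 -1"
  writeLines(rows, f3)
  expect_warning(cu3 <- read_saxs(f3), "dropped 1")
  expect_equal(nrow(cu3), 9)
  expect_true(all(cu3$sigma > 0))

  # two-column files only behind the explicit flag
  f4 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.01 100", "0.02 90", "0.03 80"), f4)
  expect_error(read_saxs(f4), "columns")
  cu4 <- read_saxs(f4, allow_two_columns = TRUE)
  expect_equal(cu4$sigma, 0.01 * cu4$I)

  # no numeric rows is a format error; nm units convert q
  f5 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# only", "# comments"), f5)
  expect_error(read_saxs(f5), "no numeric rows")
  f6 <- withr::local_tempfile(fileext = ".dat")
  writeLines("0.1 100 1", f6)
  expect_equal(read_saxs(f6, qunit = "nm")$q, 0.01)
})

test_that("curve write/read round-trips preserve values", {
  q <- seq(0.005, 0.3, length.out = 40)
  I <- sphere_intensity(q, 30, 12345.678)
  cu <- saxs_curve(q, I, lab_sigma(q, I))
  f <- withr::local_tempfile(fileext = ".dat")
  write_saxs(cu, f, I_model = I * 1.01)
  rt <- read_saxs(f)
  expect_equal(rt$q, cu$q, tolerance = 1e-6)
  expect_equal(rt$I, cu$I, tolerance = 1e-6)
  expect_equal(rt$sigma, cu$sigma, tolerance = 1e-6)
})

test_that("saxs_curve enforces its invariants", {
  expect_error(saxs_curve(c(0.1, 0.2), c(1, 2, 3)), "equal length")
  expect_error(saxs_curve(c(-0.1, 0.2), c(1, 2)), "finite")
  expect_error(saxs_curve(c(0.1, 0.2), c(1, 2), c(1, 0)), "sigma")
  expect_error(saxs_curve(c(0.1, 0.1), c(1, 2), c(1, 1)), "increasing")
  # unsorted input is sorted
  cu <- saxs_curve(c(0.2, 0.1), c(2, 1), c(1, 1))
  expect_equal(cu$q, c(0.1, 0.2))
  expect_equal(cu$I, c(1, 2))
})

test_that("PDB and mmCIF renderings of one model parse identically", {
  pdb <- read_structure(write_fixture_pdb(withr::local_tempfile(fileext = ".pdb")))
  cif <- read_structure(write_fixture_cif(withr::local_tempfile(fileext = ".cif")))
  # waters dropped, altlocs resolved to highest occupancy
  expect_equal(nrow(pdb), 3)
  expect_equal(nrow(cif), 3)
  expect_false("HOH" %in% pdb$resname)
  expect_equal(pdb$x[pdb$resno == 2], 10.5)  # occ 0.6 conformer wins
  expect_equal(pdb$x, cif$x, tolerance = 1e-3)
  expect_equal(pdb$y, cif$y, tolerance = 1e-3)
  expect_equal(pdb$z, cif$z, tolerance = 1e-3)
  expect_equal(pdb$resname, cif$resname)
})

test_that("structure write/read round-trips and empty models error", {
  md <- make_globule(30, seed = 8)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(md, f)
  rt <- read_structure(f)
  expect_equal(nrow(rt), nrow(md))
  expect_equal(rt$x, md$x, tolerance = 1e-3)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", f2)
  expect_error(read_structure(f2))
})

test_that("MRC maps round-trip and axis order is normalised", {
  set.seed(4)
  m <- density_map(array(abs(rnorm(8^3)), dim = c(8, 8, 8)), 2.5,
                   origin = c(1, 2, 3))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_density_map(m, f)
  m2 <- read_density_map(f)
  expect_equal(m2$grid, m$grid, tolerance = 1e-6)
  expect_equal(m2$voxel_size, m$voxel_size)
  expect_equal(m2$origin, m$origin, tolerance = 1e-5)

  # write the same physical density with swapped axis order (mapc=2, mapr=1)
  fp <- withr::local_tempfile(fileext = ".mrc")
  con <- file(fp, "wb")
  d <- dim(m$grid)
  perm <- aperm(m$grid, c(2, 1, 3))  # file stores y fastest
  writeBin(as.integer(c(dim(perm), 2L, 0L, 0L, 0L, d)), con, size = 4,
           endian = "little")
  writeBin(as.numeric(c(d * m$voxel_size, 90, 90, 90)), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(2L, 1L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(perm), max(perm), mean(perm))), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(1L, 0L)), con, size = 4, endian = "little")
  writeBin(raw(100), con)
  writeBin(as.numeric(m$origin), con, size = 4, endian = "little")
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  writeBin(as.numeric(stats::sd(perm)), con, size = 4, endian = "little")
  writeBin(as.integer(0L), con, size = 4, endian = "little")
  writeBin(raw(800), con)
  writeBin(as.numeric(perm), con, size = 4, endian = "little")
  close(con)
  m3 <- read_density_map(fp)
  expect_equal(dim(m3$grid), dim(m$grid))
  # trilinear samples at random physical points agree between orderings
  set.seed(9)
  pts <- cbind(runif(10, 4, 16), runif(10, 5, 17), runif(10, 6, 18))
  expect_equal(map_interpolate(m3, pts), map_interpolate(m2, pts),
               tolerance = 1e-5)

  # all-zero map is valid and flagged empty
  z <- density_map(array(0, dim = c(4, 4, 4)), 2)
  fz <- withr::local_tempfile(fileext = ".mrc")
  write_density_map(z, fz)
  expect_message(mz <- read_density_map(fz), "empty")
  expect_true(map_is_empty(mz))
})

test_that("write_report serialises fit results and fitted curves re-parse", {
  q <- seq(0.005, 0.2, length.out = 60)
  I <- sphere_intensity(q, 30, 100)
  cu <- saxs_curve(q, I, lab_sigma(q, I))
  g <- guinier_fit(cu)
  f <- withr::local_tempfile(fileext = ".txt")
  write_report(list(guinier = g, extra = list(n = 3)), f)
  txt <- readLines(f)
  expect_true(any(grepl("guinier.Rg", txt)))
  expect_true(any(grepl("guinier.I0", txt)))
  js <- jsonlite::read_json(sub("\\.txt$", ".json", f))
  expect_equal(js$guinier.Rg, g$Rg, tolerance = 1e-6)
  # fitted-curve file round-trips with the same q grid
  fc <- withr::local_tempfile(fileext = ".dat")
  write_saxs(cu, fc, I_model = I)
  expect_equal(read_saxs(fc)$q, cu$q, tolerance = 1e-7)
})
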