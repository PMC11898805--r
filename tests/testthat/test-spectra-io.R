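make_cube <- function(vals, wl, kind = "raw") {
  grid <- tibble::tibble(wavelength = wl, sensor = ifelse(wl < 990, "VNIR", "SWIR"))
  hypercube(array(vals, dim = c(2, 2, length(wl))), grid, kind = kind)
}

test_that("ENVI cubes round-trip in every interleave", {
  set.seed(1)
  wl <- c(500, 1000, 1500, 2000)
  cube <- make_cube(runif(16), wl, kind = "reflectance")
  for (il in c("bil", "bip", "bsq")) {
    path <- file.path(withr::local_tempdir(), paste0("cube_", il))
    write_envi_cube(cube, path, interleave = il)
    back <- read_envi_cube(paste0(path, ".hdr"), kind = "reflectance")
    expect_equal(back$values, cube$values, ignore_attr = TRUE)
    expect_equal(back$grid$wavelength, wl)
  }
})

test_that("a hand-built BIL file is parsed with correct layout and tags", {
  # 2 rows x 2 cols x 3 bands; BIL layout: line, then band, then sample.
  # value = row*100 + col*10 + band
  dir <- withr::local_tempdir()
  bin <- file.path(dir, "fix")
  vals <- c(
    # line 1: band1 (cols 1,2), band2, band3
    111, 121, 112, 122, 113, 123,
    # line 2
    211, 221, 212, 222, 213, 223
  )
  con <- file(bin, "wb")
  writeBin(as.double(vals), con, size = 8, endian = "little")
  close(con)
  writeLines(c(
    "ENVI", "samples = 2", "lines = 2", "bands = 3", "data type = 5",
    "interleave = bil", "byte order = 0",
    "wavelength = {500, 1000, 1500}"
  ), paste0(bin, ".hdr"))
  cube <- read_envi_cube(paste0(bin, ".hdr"))
  expect_equal(cube$values[1, 2, 3], 123)
  expect_equal(cube$values[2, 1, 2], 212)
  expect_equal(cube$grid$sensor, c("VNIR", "SWIR", "SWIR"))
})

test_that("missing or inconsistent header fields are named in errors", {
  dir <- withr::local_tempdir()
  bin <- file.path(dir, "bad")
  con <- file(bin, "wb")
  writeBin(as.double(1:8), con, size = 8)
  close(con)
  writeLines(c("ENVI", "samples = 2", "lines = 2", "bands = 2",
               "data type = 5", "interleave = bil"), paste0(bin, ".hdr"))
  expect_error(read_envi_cube(paste0(bin, ".hdr")), "wavelength")
  writeLines(c("ENVI", "samples = 2", "lines = 2", "bands = 2",
               "data type = 5", "interleave = bil",
               "wavelength = {500, 600, 700}"), paste0(bin, ".hdr"))
  expect_error(read_envi_cube(paste0(bin, ".hdr")), "3 values")
})

test_that("plate correction satisfies its algebraic identities", {
  wl <- c(500, 1500)
  white <- make_cube(rep(110, 8), wl, "white")
  black <- make_cube(rep(10, 8), wl, "black")
  raw_mid <- make_cube(rep(60, 8), wl, "raw")
  refl <- calibrate_reflectance(raw_mid, white, black)
  expect_equal(as.vector(refl$values), rep(0.5, 8))
  expect_equal(
    as.vector(calibrate_reflectance(make_cube(rep(110, 8), wl, "raw"), white, black)$values),
    rep(1, 8)
  )
  expect_equal(
    as.vector(calibrate_reflectance(make_cube(rep(10, 8), wl, "raw"), white, black)$values),
    rep(0, 8)
  )
})

test_that("coincident white and black frames are a hard error naming bands", {
  wl <- c(500, 1500)
  white <- make_cube(c(rep(1, 4), rep(0, 4)), wl, "white")
  black <- make_cube(rep(0, 8), wl, "black")
  raw <- make_cube(rep(0.5, 8), wl, "raw")
  expect_error(calibrate_reflectance(raw, white, black), "band\\(s\\): 2")
})

test_that("calibration is invariant to a common affine transform", {
  set.seed(42)
  wl <- seq(500, 2400, length.out = 5)
  for (rep_i in 1:20) {
    refl_true <- array(runif(2 * 2 * 5), dim = c(2, 2, 5))
    gain <- runif(1, 10, 1000)
    offset <- runif(1, -50, 50)
    raw <- make_cube(offset + gain * refl_true, wl, "raw")
    white <- make_cube(array(offset + gain, dim = c(2, 2, 5)), wl, "white")
    black <- make_cube(array(offset, dim = c(2, 2, 5)), wl, "black")
    base <- calibrate_reflectance(raw, white, black)$values
    a <- runif(1, 0.5, 3); b <- runif(1, -10, 10)
    tr <- function(cube, kind) make_cube(a * cube$values + b, wl, kind)
    again <- calibrate_reflectance(tr(raw, "raw"), tr(white, "white"),
                                   tr(black, "black"))$values
    expect_equal(again, base, tolerance = 1e-12)
    expect_equal(base, refl_true, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("ROI means are exact, permutation-invariant and linear", {
  wl <- c(500, 1500, 2000)
  vals <- array(0.3, dim = c(2, 2, 3))
  cube <- make_cube(vals, wl, "reflectance")
  mask <- matrix(TRUE, 2, 2)
  expect_equal(extract_roi_mean(cube, mask)$reflectance, rep(0.3, 3))

  one <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  vals[1, 1, ] <- c(0.1, 0.2, 0.9)
  cube <- make_cube(vals, wl, "reflectance")
  expect_equal(extract_roi_mean(cube, one)$reflectance, c(0.1, 0.2, 0.9))

  two <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  vals[2, 1, ] <- c(0.3, 0.4, 0.1)
  cube <- make_cube(vals, wl, "reflectance")
  expect_equal(extract_roi_mean(cube, two)$reflectance, c(0.2, 0.3, 0.5))

  # linearity: mean(a*X + b) = a*mean(X) + b
  lin <- make_cube(0.9 * vals + 0.05, wl, "reflectance")
  expect_equal(extract_roi_mean(lin, two)$reflectance,
               0.9 * extract_roi_mean(cube, two)$reflectance + 0.05)
  expect_error(extract_roi_mean(cube, matrix(FALSE, 2, 2)), "no pixels")
})

test_that("band fusion assigns the seam to the configured sensor", {
  vnir <- tibble::tibble(wavelength = seq(410, 990, by = 58),
                         reflectance = runif(11))
  swir <- tibble::tibble(wavelength = seq(990, 2500, by = 151),
                         reflectance = runif(11))
  fused <- merge_sensor_bands(vnir, swir, boundary_nm = 990)
  expect_true(all(diff(fused$wavelength) > 0))
  expect_equal(nrow(fused), sum(vnir$wavelength < 990) + sum(swir$wavelength >= 990))
  seam <- fused[fused$wavelength == 990, ]
  expect_equal(seam$sensor, "SWIR")
  expect_equal(seam$reflectance, swir$reflectance[1])

  fused_v <- merge_sensor_bands(vnir, swir, boundary_nm = 990, prefer = "vnir")
  expect_equal(fused_v[fused_v$wavelength == 990, ]$sensor, "VNIR")

  disjoint <- merge_sensor_bands(
    tibble::tibble(wavelength = c(400, 500), reflectance = c(0.1, 0.2)),
    tibble::tibble(wavelength = c(1500, 1600), reflectance = c(0.3, 0.4))
  )
  expect_equal(nrow(disjoint), 4)
})

test_that("fusing the fixture sensor grids reproduces the 396-band working grid", {
  # fixture grids sized so that |VNIR < 990| + |SWIR >= 990| = 396
  vnir <- tibble::tibble(wavelength = seq(410, 989.9, length.out = 110),
                         reflectance = runif(110))
  swir <- tibble::tibble(wavelength = seq(990, 2500, length.out = 286),
                         reflectance = runif(286))
  fused <- merge_sensor_bands(vnir, swir, 990)
  expect_equal(nrow(fused), 396)
  expect_equal(range(fused$wavelength), c(410, 2500))
})

test_that("band fusion rejects non-monotone input grids", {
  bad <- tibble::tibble(wavelength = c(500, 450), reflectance = c(0.1, 0.2))
  swir <- tibble::tibble(wavelength = c(990, 1100), reflectance = c(0.3, 0.4))
  expect_error(merge_sensor_bands(bad, swir, 990), "increasing")
  expect_error(merge_sensor_bands(swir[, "wavelength"], swir, 990), "reflectance")
})
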