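# Hyperspectral cube container + ENVI I/O + reflectance calibration.

#' Hyperspectral cube
#'
#' A thin S3 wrapper around a 3-D numeric array (rows x cols x bands) with
#' its wavelength grid and a `kind` marker distinguishing raw counts from
#' the white/black reference frames and calibrated reflectance.
#'
#' @param values 3-D numeric array, band axis last.
#' @param grid Wavelength grid tibble, one row per band.
#' @param kind One of `"raw"`, `"white"`, `"black"`, `"reflectance"`.
#' @return A `hypercube` object.
#' @export
hypercube <- function(values, grid, kind = c("raw", "white", "black", "reflectance")) {
  kind <- match.arg(kind)
  check_grid(grid)
  if (length(dim(values)) != 3L) abort("`values` must be a 3-D array (rows x cols x bands).")
  if (dim(values)[3] != nrow(grid)) {
    abort("Band dimension of `values` must equal the grid length.")
  }
  if (kind == "reflectance") {
    rng <- range(values)
    if (rng[1] < -0.1 || rng[2] > 1.5) {
      warn(sprintf(
        "Reflectance values outside [-0.1, 1.5] (range %.3f..%.3f); check calibration frames.",
        rng[1], rng[2]
      ))
    }
  }
  structure(list(values = values, grid = grid, kind = kind), class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<hypercube %s: %d x %d pixels, %d bands (%.1f-%.1f nm)>\n",
    x$kind, d[1], d[2], d[3], min(x$grid$wavelength), max(x$grid$wavelength)
  ))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$values)

# ---- ENVI format ------------------------------------------------------------

# data type codes used by the ENVI header convention
.envi_types <- list(`4` = list(what = "double", size = 4L),
                    `5` = list(what = "double", size = 8L))

#' Read an ENVI cube
#'
#' Parses the text header (`.hdr`) for dimensions, interleave, byte order and
#' the wavelength list, then reads the companion binary. BIL, BIP and BSQ
#' interleaves and 32/64-bit float data types are supported.
#'
#' @param header_path Path to the `.hdr` file; the binary is the same path
#'   without the extension (or with `.dat` / `.img`).
#' @param kind Cube kind to stamp on the result (default `"raw"`).
#' @param boundary_nm Sensor seam used to tag bands (default 990).
#' @return A [hypercube()].
#' @export
read_envi_cube <- function(header_path, kind = "raw", boundary_nm = 990) {
  if (!file.exists(header_path)) abort(paste0("Header not found: ", header_path))
  hdr <- parse_envi_header(header_path)
  for (field in c("samples", "lines", "bands", "interleave", "data type")) {
    if (is.null(hdr[[field]])) abort(paste0("ENVI header missing required field `", field, "`."))
  }
  if (is.null(hdr$wavelength)) abort("ENVI header missing required field `wavelength`.")
  nb <- as.integer(hdr$bands)
  wl <- as.numeric(hdr$wavelength)
  if (length(wl) != nb) {
    abort(sprintf("`wavelength` lists %d values but `bands` = %d.", length(wl), nb))
  }
  interleave <- tolower(hdr$interleave)
  if (!interleave %in% c("bil", "bip", "bsq")) {
    abort(paste0("Unsupported interleave `", interleave, "`."))
  }
  tp <- .envi_types[[as.character(hdr[["data type"]])]]
  if (is.null(tp)) abort(paste0("Unsupported ENVI data type ", hdr[["data type"]], "."))
  endian <- if (!is.null(hdr[["byte order"]]) && as.integer(hdr[["byte order"]]) == 1L) {
    "big"
  } else "little"

  bin_path <- envi_binary_path(header_path)
  nr <- as.integer(hdr$lines)
  nc <- as.integer(hdr$samples)
  n <- nr * nc * nb
  con <- file(bin_path, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, what = tp$what, n = n, size = tp$size, endian = endian)
  if (length(vals) != n) abort("ENVI binary shorter than header dimensions imply.")

  # file layouts: BSQ = [col, row, band], BIL = [col, band, row],
  # BIP = [band, col, row] (fastest-varying first)
  arr <- switch(interleave,
    bsq = aperm(array(vals, dim = c(nc, nr, nb)), c(2, 1, 3)),
    bil = aperm(array(vals, dim = c(nc, nb, nr)), c(3, 1, 2)),
    bip = aperm(array(vals, dim = c(nb, nc, nr)), c(3, 2, 1))
  )
  grid <- tibble(wavelength = wl, sensor = ifelse(wl < boundary_nm, "VNIR", "SWIR"))
  hypercube(arr, grid, kind = kind)
}

#' Write an ENVI cube
#'
#' @param cube A [hypercube()].
#' @param path Binary output path; the header is written to `paste0(path, ".hdr")`.
#' @param interleave `"bil"`, `"bip"` or `"bsq"`.
#' @param data_type 4 (float32) or 5 (float64).
#' @return `path`, invisibly.
#' @export
write_envi_cube <- function(cube, path, interleave = c("bil", "bip", "bsq"),
                            data_type = 5) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  tp <- .envi_types[[as.character(data_type)]]
  if (is.null(tp)) abort("`data_type` must be 4 (float32) or 5 (float64).")
  d <- dim(cube$values)
  arr <- switch(interleave,
    bsq = aperm(cube$values, c(2, 1, 3)),
    bil = aperm(cube$values, c(2, 3, 1)),
    bip = aperm(cube$values, c(3, 2, 1))
  )
  hdr <- c(
    "ENVI",
    "description = {hsiq export}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("wavelength = {", paste(sprintf("%.10g", cube$grid$wavelength), collapse = ", "), "}")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(arr), con, size = tp$size, endian = "little")
  invisible(path)
}

envi_binary_path <- function(header_path) {
  base <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  for (cand in c(base, paste0(base, ".dat"), paste0(base, ".img"))) {
    if (file.exists(cand) && !identical(cand, header_path)) return(cand)
  }
  abort(paste0("No ENVI binary found next to ", header_path))
}

parse_envi_header <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  text <- paste(lines, collapse = "\n")
  out <- list()
  # brace-delimited multi-value fields
  braced <- gregexpr("([a-zA-Z ]+?)\\s*=\\s*\\{[^}]*\\}", text)[[1]]
  if (braced[1] != -1) {
    for (i in seq_along(braced)) {
      piece <- substr(text, braced[i], braced[i] + attr(braced, "match.length")[i] - 1)
      key <- trimws(sub("=.*$", "", piece))
      val <- sub("^[^{]*\\{", "", piece)
      val <- sub("\\}\\s*$", "", val)
      items <- trimws(strsplit(gsub("\n", " ", val), ",")[[1]])
      out[[tolower(key)]] <- items[nzchar(items)]
    }
    text <- gsub("([a-zA-Z ]+?)\\s*=\\s*\\{[^}]*\\}", "", text)
  }
  for (ln in strsplit(text, "\n")[[1]]) {
    if (!grepl("=", ln)) next
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (nzchar(key) && nzchar(val)) out[[key]] <- val
  }
  out
}

# ---- calibration and extraction ---------------------------------------------

#' Black/white reference reflectance calibration
#'
#' Converts raw counts to reflectance with the standard plate correction
#' `R = (raw - black) / (white - black)`, applied per pixel and band. A band
#' where the white and black frames coincide anywhere is a hard error: the
#' quotient is undefined and silent NaNs would poison wavelength selection
#' downstream.
#'
#' @param raw,white,black [hypercube()]s sharing grid and spatial shape, of
#'   kinds `"raw"`, `"white"`, `"black"`.
#' @return A reflectance [hypercube()].
#' @examples
#' cfg <- synthetic_config(n_samples = 2, noise_sd = 0)
#' s <- simulate_sample(cfg, "fumigated")
#' fr <- simulate_raw_frames(spectra_matrix(s)[1, ], cfg$grid)
#' refl <- calibrate_reflectance(fr$raw, fr$white, fr$black)
#' @export
calibrate_reflectance <- function(raw, white, black) {
  for (cube in list(raw, white, black)) stopifnot(inherits(cube, "hypercube"))
  if (!identical(dim(raw$values), dim(white$values)) ||
      !identical(dim(raw$values), dim(black$values))) {
    abort("The three cubes must share spatial and band dimensions.")
  }
  if (!isTRUE(all.equal(raw$grid$wavelength, white$grid$wavelength)) ||
      !isTRUE(all.equal(raw$grid$wavelength, black$grid$wavelength))) {
    abort("The three cubes must share one wavelength grid.")
  }
  denom <- white$values - black$values
  if (any(denom == 0)) {
    bad <- which(apply(denom == 0, 3, any))
    abort(paste0(
      "White and black frames coincide (zero denominator) in band(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  refl <- (raw$values - black$values) / denom
  hypercube(refl, raw$grid, kind = "reflectance")
}

#' Mean spectrum over a region of interest
#'
#' @param cube Reflectance [hypercube()].
#' @param mask Logical matrix matching the cube's spatial dimensions, at
#'   least one `TRUE` pixel.
#' @return Tibble with `wavelength`, `sensor` and `reflectance` (the
#'   per-band arithmetic mean over masked pixels).
#' @export
extract_roi_mean <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$kind != "reflectance") abort("`cube` must be a reflectance cube.")
  d <- dim(cube$values)
  if (!is.logical(mask) || !identical(dim(mask), d[1:2])) {
    abort("`mask` must be a logical matrix matching the cube's spatial shape.")
  }
  if (!any(mask)) abort("`mask` selects no pixels.")
  flat <- matrix(cube$values, nrow = d[1] * d[2], ncol = d[3])
  mean_spec <- colMeans(flat[as.vector(mask), , drop = FALSE])
  dplyr::mutate(cube$grid, reflectance = mean_spec)
}

#' Fuse VNIR and SWIR spectra onto one working grid
#'
#' Concatenates the VNIR bands strictly below the seam with the SWIR bands at
#' or above it (the SWIR sensor is native at the seam; set
#' `prefer = "vnir"` for the opposite convention). No interpolation is
#' performed: the working grid is the union grid.
#'
#' @param vnir,swir Tibbles with `wavelength` and `reflectance` columns.
#' @param boundary_nm Seam wavelength (default 990).
#' @param prefer Which sensor owns the seam band, `"swir"` (default) or `"vnir"`.
#' @return Tibble `wavelength`, `sensor`, `reflectance`, strictly increasing.
#' @export
merge_sensor_bands <- function(vnir, swir, boundary_nm = 990,
                               prefer = c("swir", "vnir")) {
  prefer <- match.arg(prefer)
  for (df in list(vnir, swir)) {
    if (!all(c("wavelength", "reflectance") %in% names(df))) {
      abort("Inputs need `wavelength` and `reflectance` columns.")
    }
    if (any(diff(df$wavelength) <= 0)) abort("Input grids must be strictly increasing.")
  }
  if (prefer == "swir") {
    keep_v <- vnir$wavelength < boundary_nm
    keep_s <- swir$wavelength >= boundary_nm
  } else {
    keep_v <- vnir$wavelength <= boundary_nm
    keep_s <- swir$wavelength > boundary_nm
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(vnir[keep_v, c("wavelength", "reflectance")], sensor = "VNIR"),
    dplyr::mutate(swir[keep_s, c("wavelength", "reflectance")], sensor = "SWIR")
  )
  if (any(diff(out$wavelength) <= 0)) {
    abort("Fused grid is not strictly increasing; check the input ranges.")
  }
  out[, c("wavelength", "sensor", "reflectance")]
}
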