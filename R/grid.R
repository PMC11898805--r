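#' Build a working wavelength grid
#'
#' Constructs the band-center grid the whole pipeline operates on: a strictly
#' increasing sequence of wavelengths (nm) spanning the fused VNIR + SWIR
#' range, with each band tagged by the sensor it originates from. The default
#' reproduces the 396-band working grid obtained by fusing a 410--990 nm
#' visible/near-infrared sensor with a 990--2500 nm short-wave-infrared
#' sensor.
#'
#' @param n_bands Number of band centers (>= 2).
#' @param range_nm Length-2 numeric, grid limits in nm (within 350--2550).
#' @param boundary_nm Sensor seam: bands strictly below are tagged `"VNIR"`,
#'   bands at or above are tagged `"SWIR"`. Default 990 nm.
#'
#' @return A tibble with columns `wavelength` (nm, strictly increasing) and
#'   `sensor` (`"VNIR"` or `"SWIR"`).
#'
#' @examples
#' grid <- make_wavelength_grid()
#' nrow(grid)          # 396
#' range(grid$wavelength)
#' @export
make_wavelength_grid <- function(n_bands = 396, range_nm = c(410, 2500),
                                 boundary_nm = 990) {
  if (length(n_bands) != 1L || is.na(n_bands) || n_bands < 2) {
    abort("`n_bands` must be a single count >= 2.")
  }
  if (length(range_nm) != 2L || any(is.na(range_nm)) || range_nm[1] >= range_nm[2]) {
    abort("`range_nm` must be an increasing interval c(low, high).")
  }
  if (range_nm[1] < 350 || range_nm[2] > 2550) {
    abort("`range_nm` must lie within [350, 2550] nm.")
  }
  centers <- seq(range_nm[1], range_nm[2], length.out = as.integer(n_bands))
  tibble(
    wavelength = centers,
    sensor = ifelse(centers < boundary_nm, "VNIR", "SWIR")
  )
}

# Validate a grid-shaped tibble; used by cube and dataset constructors.
check_grid <- function(grid) {
  if (!is.data.frame(grid) || !all(c("wavelength", "sensor") %in% names(grid))) {
    abort("A wavelength grid needs `wavelength` and `sensor` columns.")
  }
  w <- grid$wavelength
  if (any(diff(w) <= 0)) abort("Grid wavelengths must be strictly increasing.")
  invisible(grid)
}
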