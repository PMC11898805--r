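# Synthetic two-class reflectance spectra with latent analyte contents.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: a smooth baseline reflectance (three broad Gaussian humps), one
# dedicated absorption feature per analyte whose depth is linear in that
# analyte's content, a compact fumigation depression in the 1200--1400 nm
# region gated by the class label, and i.i.d. additive Gaussian noise.
# Constants below are documented package choices, not instrument estimates.

# baseline humps: amplitude, center (nm), sd (nm)
.baseline_humps <- matrix(
  c(0.42,  700, 180,
    0.30, 1320, 260,
    0.22, 2020, 300),
  ncol = 3, byrow = TRUE
)
.baseline_offset <- 0.18

# analyte absorption features: Gaussian dips for polysaccharide and phenol
# (SWIR), raised-cosine bump co-located with the fumigation signature for SO2
.analyte_features <- list(
  polysaccharide = list(center = 1580, sd = 30, coeff = 0.0015), # per mg/g
  phenol         = list(center = 2060, sd = 30, coeff = 0.0060), # per mg/g
  so2            = list(coeff = 2e-4)                            # per ug/g
)

#' Configuration for the synthetic spectrum generator
#'
#' Bundles and validates every knob of the generator. Defaults emulate the
#' study design the pipeline targets: 500 samples, half sulfur-fumigated,
#' a fumigation signature confined to 1200--1400 nm, and the 396-band
#' 410--2500 nm working grid.
#'
#' @param n_samples Number of samples (>= 2).
#' @param fumigated_fraction Proportion of fumigated samples in \[0, 1\].
#' @param signature_band Length-2 nm interval carrying the fumigation
#'   depression (subset of \[410, 2500\]).
#' @param signature_depth Peak reflectance depression (dimensionless) a
#'   fumigated sample at the top of the SO2 range receives.
#' @param content_ranges Named list of `c(min, max)` draws for
#'   `polysaccharide` (mg/g), `phenol` (mg/g) and `so2` (ug/g, fumigated
#'   samples only).
#' @param so2_floor SO2 content assigned to every sun-dried sample (ug/g).
#' @param noise_sd Additive reflectance noise standard deviation (>= 0).
#' @param seed Integer seed; every sample derives its own substream from it.
#' @param grid Wavelength grid tibble, see [make_wavelength_grid()].
#'
#' @return A list of class `"synthetic_config"`.
#' @examples
#' cfg <- synthetic_config(n_samples = 20, seed = 7)
#' @export
synthetic_config <- function(n_samples = 500,
                             fumigated_fraction = 0.5,
                             signature_band = c(1200, 1400),
                             signature_depth = 0.1,
                             content_ranges = list(
                               polysaccharide = c(20, 80),
                               phenol = c(2, 20),
                               so2 = c(100, 500)
                             ),
                             so2_floor = 0,
                             noise_sd = 0.01,
                             seed = 1,
                             grid = make_wavelength_grid()) {
  if (n_samples < 2) abort("`n_samples` must be >= 2.")
  if (fumigated_fraction < 0 || fumigated_fraction > 1) {
    abort("`fumigated_fraction` must lie in [0, 1].")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (length(signature_band) != 2L || signature_band[1] >= signature_band[2] ||
      signature_band[1] < 410 || signature_band[2] > 2500) {
    abort("`signature_band` must be an increasing interval inside [410, 2500] nm.")
  }
  for (nm in c("polysaccharide", "phenol", "so2")) {
    rng <- content_ranges[[nm]]
    if (is.null(rng) || length(rng) != 2L || rng[1] >= rng[2] || rng[1] < 0) {
      abort(paste0("`content_ranges$", nm, "` must be a non-degenerate non-negative range."))
    }
  }
  check_grid(grid)
  structure(
    list(
      n_samples = as.integer(n_samples),
      fumigated_fraction = fumigated_fraction,
      signature_band = signature_band,
      signature_depth = signature_depth,
      content_ranges = content_ranges,
      so2_floor = so2_floor,
      noise_sd = noise_sd,
      seed = as.integer(seed),
      grid = grid
    ),
    class = "synthetic_config"
  )
}

# raised-cosine bump with compact support [a, b]: 0 at the edges, 1 at the
# midpoint, exactly zero outside -- keeps the class difference confined to
# the signature band.
cosine_bump <- function(wavelength, band) {
  inside <- wavelength >= band[1] & wavelength <= band[2]
  out <- numeric(length(wavelength))
  out[inside] <- 0.5 * (1 - cos(2 * pi * (wavelength[inside] - band[1]) /
                                  (band[2] - band[1])))
  out
}

# Noiseless reflectance for given contents and class; vector over the grid.
synthetic_reflectance <- function(config, contents, fumigated) {
  w <- config$grid$wavelength
  refl <- rep(.baseline_offset, length(w))
  for (i in seq_len(nrow(.baseline_humps))) {
    h <- .baseline_humps[i, ]
    refl <- refl + h[1] * exp(-((w - h[2])^2) / (2 * h[3]^2))
  }
  for (nm in c("polysaccharide", "phenol")) {
    f <- .analyte_features[[nm]]
    refl <- refl - f$coeff * contents[[nm]] *
      exp(-((w - f$center)^2) / (2 * f$sd^2))
  }
  bump <- cosine_bump(w, config$signature_band)
  refl <- refl - .analyte_features$so2$coeff * contents[["so2"]] * bump
  if (fumigated) {
    so2_top <- max(config$content_ranges$so2)
    refl <- refl - config$signature_depth * (contents[["so2"]] / so2_top) * bump
  }
  refl
}

draw_contents <- function(config, fumigated) {
  cr <- config$content_ranges
  list(
    polysaccharide = runif(1, cr$polysaccharide[1], cr$polysaccharide[2]),
    phenol = runif(1, cr$phenol[1], cr$phenol[2]),
    so2 = if (fumigated) runif(1, cr$so2[1], cr$so2[2]) else config$so2_floor
  )
}

#' Simulate a single sample spectrum
#'
#' Draws (or accepts) analyte contents, builds the noiseless reflectance,
#' applies the class-gated fumigation depression, adds noise and clips to
#' \[0, 1.05\]. Each `sample_index` owns a deterministic RNG substream of the
#' config seed, so regenerating a dataset with more samples never reshuffles
#' earlier ones.
#'
#' @param config A [synthetic_config()].
#' @param label `"sun_dried"` or `"fumigated"`.
#' @param sample_index Counter selecting the RNG substream (default 1).
#' @param contents Optional named list (`polysaccharide`, `phenol`, `so2`)
#'   overriding the random draw; useful for matched-pair comparisons.
#'
#' @return One-row tibble: `sample_id`, `label`, the three contents, then one
#'   reflectance column per band named by its wavelength in nm.
#' @examples
#' cfg <- synthetic_config(n_samples = 2, noise_sd = 0, seed = 3)
#' s <- simulate_sample(cfg, "fumigated", sample_index = 1)
#' @export
simulate_sample <- function(config, label = c("sun_dried", "fumigated"),
                            sample_index = 1L, contents = NULL) {
  label <- match.arg(label)
  stopifnot(inherits(config, "synthetic_config"))
  fumigated <- label == "fumigated"
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, sample_index))
  if (is.null(contents)) contents <- draw_contents(config, fumigated)
  refl <- synthetic_reflectance(config, contents, fumigated)
  if (config$noise_sd > 0) refl <- refl + rnorm(length(refl), 0, config$noise_sd)
  refl <- pmin(pmax(refl, 0), 1.05)
  spec <- as_tibble(setNames(as.list(refl), band_names(config$grid)))
  dplyr::bind_cols(
    tibble(
      sample_id = sprintf("S%04d", sample_index),
      label = label,
      polysaccharide = contents$polysaccharide,
      phenol = contents$phenol,
      so2 = contents$so2
    ),
    spec
  )
}

#' Simulate a full labelled dataset
#'
#' Generates `n_samples` spectra with the configured fumigated fraction
#' (`round(n * fraction)` fumigated samples first, then sun-dried), contents
#' drawn uniformly over the configured ranges, deterministic under the seed.
#'
#' @param config A [synthetic_config()].
#' @return A tibble, one row per sample, in the same layout as
#'   [simulate_sample()], with the grid attached as attribute `"grid"` and
#'   the config as attribute `"provenance"`.
#' @examples
#' data <- simulate_dataset(synthetic_config(n_samples = 10, seed = 2))
#' table(data$label)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples
  n_fum <- round(n * config$fumigated_fraction)
  labels <- c(rep("fumigated", n_fum), rep("sun_dried", n - n_fum))
  rows <- purrr::map(seq_len(n), function(i) {
    simulate_sample(config, labels[i], sample_index = i)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "grid") <- config$grid
  attr(out, "provenance") <- config
  out
}

#' Simulate raw / white / black frames for one sample
#'
#' Builds the three reference frames the black/white-plate calibration
#' consumes, by replicating the sample's reflectance over a small spatial
#' patch: `black = offset`, `white = offset + gain`, and
#' `raw = offset + gain * reflectance` per band, so that calibration is the
#' exact algebraic inverse.
#'
#' @param spectrum Numeric reflectance vector (one per band).
#' @param grid Wavelength grid matching `spectrum`.
#' @param gain Positive detector gain (counts per unit reflectance).
#' @param offset Dark-current offset (counts).
#' @param patch Spatial dimensions `c(rows, cols)` of the simulated patch.
#'
#' @return A list with hypercubes `raw`, `white`, `black` and a logical
#'   `mask` marking the patch.
#' @examples
#' cfg <- synthetic_config(n_samples = 2, noise_sd = 0)
#' s <- simulate_sample(cfg, "sun_dried")
#' frames <- simulate_raw_frames(spectra_matrix(s)[1, ], cfg$grid)
#' @export
simulate_raw_frames <- function(spectrum, grid, gain = 1000, offset = 80,
                                patch = c(4L, 4L)) {
  if (gain <= 0) abort("`gain` must be positive.")
  check_grid(grid)
  if (length(spectrum) != nrow(grid)) {
    abort("`spectrum` length must equal the number of grid bands.")
  }
  nb <- nrow(grid)
  shape <- c(patch[1], patch[2], nb)
  raw <- array(rep(offset + gain * spectrum, each = prod(patch)), dim = shape)
  white <- array(offset + gain, dim = shape)
  black <- array(offset, dim = shape)
  mask <- matrix(TRUE, patch[1], patch[2])
  list(
    raw = hypercube(raw, grid, kind = "raw"),
    white = hypercube(white, grid, kind = "white"),
    black = hypercube(black, grid, kind = "black"),
    mask = mask
  )
}

# ---- dataset helpers --------------------------------------------------------

band_names <- function(grid) sprintf("%.4f", grid$wavelength)

is_band_name <- function(x) grepl("^[0-9]+(\\.[0-9]+)?$", x)

#' Extract the spectral matrix from a dataset tibble
#'
#' @param data Dataset tibble whose band columns are named by wavelength.
#' @return Numeric matrix, samples x bands, columns ordered by wavelength.
#' @export
spectra_matrix <- function(data) {
  bands <- names(data)[is_band_name(names(data))]
  if (!length(bands)) abort("No wavelength-named columns found.")
  bands <- bands[order(as.numeric(bands))]
  m <- as.matrix(data[bands])
  rownames(m) <- if ("sample_id" %in% names(data)) data$sample_id else NULL
  storage.mode(m) <- "double"
  m
}

#' Recover the wavelength grid of a dataset tibble
#'
#' Uses the `"grid"` attribute when present; otherwise parses the band
#' column names and re-tags sensors by the boundary.
#'
#' @param data Dataset tibble.
#' @param boundary_nm Sensor seam used when re-deriving tags (default 990).
#' @return Grid tibble (`wavelength`, `sensor`).
#' @export
dataset_grid <- function(data, boundary_nm = 990) {
  g <- attr(data, "grid", exact = TRUE)
  if (!is.null(g)) return(g)
  w <- sort(as.numeric(names(data)[is_band_name(names(data))]))
  tibble(wavelength = w, sensor = ifelse(w < boundary_nm, "VNIR", "SWIR"))
}

#' Write / read a dataset as CSV (plus a YAML provenance sidecar)
#'
#' The CSV layout is one row per sample: `sample_id`, `label`, the three
#' contents, then one reflectance column per band headed by wavelength (nm).
#'
#' @param data Dataset tibble.
#' @param path CSV path; a `.yaml` sidecar with the generator config is
#'   written alongside when the dataset carries provenance.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(data, path) {
  readr::write_csv(data, path)
  prov <- attr(data, "provenance", exact = TRUE)
  if (inherits(prov, "synthetic_config")) {
    cfg <- prov[setdiff(names(prov), "grid")]
    cfg$grid_n_bands <- nrow(prov$grid)
    cfg$grid_range_nm <- range(prov$grid$wavelength)
    yaml::write_yaml(cfg, paste0(tools::file_path_sans_ext(path), ".yaml"))
  }
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  attr(out, "grid") <- dataset_grid(out)
  out
}

# Save/restore the global RNG state so seeded generators do not perturb the
# caller's stream.
.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
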