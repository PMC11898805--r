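# Reference-chemistry arithmetic: standard curves and the three content
# formulas that produce the ground-truth analyte values the spectra are
# regressed against.

#' Fit an absorbance-to-concentration standard curve
#'
#' Ordinary least-squares line mapping measured absorbance directly to
#' concentration (mg/mL). Fitting in this direction matches how the kit
#' readout enters the content formulas and avoids dividing by the slope at
#' read time.
#'
#' @param concentrations Standard concentrations (mg/mL), >= 2 distinct values.
#' @param absorbances Matching absorbance readings.
#' @return A one-row tibble of class `"standard_curve"`: `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @examples
#' curve <- fit_standard_curve(c(1, 0.5, 0.25, 0.125, 0.0625),
#'                             c(0.50, 0.25, 0.125, 0.0625, 0.03125))
#' read_concentration(curve, 0.4)
#' @export
fit_standard_curve <- function(concentrations, absorbances) {
  if (length(concentrations) != length(absorbances)) {
    abort("`concentrations` and `absorbances` must have equal length.")
  }
  if (length(concentrations) < 2 || length(unique(concentrations)) < 2) {
    abort("Need at least two distinct standard concentrations.")
  }
  fit <- lm(concentrations ~ absorbances)
  r2 <- if (sd(concentrations) == 0) NA_real_ else summary(fit)$r.squared
  out <- tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    n = length(concentrations)
  )
  class(out) <- c("standard_curve", class(out))
  out
}

#' @rdname fit_standard_curve
#' @param curve A `"standard_curve"`.
#' @param absorbance Absorbance reading(s) to convert.
#' @export
read_concentration <- function(curve, absorbance) {
  stopifnot(inherits(curve, "standard_curve"))
  curve$intercept + curve$slope * absorbance
}

#' Total polysaccharide content
#'
#' `M1 = 5 * Y / W` where `Y` is the assay concentration (mg/mL) read off the
#' standard curve and `W` the sample mass (g); the factor 5 carries the kit's
#' extraction volume.
#'
#' @param Y Assay concentration, mg/mL (>= 0).
#' @param W Sample mass, g (> 0; the kit protocol uses 0.05 g).
#' @return Content in mg/g.
#' @examples
#' polysaccharide_content(0.5, 0.05)  # 50 mg/g
#' @export
polysaccharide_content <- function(Y, W = 0.05) {
  if (any(W <= 0)) abort("Sample mass `W` must be positive.")
  if (any(Y < 0)) abort("Concentration `Y` must be non-negative.")
  5 * Y / W
}

#' Total phenol content
#'
#' `M2 = 2.5 * X / W` with `X` the assay concentration (mg/mL) and `W` the
#' sample mass (g; the kit protocol uses 0.1 g).
#'
#' @param X Assay concentration, mg/mL (>= 0).
#' @param W Sample mass, g (> 0).
#' @return Content in mg/g.
#' @examples
#' total_phenol_content(0.04, 0.1)  # 1 mg/g
#' @export
total_phenol_content <- function(X, W = 0.1) {
  if (any(W <= 0)) abort("Sample mass `W` must be positive.")
  if (any(X < 0)) abort("Concentration `X` must be non-negative.")
  2.5 * X / W
}

#' Sulfur dioxide residue from an acid-base titration
#'
#' `M3 = (A - B) * c * 0.032 * 1e6 / W`: blank-corrected titrant volume times
#' molarity times the SO2 equivalent of 1 mL of 1 mol/L sodium hydroxide
#' (0.032 g), scaled to micrograms per gram of sample.
#'
#' @param A Titrant volume for the sample, mL.
#' @param B Blank titrant volume, mL (`A >= B >= 0`).
#' @param c Titrant molarity, mol/L (> 0; the pharmacopoeia method uses 0.01).
#' @param W Sample mass, g (> 0; the method uses ~10 g).
#' @return Residue in ug/g.
#' @examples
#' so2_residue(A = 2, B = 0.5, c = 0.01, W = 10)  # 48 ug/g
#' @export
so2_residue <- function(A, B, c = 0.01, W = 10) {
  if (any(B < 0) || any(A < B)) abort("Volumes must satisfy A >= B >= 0.")
  if (any(c <= 0)) abort("Molarity `c` must be positive.")
  if (any(W <= 0)) abort("Sample mass `W` must be positive.")
  (A - B) * c * 0.032 * 1e6 / W
}
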