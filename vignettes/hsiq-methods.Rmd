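---
title: "Hyperspectral chemometrics for sulfur-fumigation screening: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral chemometrics for sulfur-fumigation screening: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sulfur fumigation is a cheap way to dry and whiten medicinal and food
plants (lily bulb is the motivating crop), but it leaves sulfur-dioxide
residues and degrades nutrients. Near-infrared hyperspectral imaging offers
a non-destructive screen: a calibrated reflectance spectrum per sample, a
classifier for fumigated versus sun-dried material, and regressors for
polysaccharide (mg/g), total phenol (mg/g) and SO~2~ residue (µg/g).

`hsiq` implements that pipeline end to end: black/white-plate reflectance
calibration, region-of-interest mean spectra, VNIR/SWIR band fusion onto a
396-band 410–2500 nm working grid, reference-assay arithmetic, wavelength
selection by interval random frog (iRF) and variable combination population
analysis (VCPA), and four predictors — SVM, a 1-D CNN, an LSTM and a
CNN-LSTM hybrid (CLSTM) — benchmarked over full and selected band sets.
Because no public dataset with this design exists, the package ships a
seeded synthetic generator that reproduces the statistical structure the
analysis assumes, so every stage is testable.

## Reflectance calibration

Raw counts are converted to reflectance per pixel and band with the
standard plate correction

$$R = \frac{R_O - R_b}{R_w - R_b},$$

where $R_O$, $R_w$ and $R_b$ are the raw, white-reference and dark-current
frames. Two properties make this testable without hardware: the correction
is the exact algebraic inverse of the package's frame simulator, and it is
invariant under any common affine transform $a x + b$ of all three frames.
A band where the white and black frames coincide is a hard error rather
than a silent `NaN`: undefined bands would otherwise poison wavelength
selection downstream. Calibrated reflectance slightly above 1 is allowed
(real white references are ~99 % reflective); values outside
$[-0.1, 1.5]$ raise a warning only.

Band fusion concatenates VNIR bands strictly below the 990 nm seam with
SWIR bands at or above it. The SWIR sensor is native at the seam, so it
owns the 990 nm band by default (`prefer = "vnir"` flips the convention).
No interpolation is performed: all downstream mathematics is grid-agnostic,
so the union grid is the working grid.

## Reference assays

Ground-truth contents come from three pieces of assay arithmetic:
polysaccharide $M_1 = 5\,Y/W$ (kit concentration $Y$ mg/mL, sample mass
$W$ g, protocol mass 0.05 g), total phenol $M_2 = 2.5\,X/W$ (protocol mass
0.1 g), and titrated SO~2~ residue
$M_3 = (A - B)\,c \times 0.032 \times 10^6 / W$ (titrant volumes $A$, $B$
mL, molarity $c$, 0.032 g of SO~2~ per mL of 1 mol/L sodium hydroxide).
Standard curves are fitted absorbance → concentration directly, which is
the direction the kit readout is used in and avoids dividing by the fitted
slope at read time.

## The synthetic generator

The generator is the package's stand-in for the field data and defines the
study conditions every test runs under:

* **Baseline**: three broad Gaussian humps (amplitudes 0.42/0.30/0.22 at
  700/1320/2020 nm, widths 180/260/300 nm) over an offset of 0.18 —
  smooth, realistic reflectance without a radiative-transfer model.
* **Analyte features**: one absorption feature per analyte with depth
  linear in content. Polysaccharide and phenol are Gaussians at 1580 and
  2060 nm (width 30 nm; 0.0015 and 0.006 reflectance per mg/g) — far
  enough apart that each content is recoverable from its band by least
  squares with $R^2 = 1$ when noise is off. The SO~2~ feature uses a
  raised-cosine bump supported exactly on the signature band
  (1200–1400 nm by default), not a Gaussian, so the class difference is
  *identically zero* outside the band — a property the selection tests
  rely on.
* **Fumigation signature**: fumigated samples get an extra depression of
  the same bump shape with peak `signature_depth` × (M3 / max SO~2~),
  i.e. proportional to their residual load. Sun-dried samples carry the
  SO~2~ floor (0 µg/g) and no depression.
* **Contents** are drawn uniformly (range checks stay exact):
  polysaccharide 20–80 mg/g, phenol 2–20 mg/g, SO~2~ 100–500 µg/g for
  fumigated samples. These ranges are free parameters of the generator,
  chosen as plausible magnitudes for dried bulb material; they are not
  estimates of any real crop.
* **Noise** is i.i.d. additive Gaussian per band (default sd 0.01);
  spectra are clipped to $[0, 1.05]$, the ceiling above 1 matching real
  calibrated data.
* **Seeding**: each sample owns a substream derived from the dataset seed
  and its counter, so growing `n_samples` never reshuffles earlier
  samples; equal configs give byte-identical datasets.

What the generator does *not* emulate: scattering and moisture
confounders, baseline drift correlated across bands, spatial texture
within a sample, and instrument-specific band spacing. Passing tests
therefore demonstrate that the algorithms recover planted structure under
the stated noise model — not field performance on real lilies.

## Wavelength selection

Both selectors score a candidate band subset by cross-validated
partial-least-squares (PLS1) fitness: RMSECV for content targets, CV
misclassification for the class target (5 folds and up to 10 latent
variables by default; the selection studies in this package use 3 folds
and 5 latent variables, which is cheaper and equally discriminating at
n = 200). The PLS kernel is written in-package for speed inside the
selection loops and is cross-checked against an established PLS
implementation in the test suite.

**Interval random frog** tiles the grid into width-20/step-10 band windows
and runs a reversible-jump chain over window subsets. Each iteration draws
a candidate dimension $Q^* \sim \mathcal{N}(Q, 0.3Q)$; shrinking drops the
least important members (mean |PLS coefficient| over the window, fitted on
the current subset), growing adds random absent windows. A fitter
candidate is always accepted; a worse one with probability
$\min(1, \eta\, \mathrm{obj}/\mathrm{obj}^*)$, $\eta = 0.1$. The damping
constant matters: with plain ratio acceptance the chain absorbs
fitness-neutral windows (adding uninformative bands barely hurts a PLS
with few latent variables) and visitation probabilities flatten; $\eta$
restores the contrast the method needs. Visits are counted after a
burn-in (one quarter of the chain by default) because the chain needs time
to compress from its random initial subset. A window's selection
probability is its visitation frequency; each band inherits the maximum
over covering windows, and the bands of the `n_keep` top windows form the
selected set (ties broken by ascending window start, for reproducibility).

**VCPA** repeatedly scores random variable combinations (binary matrix
sampling, inclusion probability 0.5 over the currently retained bands),
keeps the best 10 % of combinations, ranks bands by inclusion frequency in
that elite pool, and shrinks the retained set along the exponentially
decreasing schedule $N_i = \mathrm{round}(p\,e^{-ki})$ with $k$ fixed so
the last of the runs retains `final_pool` bands. The survivors are then
searched exhaustively (all non-empty subsets, hence `final_pool` ≤ 14) and
the fittest subset wins; ties go to the smaller subset. `min_subset`
optionally floors the subset size — the pipeline sets 4 so the selected
bands can feed the convolutional models.

Both selectors record the data they were fitted on (a content hash); the
benchmark refuses a selection whose hash does not match its training
partition, which makes test-set leakage a hard error rather than a silent
bias.

## Models

The spectrum enters the networks as a length-$p$ sequence with one
channel. The CNN is: input batch-norm → 32 kernel-2 stride-2 convolutions
→ ReLU → average pooling (window 2) → dropout → 128 kernel-2 stride-2
convolutions → batch-norm → ReLU → dropout → fully connected 128 (tanh) →
output (2 softmax units for classification, 1 linear unit for
regression). On 396 bands the conv stack emits 49 positions × 128
channels. The CLSTM replaces the first fully connected layer with a
64-cell LSTM read along the downsampled band axis; its final hidden state
feeds the 128-wide layer. CNN and CLSTM share identical convolutional
configurations by construction, and the LSTM hidden size matches the
stand-alone LSTM model, so comparisons isolate the architectural change.

The LSTM uses the standard gate equations
($f,i,o$ logistic, $g$ tanh, $c_t = f \odot c_{t-1} + i \odot g$,
$h_t = o \odot \tanh c_t$); the layer is verified against a hand-rolled
single-cell oracle. For the stand-alone LSTM the spectrum is chunked into
steps of 4 consecutive bands (configurable): feeding 396 scalar steps
makes backpropagation through time degenerate, and chunking is the usual
remedy when a long 1-D signal meets a recurrent model.

Unstated engineering choices, all exposed in configuration: ReLU after
conv/batch-norm (the architecture names an unspecified activation; tanh on
the fully connected layer as stated), dropout 0.3, Adam with learning rate
10^-3^, batch 32, up to 300 epochs with early stopping (patience 30 on a
10 % validation split) as package defaults. Regression targets are
z-scored internally and de-standardized at prediction, which stabilizes
mixed-unit targets. The evaluation studies in this package train with a
fixed budget instead (40–60 epochs, learning rate 3 × 10^-3^, no early
stop): on 280 training spectra a 10 % validation split is ~28 samples, and
early stopping against so noisy a signal occasionally restores a
poorly-started snapshot. Training is deterministic given the seed and a
fixed BLAS thread count.

The SVM baseline delegates to `e1071` (C-classification / ε-regression,
radial kernel by default), the library a practitioner would use.

## Evaluation

Metrics are RMSE, MAE, Pearson's $R$ between measured and predicted
contents, and $R^2$ reported as the square of $R$ (the convention used for
measured-versus-predicted scatter); classification reports percent
accuracy. All four regression metrics are verified against independent
loop-style oracles, and MAE ≤ RMSE holds on every draw by construction.

The benchmark grid crosses band sets {Full, iRF, VCPA} with models {SVM,
CNN, LSTM, CLSTM} under one shared stratified 70/30 split (the split ratio
is a package default; re-splitting per cell would confound model and
split). Every cell records its derived seed, and the full grid is
bit-reproducible given the run configuration.

## Problem sizes and reproducibility

The shipped studies are scaled to a laptop core: selection-recovery runs
use n = 200 spectra, 1000-iteration iRF chains and a 10-run/100-combination
VCPA; model-recovery runs use n = 400 spectra, five seeds, 40–60 epochs.
These sizes are the package's chosen study conditions; the generator, all
thresholds and all seeds are fixed in code. `scripts/acceptance.R` re-runs
the whole battery from scratch and writes the resulting numbers as JSON;
the test suite asserts the same properties with `testthat`.

## Known limitations

* The synthetic generator is the only data source; nothing here validates
  instrument physics or real-crop chemistry.
* iRF hyperparameters ($\eta$, burn-in, interval width) and both
  selectors' run counts are method-literature defaults, not values tuned
  to any published dataset.
* The networks are small and CPU-bound by design; no GPU path, no
  hyperparameter search, no attention variants.
* Selection probabilities from short chains are noisy; ranking stability
  begins around 1000 iterations at these problem sizes.
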