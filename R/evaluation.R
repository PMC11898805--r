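# Splitting, the paper-style evaluation metrics, and the models x band-sets
# benchmark grid.

#' Stratified train/test split
#'
#' @param data Dataset tibble.
#' @param test_fraction Test proportion in (0, 1).
#' @param stratify Preserve class proportions of `label` (default `TRUE`).
#' @param seed Seed.
#' @return List with tibbles `train` and `test` (disjoint, exhaustive) and
#'   the integer `test_idx`.
#' @examples
#' d <- simulate_dataset(synthetic_config(n_samples = 20, seed = 1))
#' sp <- stratified_split(d, 0.3, seed = 1)
#' @export
stratified_split <- function(data, test_fraction = 0.3, stratify = TRUE,
                             seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must lie strictly in (0, 1).")
  }
  n <- nrow(data)
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (stratify) {
    if (!"label" %in% names(data)) abort("Stratified split needs a `label` column.")
    cls <- split(seq_len(n), data$label)
    if (length(cls) < 2 || any(lengths(cls) < 2)) {
      abort("Stratified split needs >= 2 members of each class.")
    }
    test_idx <- sort(unlist(lapply(cls, function(idx) {
      sample(idx, round(length(idx) * test_fraction))
    }), use.names = FALSE))
  } else {
    test_idx <- sort(sample.int(n, round(n * test_fraction)))
  }
  grid <- attr(data, "grid", exact = TRUE)
  train <- data[-test_idx, , drop = FALSE]
  test <- data[test_idx, , drop = FALSE]
  attr(train, "grid") <- grid
  attr(test, "grid") <- grid
  list(train = train, test = test, test_idx = test_idx)
}

#' Regression metrics (Pearson R, R-squared, MAE, RMSE)
#'
#' `RMSE = sqrt(mean((pred - actual)^2))`, `MAE = mean(|pred - actual|)`,
#' `R` the Pearson correlation between actual and predicted, and `R^2` its
#' square (the convention used when comparing measured against predicted
#' contents).
#'
#' @param actual,predicted Equal-length numeric vectors (n >= 2).
#' @return One-row tibble: `n`, `r`, `r_squared`, `mae`, `rmse`.
#' @examples
#' regression_metrics(1:5, c(1.1, 2.1, 2.9, 4.2, 5))
#' @export
regression_metrics <- function(actual, predicted) {
  if (length(actual) != length(predicted)) abort("Input lengths differ.")
  if (length(actual) < 2) abort("Need at least 2 observations.")
  if (sd(actual) == 0) abort("`actual` is constant; Pearson R is undefined.")
  r <- if (sd(predicted) == 0) 0 else cor(actual, predicted)
  tibble(
    n = length(actual),
    r = r,
    r_squared = r^2,
    mae = mean(abs(predicted - actual)),
    rmse = sqrt(mean((predicted - actual)^2))
  )
}

#' Classification accuracy (percent)
#'
#' @param actual,predicted Equal-length label vectors.
#' @return Percentage of agreeing positions, in \[0, 100\].
#' @examples
#' classification_accuracy(c("a", "a", "b", "b"), c("a", "a", "b", "a"))  # 75
#' @export
classification_accuracy <- function(actual, predicted) {
  if (length(actual) != length(predicted)) abort("Input lengths differ.")
  if (!length(actual)) abort("Need at least one observation.")
  100 * mean(as.character(actual) == as.character(predicted))
}

#' Run the band-sets x models benchmark grid
#'
#' Trains every model on every band set with one shared train/test split and
#' reports per-cell metrics: train/test accuracy for classification, or
#' Pearson R, R-squared, MAE and RMSE for content regression. Wavelength
#' selections must have been computed on the training partition only; each
#' `wavelength_selection` carries a hash of the data it saw, and a mismatch
#' with the training partition is a hard error (test-set leakage).
#'
#' @param split A [stratified_split()] result.
#' @param selections Named list of band sets: `NULL` entries mean the full
#'   grid, `wavelength_selection` objects contribute their selected bands
#'   (e.g. `list(Full = NULL, iRF = sel1, VCPA = sel2)`).
#' @param models Character vector from `c("svm", "cnn", "lstm", "clstm")`.
#' @param target `"label"` or a content target.
#' @param training A [training_config()] shared by the network cells.
#' @param seed Base seed; each cell derives its own.
#' @param keep_predictions Attach per-cell test predictions (for scatter
#'   plots) as attribute `"predictions"`.
#' @return A tibble of class `"benchmark_table"`, one row per cell.
#' @export
run_benchmark <- function(split, selections = list(Full = NULL),
                          models = c("svm", "cnn", "lstm", "clstm"),
                          target = "label",
                          training = training_config(),
                          seed = 1L,
                          keep_predictions = FALSE) {
  if (!all(c("train", "test") %in% names(split))) {
    abort("`split` must be a stratified_split() result.")
  }
  models <- match.arg(models, c("svm", "cnn", "lstm", "clstm"), several.ok = TRUE)
  col <- target_column(target)
  task <- if (col == "label") "classification" else "regression"
  train <- split$train
  test <- split$test
  Xtr <- spectra_matrix(train)
  ytr <- if (task == "classification") train$label else train[[col]]
  train_hash <- content_hash(list(unname(Xtr), as.character(ytr)))

  band_sets <- purrr::imap(selections, function(sel, name) {
    if (is.null(sel)) return(seq_len(ncol(Xtr)))
    if (!inherits(sel, "wavelength_selection")) {
      abort(paste0("Selection `", name, "` is not a wavelength_selection."))
    }
    if (!identical(sel$data_hash, train_hash)) {
      abort(paste0(
        "Selection `", name, "` was not computed on this training partition ",
        "(hash mismatch): refusing to proceed to avoid test-set leakage."
      ))
    }
    if (!length(sel$selected)) abort(paste0("Selection `", name, "` is empty."))
    sel$selected
  })

  rows <- list()
  preds <- list()
  cell_i <- 0L
  for (set_name in names(band_sets)) {
    bands <- band_sets[[set_name]]
    tr_b <- subset_bands(train, bands)
    te_b <- subset_bands(test, bands)
    for (mod in models) {
      cell_i <- cell_i + 1L
      cell_seed <- derive_seed(seed, cell_i)
      if (mod == "svm") {
        pred_te <- svm_fit_predict(tr_b, te_b, target = target, seed = cell_seed)
        pred_tr <- if (task == "classification") {
          fit <- attr(pred_te, "fit")
          tibble(.pred_class = predict(fit, spectra_matrix(tr_b)))
        } else {
          tibble(.pred = as.numeric(predict(attr(pred_te, "fit"),
                                            spectra_matrix(tr_b))))
        }
      } else {
        arch <- architecture_config(mod, task)
        cfg <- training
        cfg$seed <- cell_seed
        m <- build_model(arch, n_bands = length(bands), seed = cell_seed)
        m <- train_model(m, tr_b, target, cfg)
        pred_te <- predict(m, te_b)
        pred_tr <- predict(m, tr_b)
      }
      if (task == "classification") {
        row <- tibble(
          band_set = set_name, model = mod, n_bands = length(bands),
          train_accuracy = classification_accuracy(tr_b$label, pred_tr$.pred_class),
          test_accuracy = classification_accuracy(te_b$label, pred_te$.pred_class)
        )
      } else {
        mets <- regression_metrics(te_b[[col]], pred_te$.pred)
        row <- dplyr::bind_cols(
          tibble(band_set = set_name, model = mod, n_bands = length(bands)),
          mets[, c("r", "r_squared", "mae", "rmse")],
          tibble(train_rmse = sqrt(mean((pred_tr$.pred - tr_b[[col]])^2)))
        )
      }
      row$seed <- cell_seed
      rows[[cell_i]] <- row
      if (keep_predictions) {
        preds[[paste(set_name, mod, sep = "/")]] <- if (task == "classification") {
          tibble(band_set = set_name, model = mod,
                 actual = te_b$label, predicted = as.character(pred_te$.pred_class))
        } else {
          tibble(band_set = set_name, model = mod,
                 actual = te_b[[col]], predicted = pred_te$.pred)
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "task") <- task
  attr(out, "target") <- col
  if (keep_predictions) attr(out, "predictions") <- dplyr::bind_rows(preds)
  class(out) <- c("benchmark_table", class(out))
  out
}

# restrict a dataset tibble to a subset of band indices (keeping metadata)
subset_bands <- function(data, bands) {
  band_cols <- names(data)[is_band_name(names(data))]
  band_cols <- band_cols[order(as.numeric(band_cols))]
  keep <- c(setdiff(names(data), band_cols), band_cols[bands])
  out <- data[keep]
  g <- attr(data, "grid", exact = TRUE)
  if (!is.null(g)) attr(out, "grid") <- g[bands, , drop = FALSE]
  out
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat(sprintf("<benchmark: %s on `%s`, %d cells>\n",
              attr(x, "task"), attr(x, "target"), nrow(x)))
  NextMethod()
}

#' Plot a benchmark grid
#'
#' @param object A `benchmark_table`.
#' @param ... Unused.
#' @return A ggplot (test accuracy or RMSE per cell).
#' @method autoplot benchmark_table
#' @export
autoplot.benchmark_table <- function(object, ...) {
  metric <- if (attr(object, "task") == "classification") "test_accuracy" else "rmse"
  ggplot(object, aes(x = .data$model, y = .data[[metric]], fill = .data$band_set)) +
    geom_col(position = "dodge") +
    labs(title = sprintf("Benchmark (%s)", attr(object, "target")),
         x = NULL, y = metric, fill = "band set") +
    theme_minimal()
}

#' Scatter plot of predicted against measured contents
#'
#' @param predictions Tibble with `actual` and `predicted` columns (e.g. the
#'   `"predictions"` attribute of a regression benchmark), optionally with
#'   `band_set`/`model` columns for faceting.
#' @return A ggplot.
#' @export
plot_predictions <- function(predictions) {
  p <- ggplot(predictions, aes(x = .data$actual, y = .data$predicted)) +
    geom_point(alpha = 0.5) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = "measured content", y = "predicted content") +
    theme_minimal()
  if (all(c("band_set", "model") %in% names(predictions))) {
    p <- p + facet_wrap(~ band_set + model)
  }
  p
}
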