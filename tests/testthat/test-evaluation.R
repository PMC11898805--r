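test_that("stratified splits preserve class balance and are seeded", {
  d <- simulate_dataset(synthetic_config(n_samples = 100, seed = 3))
  sp <- stratified_split(d, 0.3, seed = 4)
  expect_equal(nrow(sp$train), 70)
  expect_equal(nrow(sp$test), 30)
  expect_equal(sum(sp$test$label == "fumigated"), 15)
  expect_equal(sum(sp$train$label == "fumigated"), 35)
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0)
  sp2 <- stratified_split(d, 0.3, seed = 4)
  expect_identical(sp$test_idx, sp2$test_idx)

  expect_error(stratified_split(d, 0), "test_fraction")
  expect_error(stratified_split(d, 1.2), "test_fraction")
  single <- d[d$label == "fumigated", ]
  expect_error(stratified_split(single, 0.3), "each class")
})

test_that("regression metrics satisfy their closed-form identities", {
  m <- regression_metrics(1:10, 1:10)
  expect_equal(m$r, 1)
  expect_equal(m$r_squared, 1)
  expect_equal(m$mae, 0)
  expect_equal(m$rmse, 0)

  shifted <- regression_metrics(1:10, (1:10) + 1)
  expect_equal(shifted$mae, 1)
  expect_equal(shifted$rmse, 1)
  expect_equal(shifted$r, 1)

  expect_error(regression_metrics(1:3, 1:4), "lengths differ")
  expect_error(regression_metrics(rep(2, 5), 1:5), "constant")
})

test_that("metrics agree with the loop oracle and respect MAE <= RMSE", {
  set.seed(12)
  for (rep_i in 1:200) {
    n <- sample(5:40, 1)
    actual <- rnorm(n, sd = runif(1, 0.5, 50))
    predicted <- actual + rnorm(n, sd = runif(1, 0.01, 20))
    m <- regression_metrics(actual, predicted)
    o <- oracle_metrics(actual, predicted)
    expect_equal(m$rmse, o$rmse, tolerance = 1e-10)
    expect_equal(m$mae, o$mae, tolerance = 1e-10)
    expect_equal(m$r, o$r, tolerance = 1e-10)
    expect_equal(m$r_squared, o$r2, tolerance = 1e-10)
    expect_lte(m$mae, m$rmse + 1e-12)
  }
})

test_that("Pearson R is invariant to positive affine rescaling of predictions", {
  set.seed(13)
  actual <- rnorm(30)
  predicted <- actual + rnorm(30, sd = 0.3)
  base <- regression_metrics(actual, predicted)
  scaled <- regression_metrics(actual, 3.7 * predicted + 11)
  expect_equal(scaled$r, base$r, tolerance = 1e-12)
})

test_that("classification accuracy is an exact percentage", {
  expect_equal(classification_accuracy(c("a", "b"), c("a", "b")), 100)
  expect_equal(classification_accuracy(c("a", "a", "b", "b"), c("a", "a", "b", "a")), 75)
  expect_equal(classification_accuracy(c("a", "a"), c("b", "b")), 0)
  expect_error(classification_accuracy(c("a"), c("a", "b")), "lengths differ")
})

test_that("the benchmark grid is complete, finite and leakage-guarded", {
  d <- tiny_dataset(n = 48, n_bands = 32, noise_sd = 0.01, depth = 0.15)
  sp <- stratified_split(d, 0.25, seed = 1)
  Xtr <- spectra_matrix(sp$train)
  wl <- dataset_grid(d)$wavelength
  fs <- fitness_spec(folds = 3, max_lv = 3)
  sel <- irf_select(Xtr, sp$train$label, n_iterations = 40, n_keep = 1,
                    seed = 2, fitness = fs, wavelengths = wl)
  tab <- run_benchmark(
    sp, selections = list(Full = NULL, iRF = sel),
    models = c("svm", "cnn"), target = "label",
    training = training_config(epochs = 1, validation_fraction = 0, patience = 0),
    seed = 3
  )
  expect_equal(nrow(tab), 4)
  expect_setequal(unique(tab$band_set), c("Full", "iRF"))
  expect_true(all(is.finite(tab$train_accuracy)))
  expect_true(all(is.finite(tab$test_accuracy)))

  # selection computed on the full dataset (test rows included) must be refused
  leaky <- irf_select(spectra_matrix(d), d$label, n_iterations = 20, n_keep = 1,
                      seed = 2, fitness = fs, wavelengths = wl)
  expect_error(
    run_benchmark(sp, selections = list(iRF = leaky), models = "svm",
                  target = "label"),
    "leakage"
  )
})

test_that("a regression benchmark reports the four metrics per cell", {
  d <- tiny_dataset(n = 40, n_bands = 32, noise_sd = 0.01, depth = 0.15)
  sp <- stratified_split(d, 0.25, seed = 5)
  tab <- run_benchmark(
    sp, selections = list(Full = NULL), models = "svm", target = "so2",
    seed = 1, keep_predictions = TRUE
  )
  expect_named(tab, c("band_set", "model", "n_bands", "r", "r_squared",
                      "mae", "rmse", "train_rmse", "seed"))
  preds <- attr(tab, "predictions")
  expect_equal(nrow(preds), nrow(sp$test))
  expect_s3_class(plot_predictions(preds), "ggplot")
  expect_s3_class(autoplot(tab), "ggplot")
})
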