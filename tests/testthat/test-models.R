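test_that("LSTM cell matches hand gate arithmetic at zero weights", {
  H <- 2
  zero <- matrix(0, H, H + 1)
  p <- list(W_f = zero, W_i = zero, W_g = zero, W_o = zero,
            b_f = rep(0, H), b_i = rep(0, H), b_g = rep(0, H), b_o = rep(0, H))
  r <- lstm_cell_forward(p, x_t = 0.7, h_prev = rep(0, H), c_prev = rep(0, H))
  expect_equal(r$f, rep(0.5, H))
  expect_equal(r$i, rep(0.5, H))
  expect_equal(r$o, rep(0.5, H))
  expect_equal(r$g, rep(0, H))
  expect_equal(r$c, rep(0, H))
  expect_equal(r$h, rep(0, H))

  v <- c(0.4, -1.2)
  r2 <- lstm_cell_forward(p, x_t = 0.7, h_prev = rep(0, H), c_prev = v)
  expect_equal(r2$c, 0.5 * v)
  expect_equal(r2$h, 0.5 * tanh(0.5 * v))

  expect_error(lstm_cell_forward(p, x_t = c(1, 2), h_prev = rep(0, H),
                                 c_prev = rep(0, H)), "W_f")
})

test_that("the batched LSTM layer equals repeated cell application", {
  set.seed(10)
  for (rep_i in 1:10) {
    H <- sample(2:4, 1)
    C <- sample(2:3, 1)
    T_steps <- sample(2:5, 1)
    layer <- hsiq:::layer_lstm(C, H)
    x <- array(rnorm(C * T_steps), dim = c(1, C, T_steps))
    out <- hsiq:::lstm_forward(layer, x)$out
    cp <- hsiq:::lstm_layer_cell_params(layer)
    h <- rep(0, H); cs <- rep(0, H)
    for (t in seq_len(T_steps)) {
      step <- lstm_cell_forward(cp, x[1, , t], h, cs)
      h <- step$h; cs <- step$c
    }
    expect_equal(as.numeric(out), h, tolerance = 1e-6)
  }
})

test_that("the conv stack obeys its shape law and CNN/CLSTM share it", {
  expect_equal(conv_stack_len(396), 49)
  expect_equal(conv_stack_len(100), 12)
  expect_equal(conv_stack_len(4), 1)

  cnn <- build_model(architecture_config("cnn", "classification"), 396, seed = 1)
  clstm <- build_model(architecture_config("clstm", "classification"), 396, seed = 1)
  conv_shapes <- function(m) {
    lapply(Filter(function(l) l$type %in% c("conv", "bn"), m$layers),
           function(l) lapply(l$params, dim))
  }
  expect_identical(conv_shapes(cnn), conv_shapes(clstm))

  # forward through the conv stack yields the predicted sequence length
  X <- matrix(rnorm(2 * 396), 2, 396)
  xb <- hsiq:::shape_input(clstm, X)
  out <- xb
  for (l in clstm$layers[1:9]) out <- hsiq:::layer_forward(l, out, FALSE)$out
  expect_equal(dim(out), c(2, 128, 49))
})

test_that("architecture contracts hold and bad sizes error", {
  m <- build_model(architecture_config("clstm", "classification"), 396, seed = 5)
  lstm_layer <- Filter(function(l) l$type == "lstm", m$layers)[[1]]
  expect_equal(lstm_layer$hidden, 64)
  dense1 <- Filter(function(l) l$type == "dense", m$layers)[[1]]
  expect_equal(ncol(dense1$params$W), 128)
  dense2 <- Filter(function(l) l$type == "dense", m$layers)[[2]]
  expect_equal(ncol(dense2$params$W), 2)

  m2 <- build_model(architecture_config("clstm", "classification"), 396, seed = 5)
  expect_identical(m$layers, m2$layers)
  expect_error(build_model(architecture_config("cnn"), 2, seed = 1), "n_bands")
})

test_that("networks fit a noiseless separable two-class set perfectly", {
  d <- tiny_dataset(n = 60, n_bands = 64, noise_sd = 0, depth = 0.15)
  m <- build_model(architecture_config("clstm", "classification"), 64, seed = 2)
  m <- train_model(m, d, "label",
                   training_config(epochs = 200, patience = 0,
                                   validation_fraction = 0, lr = 3e-3,
                                   batch_size = 16, seed = 2))
  pr <- predict(m, d)
  expect_equal(classification_accuracy(d$label, pr$.pred_class), 100)
  expect_lte(nrow(m$history), 200)
  expect_equal(rowSums(as.matrix(pr[, c(".pred_fumigated", ".pred_sun_dried")])),
               rep(1, 60), tolerance = 1e-6)
})

test_that("training history, degenerate targets and guards behave", {
  d <- tiny_dataset(n = 24, n_bands = 32, noise_sd = 0.01)
  m <- build_model(architecture_config("cnn", "classification"), 32, seed = 1)
  m1 <- train_model(m, d, "label",
                    training_config(epochs = 1, validation_fraction = 0,
                                    patience = 0, seed = 1))
  expect_equal(nrow(m1$history), 1)

  # regression on a constant target converges to that constant
  dc <- d
  dc$so2 <- rep(5, nrow(dc))
  mr <- build_model(architecture_config("cnn", "regression", dropout = 0), 32, seed = 1)
  mr <- train_model(mr, dc, "so2",
                    training_config(epochs = 80, validation_fraction = 0,
                                    patience = 0, lr = 1e-2, seed = 1))
  pred <- predict(mr, dc)$.pred
  expect_lt(sqrt(mean((pred - 5)^2)), 1e-2)

  single <- d[d$label == "fumigated", ]
  m2 <- build_model(architecture_config("cnn", "classification"), 32, seed = 1)
  expect_error(train_model(m2, single, "label", training_config(epochs = 1)),
               "two classes")
  expect_error(predict(m1, tiny_dataset(n = 4, n_bands = 16)), "bands")
  expect_error(train_model(m, d, "label",
                           training_config(epochs = 0)), "epochs")
})

test_that("the LSTM-alone model trains on chunked spectra", {
  d <- tiny_dataset(n = 40, n_bands = 64, noise_sd = 0, depth = 0.2)
  m <- build_model(architecture_config("lstm", "classification"), 64, seed = 3)
  m <- train_model(m, d, "label",
                   training_config(epochs = 60, patience = 0,
                                   validation_fraction = 0, lr = 3e-3,
                                   batch_size = 16, seed = 3))
  pr <- predict(m, d)
  expect_gte(classification_accuracy(d$label, pr$.pred_class), 90)
})

test_that("SVM wrapper classifies and regresses sensibly", {
  # widely separated two-band toy: class decided by band 1
  set.seed(30)
  make_toy <- function(n) {
    cls <- rep(c("sun_dried", "fumigated"), n / 2)
    tibble::tibble(
      sample_id = sprintf("T%02d", seq_len(n)),
      label = cls,
      so2 = ifelse(cls == "fumigated", 300, 0) + runif(n, -5, 5),
      `500` = (cls == "fumigated") * 1 + rnorm(n, sd = 0.05),
      `1500` = runif(n)
    )
  }
  train <- make_toy(8)
  test <- make_toy(4)
  pr <- svm_fit_predict(train, test, target = "label", kernel = "linear")
  expect_equal(classification_accuracy(test$label, pr$.pred_class), 100)
  expect_equal(rowSums(as.matrix(pr[, -1])), rep(1, nrow(test)), tolerance = 1e-6)

  # y linear in band 1
  d <- tiny_dataset(n = 60, n_bands = 32, noise_sd = 0.005, depth = 0.3, seed = 21)
  sp <- stratified_split(d, 0.25, seed = 1)
  prr <- svm_fit_predict(sp$train, sp$test, target = "so2", kernel = "linear",
                         epsilon = 0.01)
  mets <- regression_metrics(sp$test$so2, prr$.pred)
  expect_gt(mets$r_squared, 0.9)

  single <- sp$train[sp$train$label == "fumigated", ]
  expect_error(svm_fit_predict(single, sp$test, target = "label"), "both classes")
})

test_that("model broom methods summarise training", {
  d <- tiny_dataset(n = 24, n_bands = 32)
  m <- train_model(build_model(architecture_config("cnn", "classification"), 32, seed = 1),
                   d, "label",
                   training_config(epochs = 2, validation_fraction = 0,
                                   patience = 0, seed = 1))
  expect_named(tidy(m), c("epoch", "train_loss", "val_loss"))
  gl <- glance(m)
  expect_equal(gl$kind, "cnn")
  expect_gt(gl$n_parameters, 1000)
  expect_s3_class(autoplot(m), "ggplot")
})
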