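# The four predictors: SVM (via e1071) and the three in-package networks
# (1-D CNN, LSTM, CNN-LSTM hybrid) for binary fumigation classification and
# single-analyte content regression on mean spectra.

#' Architecture configuration
#'
#' Describes one of the four model kinds. The convolutional stack is shared
#' verbatim between `"cnn"` and `"clstm"` (batch norm, 32 kernel-2 stride-2
#' kernels, ReLU, average pooling, dropout, then 128 kernel-2 stride-2
#' kernels with batch norm, ReLU and dropout); `"clstm"` replaces the first
#' fully connected layer with a 64-cell LSTM fed the conv-stack output
#' stepwise along the downsampled band axis. Fully connected layers have
#' widths 128 and `n_out` (2 for classification, 1 for regression) and use
#' hyperbolic-tangent activation.
#'
#' @param kind `"svm"`, `"cnn"`, `"lstm"` or `"clstm"`.
#' @param task `"classification"` or `"regression"`.
#' @param conv_kernels Kernel counts of the two conv blocks (fixed pair).
#' @param lstm_hidden LSTM hidden size (default 64).
#' @param fc_width Penultimate fully connected width (default 128).
#' @param dropout Dropout rate in the conv blocks (default 0.3).
#' @param lstm_chunk For the plain LSTM: number of consecutive bands fed per
#'   time step (default 4; the spectrum is zero-padded to a multiple).
#' @return A list of class `"architecture_config"`.
#' @export
architecture_config <- function(kind = c("clstm", "cnn", "lstm", "svm"),
                                task = c("classification", "regression"),
                                conv_kernels = c(32L, 128L),
                                lstm_hidden = 64L,
                                fc_width = 128L,
                                dropout = 0.3,
                                lstm_chunk = 4L) {
  kind <- match.arg(kind)
  task <- match.arg(task)
  structure(
    list(kind = kind, task = task, conv_kernels = as.integer(conv_kernels),
         lstm_hidden = as.integer(lstm_hidden), fc_width = as.integer(fc_width),
         dropout = dropout, lstm_chunk = as.integer(lstm_chunk),
         n_out = if (task == "classification") 2L else 1L),
    class = "architecture_config"
  )
}

# sequence length after one kernel-2 stride-2 stage (length-1 inputs are
# zero-padded, so the stack never collapses below one position)
stage_len <- function(t) max(1L, t %/% 2L)

#' Sequence length after the conv stack
#'
#' conv(k2, s2) -> average pool (k2, s2) -> conv(k2, s2), each halving the
#' band axis (floor), with a length-1 sequence zero-padded before a
#' convolution.
#'
#' @param n_bands Input band count.
#' @return Output sequence length.
#' @export
conv_stack_len <- function(n_bands) {
  stage_len(stage_len(stage_len(as.integer(n_bands))))
}

#' Build an (untrained) spectral model
#'
#' @param arch An [architecture_config()] (not `"svm"`; SVMs are fitted
#'   directly by [svm_fit_predict()]).
#' @param n_bands Number of input bands (>= 4).
#' @param seed Seed for parameter initialization.
#' @return An object of class `"hsiq_model"`.
#' @examples
#' m <- build_model(architecture_config("clstm"), n_bands = 396, seed = 1)
#' @export
build_model <- function(arch, n_bands, seed = 1L) {
  stopifnot(inherits(arch, "architecture_config"))
  if (arch$kind == "svm") abort("SVMs are fitted by svm_fit_predict(), not build_model().")
  if (n_bands < 4) abort("`n_bands` must be >= 4 for the stride-2 stack.")
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 97L))

  k1 <- arch$conv_kernels[1]
  k2 <- arch$conv_kernels[2]
  layers <- switch(arch$kind,
    cnn = {
      t_out <- conv_stack_len(n_bands)
      list(
        layer_bn(1L), layer_conv(1L, k1), layer_relu(),
        layer_pool(), layer_dropout(arch$dropout),
        layer_conv(k1, k2), layer_bn(k2), layer_relu(),
        layer_dropout(arch$dropout),
        layer_flatten(),
        layer_dense(k2 * t_out, arch$fc_width), layer_tanh(),
        layer_dense(arch$fc_width, arch$n_out)
      )
    },
    clstm = list(
      layer_bn(1L), layer_conv(1L, k1), layer_relu(),
      layer_pool(), layer_dropout(arch$dropout),
      layer_conv(k1, k2), layer_bn(k2), layer_relu(),
      layer_dropout(arch$dropout),
      layer_lstm(k2, arch$lstm_hidden),
      layer_dense(arch$lstm_hidden, arch$fc_width), layer_tanh(),
      layer_dense(arch$fc_width, arch$n_out)
    ),
    lstm = list(
      layer_lstm(arch$lstm_chunk, arch$lstm_hidden),
      layer_dense(arch$lstm_hidden, arch$fc_width), layer_tanh(),
      layer_dense(arch$fc_width, arch$n_out)
    ),
    abort(paste0("Unknown architecture kind ", arch$kind))
  )
  structure(
    list(arch = arch, layers = layers, n_bands = as.integer(n_bands),
         seed = as.integer(seed), trained = FALSE, history = tibble(),
         x_center = NULL, x_scale = NULL, y_center = 0, y_scale = 1,
         class_levels = NULL),
    class = "hsiq_model"
  )
}

#' @export
print.hsiq_model <- function(x, ...) {
  cat(sprintf(
    "<%s %s model: %d bands, %s>\n", toupper(x$arch$kind), x$arch$task,
    x$n_bands, if (x$trained) sprintf("trained (%d epochs)", nrow(x$history))
    else "untrained"
  ))
  invisible(x)
}

#' One LSTM cell step
#'
#' The standard gate equations: `f`, `i`, `o` are logistic gates and `g` the
#' tanh cell candidate, each computed from the concatenation `[h_prev, x_t]`;
#' `c_t = f * c_prev + i * g` and `h_t = o * tanh(c_t)`.
#'
#' @param params List with gate weight matrices `W_f`, `W_i`, `W_g`, `W_o`
#'   (each hidden x (hidden + input)) and biases `b_f`, `b_i`, `b_g`, `b_o`.
#' @param x_t Input vector at this step.
#' @param h_prev,c_prev Previous hidden and cell state vectors.
#' @return List with `h`, `c` and the gate activations `f`, `i`, `g`, `o`.
#' @examples
#' p <- list(W_f = matrix(0, 2, 3), W_i = matrix(0, 2, 3),
#'           W_g = matrix(0, 2, 3), W_o = matrix(0, 2, 3),
#'           b_f = rep(0, 2), b_i = rep(0, 2), b_g = rep(0, 2), b_o = rep(0, 2))
#' lstm_cell_forward(p, x_t = 1, h_prev = rep(0, 2), c_prev = rep(0, 2))$h
#' @export
lstm_cell_forward <- function(params, x_t, h_prev, c_prev) {
  a <- c(h_prev, x_t)
  for (nm in c("W_f", "W_i", "W_g", "W_o")) {
    if (ncol(params[[nm]]) != length(a)) {
      abort(paste0("`", nm, "` has ", ncol(params[[nm]]),
                   " columns but [h, x] has length ", length(a), "."))
    }
  }
  f <- sigmoid(as.numeric(params$W_f %*% a + params$b_f))
  i <- sigmoid(as.numeric(params$W_i %*% a + params$b_i))
  g <- tanh(as.numeric(params$W_g %*% a + params$b_g))
  o <- sigmoid(as.numeric(params$W_o %*% a + params$b_o))
  c_t <- f * c_prev + i * g
  h_t <- o * tanh(c_t)
  list(h = h_t, c = c_t, f = f, i = i, g = g, o = o)
}

# slice a trained LSTM layer's combined gate matrix into the per-gate cell
# parameter format (used by the oracle-equivalence tests)
lstm_layer_cell_params <- function(layer) {
  stopifnot(layer$type == "lstm")
  H <- layer$hidden
  W <- layer$params$W
  b <- layer$params$b
  gate <- function(k) t(W[, (k - 1) * H + seq_len(H), drop = FALSE])
  list(
    W_f = gate(1), W_i = gate(2), W_g = gate(3), W_o = gate(4),
    b_f = b[seq_len(H)], b_i = b[H + seq_len(H)],
    b_g = b[2 * H + seq_len(H)], b_o = b[3 * H + seq_len(H)]
  )
}

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param epochs Maximum epochs (>= 1).
#' @param batch_size Minibatch size.
#' @param validation_fraction Fraction held out for early stopping (0 turns
#'   the validation split off).
#' @param patience Early-stop patience in epochs (0 disables early stopping).
#' @param seed Seed for shuffling, dropout and the validation split.
#' @return A list of class `"training_config"`.
#' @export
training_config <- function(lr = 1e-3, epochs = 300L, batch_size = 32L,
                            validation_fraction = 0.1, patience = 30L,
                            seed = 1L) {
  if (epochs < 1) abort("`epochs` must be >= 1.")
  if (lr <= 0) abort("`lr` must be positive.")
  structure(
    list(lr = lr, epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         validation_fraction = validation_fraction, patience = as.integer(patience),
         seed = as.integer(seed)),
    class = "training_config"
  )
}

# shape spectra for a given architecture: 3-D (n, C, T)
shape_input <- function(model, X) {
  n <- nrow(X)
  if (model$arch$kind == "lstm") {
    ch <- model$arch$lstm_chunk
    T_steps <- ceiling(ncol(X) / ch)
    pad <- T_steps * ch - ncol(X)
    if (pad > 0) X <- cbind(X, matrix(0, n, pad))
    # step t carries bands (t-1)*ch + 1 .. t*ch
    aperm(array(t(X), dim = c(ch, T_steps, n)), c(3, 1, 2))
  } else {
    array(t(X), dim = c(1, ncol(X), n)) |> aperm(c(3, 1, 2))
  }
}

target_column <- function(target) {
  switch(target,
    label = "label", M1 = "polysaccharide", M2 = "phenol", M3 = "so2",
    polysaccharide = "polysaccharide", phenol = "phenol", so2 = "so2",
    abort(paste0("Unknown target `", target, "`."))
  )
}

#' Train a spectral network
#'
#' Minibatch Adam on cross-entropy (classification) or mean squared error
#' (regression; the target is z-scored internally and de-standardized at
#' prediction time). Inputs are standardized per band with training-set
#' statistics. With a validation split and patience, the parameters from the
#' best validation epoch are restored.
#'
#' @param model An untrained [build_model()] result.
#' @param data Dataset tibble (wavelength-named band columns plus targets).
#' @param target `"label"` for classification, or one of `"polysaccharide"`,
#'   `"phenol"`, `"so2"` (aliases `"M1"`, `"M2"`, `"M3"`).
#' @param config A [training_config()].
#' @return The trained model, with a per-epoch `history` tibble.
#' @export
train_model <- function(model, data, target, config = training_config()) {
  stopifnot(inherits(model, "hsiq_model"))
  X <- spectra_matrix(data)
  if (ncol(X) != model$n_bands) {
    abort(sprintf("Model expects %d bands, data has %d.", model$n_bands, ncol(X)))
  }
  col <- target_column(target)
  task <- model$arch$task
  if (task == "classification") {
    if (col != "label") abort("Classification models train on `target = \"label\"`.")
    f <- factor(data$label)
    if (nlevels(f) != 2) abort("Classification needs exactly two classes in the training data.")
    y <- as.integer(f)
    model$class_levels <- levels(f)
  } else {
    if (col == "label") abort("Regression models need a content target, not `label`.")
    y_raw <- data[[col]]
    model$y_center <- mean(y_raw)
    model$y_scale <- if (sd(y_raw) > 0) sd(y_raw) else 1
    y <- (y_raw - model$y_center) / model$y_scale
  }
  model$x_center <- colMeans(X)
  model$x_scale <- pmax(apply(X, 2, sd), 1e-8)
  Xs <- sweep(sweep(X, 2, model$x_center), 2, model$x_scale, `/`)
  model$target <- col

  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, 11L))

  n <- nrow(Xs)
  if (n < 2) abort("Need at least 2 training samples.")
  use_val <- config$validation_fraction > 0 && config$patience > 0 &&
    n * config$validation_fraction >= 2
  if (use_val) {
    n_val <- max(2L, round(n * config$validation_fraction))
    val_idx <- sample.int(n, n_val)
    if (task == "classification" && length(unique(y[-val_idx])) < 2) {
      use_val <- FALSE
    }
  }
  if (use_val) {
    tr_idx <- setdiff(seq_len(n), val_idx)
  } else {
    tr_idx <- seq_len(n)
    val_idx <- integer()
  }

  layers <- model$layers
  state <- adam_init(layers)
  step <- 0L
  best_val <- Inf
  best_layers <- layers
  wait <- 0L
  hist_train <- numeric()
  hist_val <- numeric()

  x_val <- if (use_val) shape_input(model, Xs[val_idx, , drop = FALSE])
  y_val <- y[val_idx]

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    epoch_loss <- 0
    n_seen <- 0L
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      xb <- shape_input(model, Xs[idx, , drop = FALSE])
      fw <- net_forward(layers, xb, training = TRUE)
      layers <- fw$layers
      lg <- loss_grad(fw$out, y[idx], task)
      if (!is.finite(lg$loss)) {
        abort(sprintf("Non-finite loss at epoch %d (%.4g); lower the learning rate.",
                      epoch, lg$loss))
      }
      grads <- net_backward(layers, fw$caches, lg$dlogits)
      step <- step + 1L
      upd <- adam_step(layers, grads, state, config$lr, step)
      layers <- upd$layers
      state <- upd$state
      epoch_loss <- epoch_loss + lg$loss * length(idx)
      n_seen <- n_seen + length(idx)
    }
    hist_train[epoch] <- epoch_loss / n_seen
    if (use_val) {
      fv <- net_forward(layers, x_val, training = FALSE)
      lv <- loss_grad(fv$out, y_val, task)$loss
      hist_val[epoch] <- lv
      if (lv < best_val - 1e-9) {
        best_val <- lv
        best_layers <- layers
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    } else {
      hist_val[epoch] <- NA_real_
    }
  }

  model$layers <- if (use_val) best_layers else layers
  model$trained <- TRUE
  model$history <- tibble(
    epoch = seq_along(hist_train),
    train_loss = hist_train,
    val_loss = hist_val[seq_along(hist_train)]
  )
  model$training_config <- config
  model
}

#' Predict from a trained spectral network
#'
#' @param object A trained `hsiq_model`.
#' @param data Dataset tibble with the same band columns as training.
#' @param ... Unused.
#' @return For classification, a tibble with `.pred_class` and one
#'   probability column per class (rows sum to 1); for regression, a tibble
#'   with `.pred` on the original content scale.
#' @export
predict.hsiq_model <- function(object, data, ...) {
  if (!object$trained) abort("Model is untrained; call train_model() first.")
  X <- spectra_matrix(data)
  if (ncol(X) != object$n_bands) {
    abort(sprintf("Model expects %d bands, data has %d.", object$n_bands, ncol(X)))
  }
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, `/`)
  xb <- shape_input(object, Xs)
  out <- net_forward(object$layers, xb, training = FALSE)$out
  if (object$arch$task == "classification") {
    p <- softmax_rows(out)
    colnames(p) <- paste0(".pred_", object$class_levels)
    cls <- object$class_levels[max.col(p)]
    dplyr::bind_cols(
      tibble(.pred_class = factor(cls, levels = object$class_levels)),
      as_tibble(p)
    )
  } else {
    tibble(.pred = out[, 1] * object$y_scale + object$y_center)
  }
}

#' Fit-and-predict support vector machine
#'
#' C-classification or epsilon-regression via `e1071::svm` with a radial
#' basis kernel by default, matching common chemometrics practice.
#'
#' @param train,test Dataset tibbles.
#' @param target As in [train_model()].
#' @param task `"classification"` or `"regression"` (inferred from the
#'   target when missing).
#' @param kernel `e1071` kernel name (default `"radial"`).
#' @param cost,epsilon SVM hyperparameters.
#' @param seed Seed (e1071 is deterministic for these tasks; kept for
#'   interface symmetry and provenance).
#' @return Prediction tibble in the [predict.hsiq_model()] layout, plus the
#'   fitted model in attribute `"fit"`.
#' @export
svm_fit_predict <- function(train, test, target = "label",
                            task = NULL, kernel = "radial",
                            cost = 10, epsilon = 0.1, seed = 1L) {
  col <- target_column(target)
  if (is.null(task)) task <- if (col == "label") "classification" else "regression"
  Xtr <- spectra_matrix(train)
  Xte <- spectra_matrix(test)
  if (ncol(Xtr) != ncol(Xte)) abort("Train and test band counts differ.")
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (task == "classification") {
    ytr <- factor(train$label)
    if (nlevels(ytr) < 2) abort("Classification needs both classes in the training data.")
    fit <- e1071::svm(Xtr, ytr, kernel = kernel, cost = cost,
                      probability = TRUE, scale = TRUE)
    pred <- predict(fit, Xte, probability = TRUE)
    p <- attr(pred, "probabilities")[, levels(ytr), drop = FALSE]
    colnames(p) <- paste0(".pred_", colnames(p))
    out <- dplyr::bind_cols(tibble(.pred_class = pred), as_tibble(p))
  } else {
    ytr <- train[[col]]
    fit <- e1071::svm(Xtr, ytr, kernel = kernel, cost = cost,
                      epsilon = epsilon, type = "eps-regression", scale = TRUE)
    out <- tibble(.pred = as.numeric(predict(fit, Xte)))
  }
  attr(out, "fit") <- fit
  out
}

# ---- broom methods ----------------------------------------------------------

#' Tidy / summarize a trained network
#'
#' `tidy()` returns the per-epoch loss history; `glance()` a one-row model
#' summary.
#'
#' @param x A trained `hsiq_model`.
#' @param ... Unused.
#' @method tidy hsiq_model
#' @export
tidy.hsiq_model <- function(x, ...) x$history

#' @rdname tidy.hsiq_model
#' @method glance hsiq_model
#' @export
glance.hsiq_model <- function(x, ...) {
  n_par <- sum(purrr::map_dbl(x$layers, function(l) {
    sum(purrr::map_dbl(l$params, length))
  }))
  tibble(
    kind = x$arch$kind,
    task = x$arch$task,
    n_bands = x$n_bands,
    n_parameters = n_par,
    epochs_run = nrow(x$history),
    final_train_loss = if (nrow(x$history)) tail(x$history$train_loss, 1) else NA_real_
  )
}

#' Plot the training history
#'
#' @param object A trained `hsiq_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hsiq_model
#' @export
autoplot.hsiq_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = "series", values_to = "loss")
  df <- df[is.finite(df$loss), ]
  ggplot(df, aes(x = .data$epoch, y = .data$loss, colour = .data$series)) +
    geom_line() +
    labs(title = sprintf("%s training history", toupper(object$arch$kind)),
         x = "epoch", y = "loss") +
    theme_minimal()
}
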