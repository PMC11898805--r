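# Shared fixtures, built in code at test time.

# small noiseless two-class dataset on a reduced grid (fast to train on)
tiny_dataset <- function(n = 60, n_bands = 64, noise_sd = 0, depth = 0.15,
                         seed = 7) {
  cfg <- synthetic_config(
    n_samples = n, noise_sd = noise_sd, signature_depth = depth, seed = seed,
    grid = make_wavelength_grid(n_bands, c(410, 2500), 990)
  )
  simulate_dataset(cfg)
}

# independent straight-line LSTM cell oracle: gate equations written out
# directly, no shared code with the package internals
oracle_lstm_cell <- function(W_f, W_i, W_g, W_o, b_f, b_i, b_g, b_o,
                             x_t, h_prev, c_prev) {
  sig <- function(z) 1 / (1 + exp(-z))
  a <- c(h_prev, x_t)
  f <- sig(drop(W_f %*% a) + b_f)
  i <- sig(drop(W_i %*% a) + b_i)
  g <- tanh(drop(W_g %*% a) + b_g)
  o <- sig(drop(W_o %*% a) + b_o)
  c_t <- f * c_prev + i * g
  list(h = o * tanh(c_t), c = c_t)
}

# loop-style regression metric oracle (scalar accumulation, no vector math)
oracle_metrics <- function(actual, predicted) {
  n <- length(actual)
  se <- 0; ae <- 0
  for (k in seq_len(n)) {
    se <- se + (predicted[k] - actual[k])^2
    ae <- ae + abs(predicted[k] - actual[k])
  }
  ma <- sum(actual) / n
  mp <- sum(predicted) / n
  num <- 0; da <- 0; dp <- 0
  for (k in seq_len(n)) {
    num <- num + (predicted[k] - mp) * (actual[k] - ma)
    dp <- dp + (predicted[k] - mp)^2
    da <- da + (actual[k] - ma)^2
  }
  r <- num / sqrt(dp * da)
  list(rmse = sqrt(se / n), mae = ae / n, r = r, r2 = r^2)
}

in_signature_fraction <- function(selection, band = c(1200, 1400)) {
  wl <- selection$scores$wavelength[selection$selected]
  mean(wl >= band[1] & wl <= band[2])
}
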