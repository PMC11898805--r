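# Univariate partial-least-squares (PLS1) kernel and the cross-validated
# fitness both wavelength selectors score candidate band subsets with.
# Written for speed inside tight selection loops: one pass per latent
# variable, no model object allocation.

# PLS1 regression (NIPALS deflation), single response.
# Returns prediction coefficients on the original scale.
pls1_fit <- function(X, y, ncomp) {
  n <- nrow(X)
  p <- ncol(X)
  ncomp <- min(ncomp, p, n - 1L)
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  yc <- y - ybar
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- Xc %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pa <- crossprod(Xc, t) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - t %*% t(pa)
    yc <- yc - t * qa
    W[, a] <- w
    P[, a] <- pa
    q[a] <- qa
    a_used <- a
  }
  if (a_used == 0L) {
    return(list(coef = numeric(p), intercept = ybar, ncomp = 0L))
  }
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  B <- W %*% solve(crossprod(P, W), q)
  list(coef = as.numeric(B), intercept = ybar - sum(xbar * B), ncomp = a_used)
}

pls1_predict <- function(fit, X) {
  as.numeric(X %*% fit$coef + fit$intercept)
}

#' Fitness specification for wavelength selection
#'
#' Both selectors score a candidate band subset by cross-validating a
#' latent-variable (PLS) regressor on it: root-mean-square error of
#' cross-validation (RMSECV) for numeric targets, CV misclassification rate
#' for class targets. Lower is fitter in both cases.
#'
#' @param folds Number of CV folds (>= 2).
#' @param max_lv Maximum latent variables; capped at the subset size and the
#'   training-fold sample count at fit time.
#' @return A list of class `"fitness_spec"`.
#' @export
fitness_spec <- function(folds = 5L, max_lv = 10L) {
  if (folds < 2) abort("`folds` must be >= 2.")
  if (max_lv < 1) abort("`max_lv` must be >= 1.")
  structure(list(folds = as.integer(folds), max_lv = as.integer(max_lv)),
            class = "fitness_spec")
}

# seeded fold assignment, balanced sizes
make_folds <- function(n, folds, seed) {
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sample(rep_len(seq_len(folds), n))
}

# y may be numeric (regression) or factor/character (binary classification,
# encoded 0/1 and thresholded at 0.5).
encode_target <- function(y) {
  if (is.numeric(y)) {
    list(y = y, classification = FALSE)
  } else {
    f <- factor(y)
    if (nlevels(f) != 2L) abort("Classification fitness needs exactly two classes.")
    list(y = as.numeric(f) - 1, classification = TRUE)
  }
}

#' Cross-validated fitness of a band subset
#'
#' @param X Numeric matrix, samples x selected bands (non-empty).
#' @param y Target: numeric content or two-level class labels.
#' @param fitness A [fitness_spec()].
#' @param seed Seed for the fold assignment.
#' @param fold_id Optional precomputed fold vector (overrides `seed`).
#' @return The objective value: RMSECV or CV misclassification fraction.
#' @export
fitness_cv <- function(X, y, fitness = fitness_spec(), seed = 1L, fold_id = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 1) abort("Band subset is empty.")
  n <- nrow(X)
  if (length(y) != n) abort("`X` rows and `y` length differ.")
  enc <- encode_target(y)
  if (sd(enc$y) == 0) abort("Target is constant; fitness undefined.")
  if (fitness$folds > n) abort("More CV folds than samples.")
  if (is.null(fold_id)) fold_id <- make_folds(n, fitness$folds, seed)
  pred <- numeric(n)
  for (k in seq_len(max(fold_id))) {
    hold <- fold_id == k
    fit <- pls1_fit(X[!hold, , drop = FALSE], enc$y[!hold], fitness$max_lv)
    pred[hold] <- pls1_predict(fit, X[hold, , drop = FALSE])
  }
  if (enc$classification) {
    mean((pred >= 0.5) != (enc$y == 1))
  } else {
    sqrt(mean((pred - enc$y)^2))
  }
}
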