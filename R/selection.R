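# Wavelength selection: interval random frog (iRF) and variable combination
# population analysis (VCPA). Both return a `wavelength_selection` object
# carrying per-band scores, the chosen subset, a diagnostic trace, and a hash
# of the data they saw (used by the benchmark's leakage guard).

#' Tile a wavelength grid into index intervals
#'
#' Builds the sliding-window intervals the interval random frog chain
#' operates on: windows of `width` bands starting every `step` bands.
#' Intervals are stored 1-based inclusive (`start`..`end`).
#'
#' @param grid_len Number of bands.
#' @param width Interval width in bands (1 <= width <= grid_len).
#' @param step Stride between interval starts (>= 1).
#' @param include_partial Append a final shorter interval when the tiling
#'   does not reach the last band (default `FALSE`).
#' @return Tibble with `interval`, `start`, `end`.
#' @examples
#' nrow(make_intervals(396, 20, 10))  # 38
#' @export
make_intervals <- function(grid_len, width = 20L, step = 10L,
                           include_partial = FALSE) {
  if (width < 1 || width > grid_len) abort("`width` must be in [1, grid_len].")
  if (step < 1) abort("`step` must be >= 1.")
  starts <- seq(1L, grid_len - width + 1L, by = step)
  ends <- starts + width - 1L
  if (include_partial && max(ends) < grid_len) {
    nxt <- max(starts) + step
    if (nxt <= grid_len) {
      starts <- c(starts, nxt)
      ends <- c(ends, grid_len)
    }
  }
  tibble(interval = seq_along(starts), start = as.integer(starts),
         end = as.integer(ends))
}

new_wavelength_selection <- function(method, wavelengths, scores, selected,
                                     trace, config, seed, data_hash,
                                     best_fitness) {
  structure(
    list(
      method = method,
      scores = tibble(band = seq_along(wavelengths),
                      wavelength = wavelengths, score = scores),
      selected = sort(selected),
      trace = trace,
      config = config,
      seed = seed,
      data_hash = data_hash,
      best_fitness = best_fitness
    ),
    class = "wavelength_selection"
  )
}

#' @export
print.wavelength_selection <- function(x, ...) {
  cat(sprintf(
    "<%s selection: %d of %d bands (%.0f-%.0f nm), best fitness %.4g>\n",
    x$method, length(x$selected), nrow(x$scores),
    min(x$scores$wavelength[x$selected]), max(x$scores$wavelength[x$selected]),
    x$best_fitness
  ))
  invisible(x)
}

resolve_wavelengths <- function(X, wavelengths) {
  if (!is.null(wavelengths)) {
    if (length(wavelengths) != ncol(X)) abort("`wavelengths` length must match ncol(X).")
    return(as.numeric(wavelengths))
  }
  cn <- colnames(X)
  if (!is.null(cn) && all(is_band_name(cn))) return(as.numeric(cn))
  as.numeric(seq_len(ncol(X)))
}

check_selection_inputs <- function(X, y, fitness) {
  if (nrow(X) != length(y)) abort("`X` rows and `y` length differ.")
  enc <- encode_target(y)
  if (sd(enc$y) == 0) abort("Target is constant; selection fitness undefined.")
  if (nrow(X) < 2 * fitness$folds) abort("Need at least 2 samples per CV fold.")
  invisible(TRUE)
}

#' Interval random frog wavelength selection
#'
#' Runs a reversible-jump pseudo-MCMC chain over subsets of wavelength
#' intervals. Each iteration draws a candidate dimension from a normal
#' distribution around the current one (a dimension jump): when shrinking,
#' the least important intervals are dropped (importance is the mean
#' absolute PLS regression coefficient over an interval's bands, fitted on
#' the current subset, so fitness-neutral intervals are stripped first);
#' when growing, random absent intervals are added. The chain scores the
#' candidate subset
#' with the cross-validated fitness, accepts outright if fitter and otherwise
#' with probability proportional to the current/candidate objective ratio
#' (`eta * ratio`, clipped to \[0, 1\]; the damping constant `eta` keeps the
#' chain from absorbing fitness-neutral intervals). An interval's selection
#' probability is the fraction of post-burn-in chain
#' states containing it; each band inherits the maximum probability over the
#' intervals covering it.
#'
#' @param X Samples x bands matrix (columns may be named by wavelength).
#' @param y Target: numeric content or two-level labels.
#' @param intervals Interval tibble from [make_intervals()]; defaults to
#'   width-20 / step-10 windows over `ncol(X)`.
#' @param fitness A [fitness_spec()].
#' @param n_iterations Chain length (default 1000).
#' @param n_burn Burn-in iterations discarded before visitation counting
#'   (default `n_iterations %/% 4`); the chain needs time to compress from
#'   its random initial subset before visit frequencies are meaningful.
#' @param n_keep Number of top-probability intervals whose bands form the
#'   selected set (default 10).
#' @param eta Damping constant of the worse-candidate acceptance probability
#'   `min(1, eta * current/candidate)` (default 0.1).
#' @param seed Integer seed (chain and CV folds).
#' @param wavelengths Optional per-column wavelengths (nm).
#' @return A `wavelength_selection` object.
#' @export
irf_select <- function(X, y, intervals = NULL, fitness = fitness_spec(),
                       n_iterations = 1000L, n_burn = NULL, n_keep = 10L,
                       eta = 0.1, seed = 1L, wavelengths = NULL) {
  X <- as.matrix(X)
  if (n_iterations < 1) abort("`n_iterations` must be >= 1.")
  if (is.null(n_burn)) n_burn <- n_iterations %/% 4L
  if (n_burn < 0 || n_burn >= n_iterations) {
    abort("`n_burn` must be in [0, n_iterations).")
  }
  check_selection_inputs(X, y, fitness)
  if (is.null(intervals)) {
    intervals <- make_intervals(ncol(X), width = min(20L, ncol(X)),
                                step = min(10L, ncol(X)))
  }
  if (any(intervals$end > ncol(X)) || any(intervals$start < 1)) {
    abort("Intervals exceed the grid bounds.")
  }
  wl <- resolve_wavelengths(X, wavelengths)
  n_int <- nrow(intervals)
  members <- purrr::map(seq_len(n_int),
                        function(i) intervals$start[i]:intervals$end[i])

  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold_id <- make_folds(nrow(X), fitness$folds, derive_seed(seed, 1L))

  cache <- new.env(parent = emptyenv())
  score_state <- function(state) {
    key <- paste(which(state), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    cols <- sort(unique(unlist(members[state])))
    val <- fitness_cv(X[, cols, drop = FALSE], y, fitness, fold_id = fold_id)
    cache[[key]] <- val
    val
  }
  y_num <- encode_target(y)$y
  # per-member importance: mean |PLS coefficient| over the interval's bands,
  # fitted on the state's band union
  member_importance <- function(on) {
    cols <- sort(unique(unlist(members[on])))
    fit <- pls1_fit(X[, cols, drop = FALSE], y_num, fitness$max_lv)
    co <- abs(fit$coef)
    vapply(on, function(i) mean(co[match(members[[i]], cols)]), numeric(1))
  }

  state <- rep(FALSE, n_int)
  state[sample.int(n_int, min(n_keep, n_int))] <- TRUE
  obj <- score_state(state)
  visits <- numeric(n_int)
  trace_size <- integer(n_iterations)
  trace_obj <- numeric(n_iterations)
  best <- obj

  for (it in seq_len(n_iterations)) {
    cand <- state
    q <- sum(state)
    q_new <- max(1L, min(n_int, as.integer(round(rnorm(1, q, 0.3 * q)))))
    if (q_new < q) {
      on <- which(state)
      imp <- member_importance(on)
      drop_n <- q - q_new
      cand[on[order(imp)[seq_len(drop_n)]]] <- FALSE
    } else if (q_new > q) {
      off <- which(!state)
      cand[sample(off, min(q_new - q, length(off)))] <- TRUE
    }
    cand_obj <- score_state(cand)
    accept <- cand_obj <= obj ||
      runif(1) < min(1, eta * obj / max(cand_obj, .Machine$double.eps))
    if (accept) {
      state <- cand
      obj <- cand_obj
    }
    best <- min(best, obj)
    if (it > n_burn) visits <- visits + state
    trace_size[it] <- sum(state)
    trace_obj[it] <- obj
  }

  prob <- visits / (n_iterations - n_burn)
  # top intervals; ties broken by ascending start index for reproducibility
  ord <- order(-prob, intervals$start)
  keep <- ord[seq_len(min(n_keep, n_int))]
  selected <- sort(unique(unlist(members[keep])))
  scores <- numeric(ncol(X))
  for (i in seq_len(n_int)) {
    idx <- members[[i]]
    scores[idx] <- pmax(scores[idx], prob[i])
  }
  new_wavelength_selection(
    method = "iRF", wavelengths = wl, scores = scores, selected = selected,
    trace = tibble(iteration = seq_len(n_iterations), size = trace_size,
                   objective = trace_obj),
    config = list(intervals = intervals, fitness = fitness,
                  n_iterations = n_iterations, n_burn = n_burn,
                  n_keep = n_keep, eta = eta),
    seed = seed, data_hash = content_hash(list(unname(X), as.character(y))),
    best_fitness = best
  )
}

# exponentially decreasing retention schedule: round(p * exp(-k * i)) with k
# chosen so run n_runs retains exactly final_pool variables
edf_schedule <- function(p, n_runs, final_pool) {
  k <- log(p / final_pool) / n_runs
  n_i <- round(p * exp(-k * seq_len(n_runs)))
  n_i[n_runs] <- final_pool
  pmax(cummin(n_i), final_pool)
}

#' Variable combination population analysis (VCPA) wavelength selection
#'
#' Repeatedly scores random variable combinations (binary matrix sampling:
#' each retained band enters a combination with probability 0.5), keeps the
#' best `keep_ratio` fraction, and shrinks the retained set along an
#' exponentially decreasing function until `final_pool` bands remain; those
#' survivors are then searched exhaustively (all non-empty subsets) and the
#' fittest subset is returned.
#'
#' @inheritParams irf_select
#' @param n_edf_runs Number of shrink iterations (default 50).
#' @param n_bms Combinations drawn per run (default 1000).
#' @param keep_ratio Fraction of combinations forming the elite pool
#'   (default 0.1).
#' @param final_pool Survivor count entering the exhaustive stage
#'   (default 10, must be <= 14).
#' @param min_subset Smallest subset size the exhaustive stage may return
#'   (default 1; set 4 when the selected bands must feed the convolutional
#'   models, whose two stride-2 convolutions need at least 4 bands).
#' @return A `wavelength_selection` object; `trace` records the retained
#'   count and best fitness per run.
#' @export
vcpa_select <- function(X, y, fitness = fitness_spec(), n_edf_runs = 50L,
                        n_bms = 1000L, keep_ratio = 0.1, final_pool = 10L,
                        min_subset = 1L, seed = 1L, wavelengths = NULL) {
  X <- as.matrix(X)
  check_selection_inputs(X, y, fitness)
  if (final_pool < 1) abort("`final_pool` must be >= 1.")
  if (final_pool > 14) abort("`final_pool` must be <= 14 (exhaustive stage is 2^final_pool).")
  if (keep_ratio <= 0 || keep_ratio > 1) abort("`keep_ratio` must be in (0, 1].")
  if (min_subset < 1 || min_subset > final_pool) {
    abort("`min_subset` must lie in [1, final_pool].")
  }
  p0 <- ncol(X)
  if (final_pool > p0) abort("`final_pool` exceeds the number of bands.")
  wl <- resolve_wavelengths(X, wavelengths)

  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold_id <- make_folds(nrow(X), fitness$folds, derive_seed(seed, 1L))

  schedule <- edf_schedule(p0, n_edf_runs, final_pool)
  retained <- seq_len(p0)
  trace <- tibble(run = integer(), retained = integer(), best_fitness = numeric())
  freq_last <- rep(1, p0)

  for (run in seq_len(n_edf_runs)) {
    m <- length(retained)
    combos <- matrix(runif(n_bms * m) < 0.5, nrow = n_bms)
    empty <- rowSums(combos) == 0L
    if (any(empty)) combos[cbind(which(empty), sample.int(m, sum(empty), replace = TRUE))] <- TRUE
    objs <- vapply(seq_len(n_bms), function(r) {
      cols <- retained[combos[r, ]]
      fitness_cv(X[, cols, drop = FALSE], y, fitness, fold_id = fold_id)
    }, numeric(1))
    n_elite <- max(1L, round(keep_ratio * n_bms))
    elite <- order(objs)[seq_len(n_elite)]
    freq <- colMeans(combos[elite, , drop = FALSE])
    keep_n <- min(schedule[run], m)
    ord <- order(-freq, retained)
    kept_pos <- ord[seq_len(keep_n)]
    freq_last <- numeric(p0)
    freq_last[retained[kept_pos]] <- freq[kept_pos]
    retained <- sort(retained[kept_pos])
    trace <- dplyr::bind_rows(trace, tibble(run = run, retained = keep_n,
                                            best_fitness = min(objs)))
  }

  # exhaustive search over all non-empty subsets of the survivors; ties go to
  # the smaller subset, then to the lexicographically first one
  m <- length(retained)
  n_sub <- 2L^m - 1L
  best_obj <- Inf
  best_subset <- retained
  for (code in seq_len(n_sub)) {
    take <- as.logical(bitwAnd(code, 2L^(seq_len(m) - 1L)))
    if (sum(take) < min_subset) next
    cols <- retained[take]
    obj <- fitness_cv(X[, cols, drop = FALSE], y, fitness, fold_id = fold_id)
    better <- obj < best_obj - 1e-15 ||
      (abs(obj - best_obj) <= 1e-15 && length(cols) < length(best_subset))
    if (better) {
      best_obj <- obj
      best_subset <- cols
    }
  }

  new_wavelength_selection(
    method = "VCPA", wavelengths = wl, scores = freq_last,
    selected = best_subset,
    trace = trace,
    config = list(fitness = fitness, n_edf_runs = n_edf_runs, n_bms = n_bms,
                  keep_ratio = keep_ratio, final_pool = final_pool,
                  min_subset = min_subset, schedule = schedule),
    seed = seed, data_hash = content_hash(list(unname(X), as.character(y))),
    best_fitness = best_obj
  )
}

# ---- broom / ggplot2 methods ------------------------------------------------

#' Tidy a wavelength selection
#'
#' @param x A `wavelength_selection`.
#' @param ... Unused.
#' @return Tibble with `band`, `wavelength`, `score`, `selected`.
#' @method tidy wavelength_selection
#' @export
tidy.wavelength_selection <- function(x, ...) {
  dplyr::mutate(x$scores, selected = .data$band %in% x$selected)
}

#' @rdname tidy.wavelength_selection
#' @method glance wavelength_selection
#' @export
glance.wavelength_selection <- function(x, ...) {
  tibble(
    method = x$method,
    n_bands = nrow(x$scores),
    n_selected = length(x$selected),
    best_fitness = x$best_fitness,
    seed = x$seed
  )
}

#' Plot per-band selection scores
#'
#' @param object A `wavelength_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wavelength_selection
#' @export
autoplot.wavelength_selection <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$wavelength, y = .data$score)) +
    geom_line(colour = "grey40") +
    geom_rug(data = df[df$selected, ], sides = "b", colour = "firebrick") +
    labs(
      x = "wavelength (nm)",
      y = if (object$method == "iRF") "selection probability" else "inclusion frequency",
      title = paste(object$method, "wavelength selection")
    ) +
    theme_minimal()
}

#' Export a selection result to JSON
#'
#' @param x A `wavelength_selection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(x, path) {
  stopifnot(inherits(x, "wavelength_selection"))
  payload <- list(
    method = x$method,
    seed = x$seed,
    best_fitness = x$best_fitness,
    scores = setNames(as.list(x$scores$score),
                      sprintf("%.4f", x$scores$wavelength)),
    selected_band = x$selected,
    selected_wavelength = x$scores$wavelength[x$selected],
    data_hash = x$data_hash
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
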