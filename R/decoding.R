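#' Decoding window specifications
#'
#' Each decoding window consists of two sub-windows whose mean responses are
#' stacked as if from distinct cells, letting the decoder assign distinct
#' axes to each sub-window. The three standard windows span exactly the same
#' total duration: short latency (50-75 and 75-100 ms), long latency (120-145
#' and 145-170 ms) and a combined window (62-87 and 132-157 ms).
#'
#' @param name `"short"`, `"long"` or `"combined"`, or any label when
#'   `sub_windows` is supplied.
#' @param sub_windows Optional list of two `[start, end)` pairs.
#' @param offset_ms Shift applied to both sub-windows (e.g. +20 ms for the
#'   anterior-medial face patch, whose dynamics lag).
#' @return A `window_spec`.
#' @export
window_spec <- function(name = c("short", "long", "combined"),
                        sub_windows = NULL, offset_ms = 0) {
  if (is.null(sub_windows)) {
    name <- match.arg(name)
    sub_windows <- switch(name,
      short = list(c(50, 75), c(75, 100)),
      long = list(c(120, 145), c(145, 170)),
      combined = list(c(62, 87), c(132, 157)))
  }
  if (length(sub_windows) != 2) abort("a window spec has exactly two sub-windows")
  sub_windows <- purrr::map(sub_windows, function(w) w + offset_ms)
  structure(list(name = name, sub_windows = sub_windows), class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %s: [%g, %g) + [%g, %g) ms\n", x$name,
              x$sub_windows[[1]][1], x$sub_windows[[1]][2],
              x$sub_windows[[2]][1], x$sub_windows[[2]][2]))
  invisible(x)
}

# stacked sub-window design matrix: stimuli x (2 * cells), sub-window 1 cells
# first, then sub-window 2 cells. When norm_idx is given, each column is
# z-scored using the mean/s.d. over those (training) stimuli, harmonizing
# per-cell gain and offset across windows so that cross-window transfer
# tests the response *pattern*, not kernel amplitude differences.
stacked_responses <- function(pop, spec, cells = NULL, norm_idx = NULL) {
  if (is.null(cells)) cells <- seq_len(dim(pop$rates)[1])
  X1 <- t(window_mean_rates(pop, spec$sub_windows[[1]])[cells, , drop = FALSE])
  X2 <- t(window_mean_rates(pop, spec$sub_windows[[2]])[cells, , drop = FALSE])
  X <- cbind(X1, X2)
  if (!is.null(norm_idx)) {
    mu <- colMeans(X[norm_idx, , drop = FALSE])
    sdv <- apply(X[norm_idx, , drop = FALSE], 2, sd)
    sdv[sdv == 0] <- 1
    X <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  }
  X
}

# ridge regression with validation-fold lambda selection; returns the fitted
# map plus centering info
ridge_fit <- function(X, Y, lambdas = 10^seq(-8, 3, by = 1), val_frac = 0.2,
                      seed = 1) {
  n <- nrow(X)
  val <- with_seed(seed, sample(n, max(1, round(val_frac * n))))
  tr <- setdiff(seq_len(n), val)
  fit_one <- function(rows, lam) {
    xc <- colMeans(X[rows, , drop = FALSE])
    yc <- colMeans(Y[rows, , drop = FALSE])
    Xc <- sweep(X[rows, , drop = FALSE], 2, xc)
    Yc <- sweep(Y[rows, , drop = FALSE], 2, yc)
    G <- crossprod(Xc) + diag(lam, ncol(X))
    W <- tryCatch(solve(G, crossprod(Xc, Yc)), error = function(e) NULL)
    if (is.null(W)) return(NULL)   # penalty too small for this Gram matrix
    list(W = W, x_center = xc, y_center = yc)
  }
  sse <- vapply(lambdas, function(lam) {
    f <- fit_one(tr, lam)
    if (is.null(f)) return(Inf)
    P <- sweep(sweep(X[val, , drop = FALSE], 2, f$x_center) %*% f$W,
               2, f$y_center, "+")
    sum((Y[val, , drop = FALSE] - P)^2)
  }, numeric(1))
  if (all(!is.finite(sse))) abort("ridge solve failed at every penalty")
  lam <- lambdas[which.min(sse)]
  out <- NULL
  for (lam2 in sort(lambdas[lambdas >= lam])) {
    out <- fit_one(seq_len(n), lam2)
    if (!is.null(out)) { lam <- lam2; break }
  }
  if (is.null(out)) abort("ridge solve failed at every penalty")
  out$lambda <- lam
  out
}

ridge_predict <- function(fit, X) {
  sweep(sweep(X, 2, fit$x_center) %*% fit$W, 2, fit$y_center, "+")
}

#' Train a window-wise linear decoder of latent stimulus features
#'
#' Ridge regression (with validation-fold selection of the penalty) from the
#' stacked two-sub-window population responses to the latent feature vectors
#' of the training stimuli.
#'
#' @param pop A `response_tensor`.
#' @param latents stimuli x L matrix of latent features (the decode target).
#' @param window A [window_spec()].
#' @param train_idx Training stimulus indices.
#' @param cells Optional cell subset (order defines the stacking).
#' @param lambdas Ridge path searched.
#' @param normalize Z-score each cell x sub-window channel over the training
#'   stimuli (per window, so cross-window transfer compares response
#'   patterns rather than kernel amplitudes).
#' @param seed Seed for the validation fold.
#' @return A `linear_decoder`: `W` ((2*cells) x L), centering vectors,
#'   `window`, `cells`, `lambda`, `train_idx`.
#' @export
train_decoder <- function(pop, latents, window, train_idx, cells = NULL,
                          lambdas = 10^seq(-8, 3, by = 1), normalize = TRUE,
                          seed = 1) {
  if (is.null(cells)) cells <- seq_len(dim(pop$rates)[1])
  X <- stacked_responses(pop, window, cells,
                         norm_idx = if (normalize) train_idx)
  fit <- ridge_fit(X[train_idx, , drop = FALSE],
                   as.matrix(latents)[train_idx, , drop = FALSE],
                   lambdas = lambdas, seed = seed)
  structure(
    list(W = fit$W, x_center = fit$x_center, y_center = fit$y_center,
         lambda = fit$lambda, window = window, cells = cells,
         train_idx = train_idx, normalize = normalize),
    class = "linear_decoder"
  )
}

#' @export
print.linear_decoder <- function(x, ...) {
  cat(sprintf("<linear_decoder> %s window, %d cells (x2 sub-windows) -> %d latents, lambda = %g\n",
              x$window$name, length(x$cells), ncol(x$W), x$lambda))
  invisible(x)
}

#' Decode latent features, optionally from a different window
#'
#' Applies a trained decoder to the named stimuli, reading the population
#' responses from `window` — the decoder's own training window by default, or
#' any other window of identical geometry for cross-window transfer (whose
#' failure measures how completely the code changed between latencies).
#'
#' @param decoder A `linear_decoder`.
#' @param pop The (same) `response_tensor`.
#' @param test_idx Stimulus indices to decode.
#' @param window A `window_spec`; default the decoder's training window.
#' @return List: `decoded` (stimuli x L), `r2_overall`, `r2_per_dim`
#'   (against the true latents if supplied via `latents`), or just the
#'   decoded matrix when `latents` is `NULL`.
#' @param latents Optional true latents for R-squared reporting.
#' @export
cross_window_decode <- function(decoder, pop, test_idx, window = decoder$window,
                                latents = NULL) {
  X <- stacked_responses(pop, window, decoder$cells,
                         norm_idx = if (isTRUE(decoder$normalize)) decoder$train_idx)
  dec <- ridge_predict(decoder, X[test_idx, , drop = FALSE])
  if (is.null(latents)) return(list(decoded = dec))
  Y <- as.matrix(latents)[test_idx, , drop = FALSE]
  sse <- colSums((Y - dec)^2)
  sst <- colSums(sweep(Y, 2, colMeans(Y))^2)
  list(decoded = dec,
       r2_per_dim = ifelse(sst == 0, 0, 1 - sse / sst),
       r2_overall = 1 - sum(sse) / sum(sst))
}

#' Nearest-neighbour identification of decoded stimuli
#'
#' A decoded item is "correct" when its nearest reference (Euclidean,
#' optionally after a fixed linear map into a metric space) is its own
#' reference among all references. Ties break to the lowest stimulus index.
#'
#' @param decoded,reference n x L matrices with matching row order.
#' @param metric_map Optional L x M matrix applied to both before the
#'   distance computation.
#' @return Fraction correct.
#' @export
identify_nearest <- function(decoded, reference, metric_map = NULL) {
  decoded <- as.matrix(decoded); reference <- as.matrix(reference)
  if (nrow(reference) == 0) abort("empty reference set")
  if (!is.null(metric_map)) {
    decoded <- decoded %*% metric_map
    reference <- reference %*% metric_map
  }
  ref_sq <- rowSums(reference^2)
  correct <- vapply(seq_len(nrow(decoded)), function(i) {
    d2 <- ref_sq - 2 * as.vector(reference %*% decoded[i, ])
    which.min(d2) == i  # which.min takes the lowest index on ties
  }, logical(1))
  mean(correct)
}

#' Identification accuracy versus population size
#'
#' For each window and cell count, resamples that many cells (without
#' replacement) `n_resample` times, trains a decoder per resample, decodes
#' the held-out stimuli and scores nearest-neighbour identification among
#' them. A cell count of 0 decodes the constant training mean (chance
#' performance `1/n_test`).
#'
#' @param pop A `response_tensor`.
#' @param latents stimuli x L latent features.
#' @param windows Named list of [window_spec()]s.
#' @param cell_counts Population sizes evaluated.
#' @param train_idx,test_idx Stimulus split (defaults: 90/10 over faces only,
#'   mirroring identification among face references).
#' @param n_resample Cell resamples per count.
#' @param metric_map Optional metric-space map for [identify_nearest()].
#' @param seed Integer seed.
#' @return Tibble: `window`, `n_cells`, `resample`, `accuracy`.
#' @export
accuracy_vs_cellcount <- function(pop, latents, windows, cell_counts,
                                  train_idx = NULL, test_idx = NULL,
                                  n_resample = 30, metric_map = NULL, seed = 1) {
  n_cells_all <- dim(pop$rates)[1]
  if (max(cell_counts) > n_cells_all) abort("cell count exceeds population size")
  if (is.null(train_idx)) {
    faces <- which(pop$category == "face")
    sp <- with_seed(seed, {
      te <- sample(faces, max(2, round(0.1 * length(faces))))
      list(train = setdiff(faces, te), test = sort(te))
    })
    train_idx <- sp$train; test_idx <- sp$test
  }
  Y <- as.matrix(latents)
  ref <- Y[test_idx, , drop = FALSE]
  # stack (and normalize) each window's responses once for all resamples
  Xw <- purrr::map(windows, function(w)
    stacked_responses(pop, w, norm_idx = train_idx))
  grid <- tidyr::expand_grid(window = names(windows), n_cells = cell_counts,
                             resample = seq_len(n_resample))
  acc <- purrr::pmap_dbl(grid, function(window, n_cells, resample) {
    cells <- with_seed(seed + 7919L * resample + n_cells, {
      if (n_cells > 0) sample(n_cells_all, n_cells) else integer(0)
    })
    if (n_cells == 0) {
      dec <- matrix(rep(colMeans(Y[train_idx, , drop = FALSE]),
                        each = length(test_idx)), length(test_idx))
      return(identify_nearest(dec, ref, metric_map))
    }
    X <- Xw[[window]][, c(cells, cells + n_cells_all), drop = FALSE]
    fit <- ridge_fit(X[train_idx, , drop = FALSE],
                     Y[train_idx, , drop = FALSE], seed = seed + resample)
    dec <- ridge_predict(fit, X[test_idx, , drop = FALSE])
    identify_nearest(dec, ref, metric_map)
  })
  grid$accuracy <- acc
  grid
}

#' Redundancy-versus-diversity simulated-unit experiment
#'
#' Builds two pools of simulated units from latent features with a decaying
#' variance spectrum: "short-latency" units linearly combine a random subset
#' of only the first `low_dims` feature dimensions, "long-latency" units a
#' random subset of all `latent_dim` dimensions; both get additive Gaussian
#' noise. Identification accuracy versus cell count is then computed for each
#' pool. Few cells favour the redundant low-dimensional pool (those
#' dimensions carry the most variance); many cells favour the diverse pool —
#' the crossover that explains the window-wise decoding results.
#'
#' @param latent_dim Total latent dimensionality.
#' @param low_dims Dimensions available to the short-latency pool.
#' @param n_stim Number of simulated (face) stimuli.
#' @param noise_sd Unit response noise s.d.
#' @param cell_counts Population sizes evaluated.
#' @param n_resample Unit resamples per count.
#' @param n_test Held-out identification set size.
#' @param n_mix Number of latent dimensions each unit linearly combines
#'   (a random subset of the eligible dimensions).
#' @param seed Integer seed.
#' @return Tibble: `pool` (`short`/`long`), `n_cells`, `resample`,
#'   `accuracy`.
#' @export
simulated_unit_experiment <- function(latent_dim = 60, low_dims = 5,
                                      n_stim = 500, noise_sd = 1,
                                      cell_counts = c(5, 10, 20, 50, 100, 200),
                                      n_resample = 10, n_test = 100,
                                      n_mix = low_dims, seed = 1) {
  if (low_dims >= latent_dim) abort("low_dims must be < latent_dim")
  n_units <- max(cell_counts)
  with_seed(seed, {
    sds <- seq_len(latent_dim)^(-0.5)   # decaying variance spectrum
    L <- matrix(rnorm(n_stim * latent_dim), n_stim) %*% diag(sds)
    make_pool <- function(dims) {
      W <- matrix(0, n_units, latent_dim)
      for (u in seq_len(n_units)) {
        sel <- sample(dims, min(n_mix, length(dims)))
        W[u, sel] <- rnorm(length(sel))
      }
      W %*% t(L) + matrix(rnorm(n_units * n_stim, sd = noise_sd), n_units)
    }
    pools <- list(short = make_pool(seq_len(low_dims)),
                  long = make_pool(seq_len(latent_dim)))
    test_idx <- sample(n_stim, n_test)
    train_idx <- setdiff(seq_len(n_stim), test_idx)
    ref <- L[test_idx, , drop = FALSE]
    grid <- tidyr::expand_grid(pool = c("short", "long"), n_cells = cell_counts,
                               resample = seq_len(n_resample))
    grid$accuracy <- purrr::pmap_dbl(grid, function(pool, n_cells, resample) {
      units <- sample(n_units, n_cells)
      X <- t(pools[[pool]][units, , drop = FALSE])
      fit <- ridge_fit(X[train_idx, , drop = FALSE],
                       L[train_idx, , drop = FALSE], seed = resample)
      dec <- ridge_predict(fit, X[test_idx, , drop = FALSE])
      identify_nearest(dec, ref)
    })
    grid
  })
}

#' Categorization and discrimination time courses
#'
#' Population separation index per sliding window for category grouping
#' (face versus object: categorization) and identity grouping (individual
#' faces: discrimination). With stimulus-gated switching, discrimination
#' peaks later than categorization.
#'
#' @param pop A `response_tensor`.
#' @param windows Sliding-window grid.
#' @param cells Optional cell subset.
#' @param pop2 Optional independent noise replicate used to debias the
#'   identity curve (see [psi_timecourse()]).
#' @return Tibble: `window_start`, `window_end`, `grouping`, `psi`.
#' @export
categorization_discrimination_timecourse <- function(pop,
                                                     windows = sliding_windows(),
                                                     cells = NULL,
                                                     pop2 = NULL) {
  dplyr::bind_rows(
    psi_timecourse(pop, "category", windows, cells),
    psi_timecourse(pop, "identity", windows, cells, pop2 = pop2)
  )
}

#' Stimulus set with frozen low-dimensional face structure
#'
#' Knockout variant of [make_stimulus_set()]: the first `frozen_dims`
#' embedding dimensions of the faces are restricted to `n_vectors` discrete
#' prototype vectors (each repeated `n_face_per_vector` times), removing
#' low-dimensional identity information while leaving the high dimensions
#' intact. Used to show that late identity separation rides on
#' high-dimensional tuning.
#'
#' @param n_face_per_vector Faces per frozen prototype.
#' @param n_vectors Number of discrete prototypes.
#' @param frozen_dims Number of leading dimensions frozen.
#' @param n_object Number of object stimuli.
#' @param D,category_offset,sd_decay,seed As in [make_stimulus_set()].
#' @return A `stimulus_set`.
#' @export
make_knockout_stimulus_set <- function(n_face_per_vector = 400, n_vectors = 5,
                                       frozen_dims = 10, n_object = 400,
                                       D = 60, category_offset = NULL,
                                       sd_decay = 0.97, seed = 1) {
  ss <- make_stimulus_set(n_face_per_vector * n_vectors, n_object, D = D,
                          category_offset = category_offset,
                          sd_decay = sd_decay, seed = seed)
  with_seed(seed + 1L, {
    protos <- matrix(rnorm(n_vectors * frozen_dims), n_vectors)
    if (is.null(category_offset)) category_offset <- c(3, 1.5, rep(0, D - 2))
    protos <- sweep(protos, 2, category_offset[seq_len(frozen_dims)], "+")
    faces <- which(ss$category == "face")
    assign_v <- rep(seq_len(n_vectors), each = n_face_per_vector)
    ss$embeddings[faces, seq_len(frozen_dims)] <- protos[assign_v, , drop = FALSE]
  })
  ss
}
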