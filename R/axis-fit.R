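#' Per-category train/test split
#'
#' Random split of stimulus indices, stratified by category, defaulting to
#' 90/10 as in classic held-out-R-squared encoding-model evaluation.
#'
#' @param category Per-stimulus labels.
#' @param test_frac Fraction (per category) held out for testing.
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `test`.
#' @export
train_test_split <- function(category, test_frac = 0.1, seed = 1) {
  category <- as.character(category)
  with_seed(seed, {
    test <- integer(0)
    for (cat in unique(category)) {
      rows <- which(category == cat)
      n_test <- max(1L, round(test_frac * length(rows)))
      test <- c(test, sample(rows, n_test))
    }
    list(train = setdiff(seq_along(category), test), test = sort(test))
  })
}

#' Fit a cell's preferred encoding axis by linear regression
#'
#' Closed-form preferred-axis estimate `w = (r - rbar) F (F'F)^{-1}`,
#' computed by a numerically stable QR least-squares solve of the centred
#' responses on the (globally normalized) stimulus features. Predictions on
#' held-out stimuli use the training-set mean rate; the held-out R-squared is
#' `1 - SSE/SST` with SST taken about the test-set mean (0 when SST = 0), and
#' may be negative.
#'
#' @param responses Per-stimulus mean firing rates (length `nrow(F)`).
#' @param F stimuli x K normalized feature matrix.
#' @param train_idx,test_idx Disjoint integer indices into the stimulus rows.
#' @param window_ms Optional `[start, end)` window recorded on the fit.
#' @param cell_id,category Optional metadata recorded on the fit.
#' @return A `preferred_axis`: `weights` (K-vector, Hz per feature unit),
#'   `mean_rate`, `r2_train`, `r2_test`, `window_ms`, `category`, `cell_id`.
#' @export
fit_axis <- function(responses, F, train_idx, test_idx,
                     window_ms = NULL, cell_id = NA, category = NA) {
  fit <- fit_axes_matrix(matrix(responses, nrow = 1), F, train_idx, test_idx)
  structure(
    list(weights = fit$weights[1, ], mean_rate = fit$mean_rate[1],
         feature_center = fit$feature_center,
         r2_train = fit$r2_train[1], r2_test = fit$r2_test[1],
         window_ms = window_ms, category = category, cell_id = cell_id),
    class = "preferred_axis"
  )
}

#' @export
print.preferred_axis <- function(x, ...) {
  cat(sprintf("<preferred_axis> K = %d, |w| = %.3g Hz, R2 train %.3f / test %.3f\n",
              length(x$weights), sqrt(sum(x$weights^2)), x$r2_train, x$r2_test))
  invisible(x)
}

# Vectorized axis fit for a whole population: one QR factorization of the
# training features, all cells solved as a matrix right-hand side. Features
# are centred on the training subset (equivalent to fitting an intercept):
# the category subset of a globally normalized space has a nonzero feature
# mean, and without the intercept the centred-response formula is biased.
fit_axes_matrix <- function(R, F, train_idx, test_idx) {
  R <- as.matrix(R); F <- as.matrix(F)
  if (length(intersect(train_idx, test_idx)) > 0) abort("train/test overlap")
  Ft <- F[train_idx, , drop = FALSE]
  if (nrow(Ft) <= ncol(Ft)) abort("need more training stimuli than feature dimensions")
  fbar <- colMeans(Ft)
  Ftc <- sweep(Ft, 2, fbar)
  qrF <- qr(Ftc)
  if (qrF$rank < ncol(Ft)) {
    abort("F'F is singular: reduce K or enable ridge regularization")
  }
  rbar <- rowMeans(R[, train_idx, drop = FALSE])
  Yc <- t(R[, train_idx, drop = FALSE] - rbar)       # train_n x cells
  W <- qr.coef(qrF, Yc)                              # K x cells
  pred_tr <- Ftc %*% W + rep(rbar, each = nrow(Ftc))
  r2_tr <- r_squared_cols(t(R[, train_idx, drop = FALSE]), pred_tr)
  Fsc <- sweep(F[test_idx, , drop = FALSE], 2, fbar)
  pred_te <- Fsc %*% W + rep(rbar, each = nrow(Fsc))
  r2_te <- r_squared_cols(t(R[, test_idx, drop = FALSE]), pred_te)
  list(weights = t(W), mean_rate = rbar, feature_center = fbar,
       r2_train = r2_tr, r2_test = r2_te)
}

# single-cell closed-form axis on a stimulus subset (training-subset centred)
lsq_axis <- function(F, r, rows) {
  Fr <- sweep(F[rows, , drop = FALSE], 2, colMeans(F[rows, , drop = FALSE]))
  qr.coef(qr(Fr), r[rows] - mean(r[rows]))
}

# columnwise R^2 of predictions vs observations (matrices n x m)
r_squared_cols <- function(obs, pred) {
  sse <- colSums((obs - pred)^2)
  sst <- colSums(sweep(obs, 2, colMeans(obs))^2)
  ifelse(sst == 0, 0, 1 - sse / sst)
}

#' Fit face and object axes for every cell in a window
#'
#' Tidy population-level wrapper around [fit_axis()]: computes window-mean
#' rates, fits a face axis (on face stimuli) and an object axis (on object
#' stimuli) per cell with a shared stratified train/test split, and reports
#' cross-category prediction accuracy.
#'
#' @param pop A `response_tensor`.
#' @param F stimuli x K feature matrix (rows aligned with `pop` stimuli).
#' @param window `[start, end)` ms window over which rates are averaged.
#' @param split A [train_test_split()]; defaults to a 90/10 split at seed 1.
#' @param cross Also evaluate each axis on the other category's test set.
#' @return Tibble with one row per cell x category: `cell`, `category`,
#'   `weights` (list-column of K-vectors), `mean_rate`, `r2_train`,
#'   `r2_test`, and (if `cross`) `r2_cross`.
#' @export
fit_axes <- function(pop, F, window = c(50, 220),
                     split = train_test_split(pop$category), cross = TRUE) {
  R <- window_mean_rates(pop, window)
  out <- purrr::map_dfr(c("face", "object"), function(cat) {
    rows <- which(pop$category == cat)
    fit <- fit_axes_matrix(R[, rows, drop = FALSE], F[rows, , drop = FALSE],
                           match(intersect(split$train, rows), rows),
                           match(intersect(split$test, rows), rows))
    tibble::tibble(
      cell = pop$cell_ids, category = cat,
      weights = purrr::map(seq_len(nrow(fit$weights)), function(j) fit$weights[j, ]),
      mean_rate = fit$mean_rate,
      r2_train = fit$r2_train, r2_test = fit$r2_test
    )
  })
  if (cross) {
    other <- c(face = "object", object = "face")
    out$r2_cross <- NA_real_
    # evaluate each cell's axis on the other category's held-out stimuli
    for (cat in c("face", "object")) {
      rows_this <- which(out$category == cat)
      rows_o <- which(pop$category == other[[cat]])
      test_o <- intersect(split$test, rows_o)
      W <- do.call(rbind, out$weights[rows_this])
      rows_c <- which(pop$category == cat)
      fbar <- colMeans(F[intersect(split$train, rows_c), , drop = FALSE])
      pred <- sweep(F[test_o, , drop = FALSE], 2, fbar) %*% t(W) +
        rep(out$mean_rate[rows_this], each = length(test_o))
      out$r2_cross[rows_this] <- r_squared_cols(t(R[, test_o, drop = FALSE]), pred)
    }
  }
  out
}

#' Cross-category prediction accuracy of a fitted axis
#'
#' Evaluates an axis fit on one stimulus category against responses to the
#' named (typically other-category) test stimuli: R-squared of
#' `<weights, f> + mean_rate`. Can be strongly negative when the axis does
#' not generalize.
#'
#' @param axis A `preferred_axis`.
#' @param responses Per-stimulus rates aligned with `F` rows.
#' @param F Feature matrix from the same `feature_space` the axis was fit in.
#' @param test_idx Indices of the evaluation stimuli.
#' @return R-squared (scalar).
#' @export
cross_predict <- function(axis, responses, F, test_idx) {
  if (length(axis$weights) != ncol(F)) abort("axis/feature space mismatch")
  Fc <- sweep(F[test_idx, , drop = FALSE], 2, axis$feature_center)
  pred <- as.vector(Fc %*% axis$weights) + axis$mean_rate
  r_squared_cols(cbind(responses[test_idx]), cbind(pred))
}

#' Normalized face-object axis correlation of a cell
#'
#' Raw axis correlation (cosine similarity between the face and object axes)
#' divided by its split-half upper bound: the mean of face-half vs face-half
#' and object-half vs object-half axis correlations over `n_splits` random
#' disjoint halves. The bound accounts for estimation noise and
#' out-of-distribution generalization; a non-positive bound flags the cell as
#' too noisy to normalize (returns `NA`).
#'
#' @param responses Per-stimulus mean rates.
#' @param F stimuli x K feature matrix.
#' @param category Per-stimulus labels with levels face/object.
#' @param n_splits Number of resampled split halves averaged into the bound.
#' @param split_seed Integer seed for the halves.
#' @param method `"cosine"` (default) or `"pearson"` on the weight vectors.
#' @param cv_min Minimum cross-validated R-squared (both categories) for the
#'   cell to be considered normalizable.
#' @return List with `raw`, `upper_bound`, `cv_face`, `cv_object`, and
#'   `normalized` (NA when the bound is not reliably positive or the tuning
#'   does not cross-validate).
#' @export
normalized_fo_correlation <- function(responses, F, category, n_splits = 20,
                                      split_seed = 1, method = c("cosine", "pearson"),
                                      cv_min = 0) {
  method <- match.arg(method)
  category <- as.character(category)
  simfun <- if (method == "cosine") cosine_sim else function(a, b) cor(a, b)
  axis_on <- function(rows) lsq_axis(F, responses, rows)
  faces <- which(category == "face"); objs <- which(category == "object")
  if (length(faces) < 4 || length(objs) < 4) abort("need >= 4 stimuli per category")
  raw <- simfun(axis_on(faces), axis_on(objs))
  # cross-validated predictive R^2 per category: a cell whose tuning does not
  # generalize across stimuli cannot be normalized (its split-half bound
  # reflects a frozen noise pattern, not reliable tuning)
  cv_r2 <- function(rows, k = 5) {
    folds <- split(sample(rows), rep_len(seq_len(k), length(rows)))
    sse <- 0
    for (f in folds) {
      tr <- setdiff(rows, f)
      w <- lsq_axis(F, responses, tr)
      pred <- mean(responses[tr]) +
        as.vector(sweep(F[f, , drop = FALSE], 2,
                        colMeans(F[tr, , drop = FALSE])) %*% w)
      sse <- sse + sum((responses[f] - pred)^2)
    }
    1 - sse / sum((responses[rows] - mean(responses[rows]))^2)
  }
  halves <- function(rows) {
    h1 <- sample(rows, floor(length(rows) / 2))
    list(h1, setdiff(rows, h1))
  }
  res <- with_seed(split_seed, {
    vals <- vapply(seq_len(n_splits), function(s) {
      hf <- halves(faces); ho <- halves(objs)
      mean(c(simfun(axis_on(hf[[1]]), axis_on(hf[[2]])),
             simfun(axis_on(ho[[1]]), axis_on(ho[[2]]))))
    }, numeric(1))
    list(vals = vals, cv_face = cv_r2(faces), cv_object = cv_r2(objs))
  })
  ub <- mean(res$vals)
  se <- sd(res$vals) / sqrt(n_splits)
  usable <- is.finite(ub) && ub > 2 * se &&
    res$cv_face > cv_min && res$cv_object > cv_min
  list(raw = raw, upper_bound = ub,
       cv_face = res$cv_face, cv_object = res$cv_object,
       normalized = if (usable) raw / ub else NA_real_)
}

#' Run the axis pipeline on exactly linear artificial units
#'
#' Constructs `n_units` units that are exact (optionally noisy) linear
#' functionals of the stimulus features and pushes them through the full
#' face/object axis analysis. Because a linear unit has a single encoding
#' axis by construction, its face and object axes must agree: the control
#' that separates genuinely distinct axes from out-of-distribution
#' generalization failure.
#'
#' @param F stimuli x K feature matrix.
#' @param category Per-stimulus labels.
#' @param n_units Number of artificial units.
#' @param noise_sd S.d. of additive Gaussian response noise (0 = noiseless).
#' @param selectivity `"face"` biases unit weights toward the first two
#'   feature dimensions (where faces sit), mimicking face-selective deep-net
#'   units; `"none"` draws isotropic weights.
#' @param split Train/test split used throughout.
#' @param n_splits,seed Passed to [normalized_fo_correlation()] / RNG.
#' @return Tibble per unit: within-category `r2_face`, `r2_object`, cross
#'   R-squared both ways, and the normalized face-object axis correlation.
#' @export
artificial_unit_control <- function(F, category, n_units = 50, noise_sd = 0,
                                    selectivity = c("face", "none"),
                                    split = train_test_split(category),
                                    n_splits = 20, seed = 1) {
  selectivity <- match.arg(selectivity)
  K <- ncol(F)
  category <- as.character(category)
  with_seed(seed, {
    W <- matrix(rnorm(n_units * K), n_units, K)
    if (selectivity == "face") {
      W[, 1:2] <- abs(W[, 1:2]) + 1  # positive loading on the face quadrant
    }
    R <- W %*% t(F)                  # units x stimuli
    if (noise_sd > 0) R <- R + matrix(rnorm(length(R), sd = noise_sd), nrow(R))
    purrr::map_dfr(seq_len(n_units), function(u) {
      r <- R[u, ]
      res <- purrr::map(c("face", "object"), function(cat) {
        rows <- which(category == cat)
        fit_axis(r[rows], F[rows, , drop = FALSE],
                 match(intersect(split$train, rows), rows),
                 match(intersect(split$test, rows), rows),
                 category = cat, cell_id = u)
      })
      names(res) <- c("face", "object")
      cr_fo <- cross_predict(res$face, r, F,
                             intersect(split$test, which(category == "object")))
      cr_of <- cross_predict(res$object, r, F,
                             intersect(split$test, which(category == "face")))
      nfo <- normalized_fo_correlation(r, F, category, n_splits = n_splits,
                                       split_seed = seed + u)
      tibble::tibble(
        unit = u, r2_face = res$face$r2_test, r2_object = res$object$r2_test,
        r2_face_on_object = cr_fo, r2_object_on_face = cr_of,
        fo_raw = nfo$raw, fo_upper = nfo$upper_bound, fo_normalized = nfo$normalized
      )
    })
  })
}

#' Most-effective non-face and least-effective face stimulus subsets
#'
#' Ranks stimuli by population-mean response in a window and returns the `k`
#' most-effective non-face stimuli, the `k` least-effective face stimuli, and
#' the ratio of their mean responses. When the ratio exceeds 1, the non-face
#' subset drives the population harder than the face subset — the premise of
#' the response-magnitude control (axis change must then track face content,
#' not drive).
#'
#' @param pop A `response_tensor`.
#' @param k Subset size per category.
#' @param window Averaging window in ms.
#' @return List: `top_object_ids`, `bottom_face_ids`, `response_ratio`, and
#'   `by_stimulus` (tibble of the population-mean responses).
#' @export
effectiveness_subsets <- function(pop, k = 100, window = c(50, 220)) {
  if (k < 1) abort("k must be >= 1")
  R <- window_mean_rates(pop, window)
  m <- colMeans(R)
  faces <- which(pop$category == "face"); objs <- which(pop$category == "object")
  if (k > length(faces) || k > length(objs)) abort("k exceeds a category size")
  top_obj <- objs[order(m[objs], decreasing = TRUE)][seq_len(k)]
  bot_face <- faces[order(m[faces])][seq_len(k)]
  list(
    top_object_ids = pop$ids[top_obj],
    bottom_face_ids = pop$ids[bot_face],
    response_ratio = mean(m[top_obj]) / mean(m[bot_face]),
    by_stimulus = tibble::tibble(id = pop$ids, category = as.character(pop$category),
                                 mean_rate = m)
  )
}
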