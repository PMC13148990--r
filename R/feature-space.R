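#' Fit a normalized K-dimensional PCA feature space
#'
#' Performs PCA on an embedding matrix (e.g. deep-network activations of the
#' stimulus images) and keeps the first `K` components. Each retained
#' dimension is normalized so that the projections of the fitting stimuli
#' have mean 0 and s.d. 1. Component signs are fixed by forcing the
#' largest-magnitude loading of each component positive, which makes the fit
#' fully deterministic.
#'
#' @param embeddings stimuli x D numeric matrix.
#' @param K Number of feature dimensions to keep (2 <= K <= rank).
#' @param fit_ids Optional ids recording which stimuli the space was fit on.
#' @return A `feature_space`: `mean` (D-vector), `components` (D x K,
#'   orthonormal columns), `scale` (K-vector of per-dimension s.d.
#'   normalizers), `explained_variance_ratio` (K-vector, non-increasing, as a
#'   fraction of total embedding variance) and `fit_ids`.
#' @export
fit_feature_space <- function(embeddings, K = 60, fit_ids = rownames(embeddings)) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (n <= K) abort("need more stimuli than feature dimensions K")
  if (K < 1) abort("K must be >= 1")
  pc <- prcomp(embeddings, center = TRUE, scale. = FALSE)
  tot_var <- sum(pc$sdev^2)
  rank_tol <- max(pc$sdev) * 1e-10
  attainable <- sum(pc$sdev > rank_tol)
  if (attainable < K) {
    abort(sprintf("embedding rank %d < requested K = %d; use K <= %d",
                  attainable, K, attainable))
  }
  comps <- pc$rotation[, seq_len(K), drop = FALSE]
  # deterministic sign: largest-magnitude loading of each component positive
  flip <- vapply(seq_len(K), function(k) {
    v <- comps[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  comps <- sweep(comps, 2, flip, "*")
  scores <- sweep(embeddings, 2, pc$center) %*% comps
  scl <- apply(scores, 2, sd)
  structure(
    list(mean = pc$center, components = comps, scale = scl,
         explained_variance_ratio = pc$sdev[seq_len(K)]^2 / tot_var,
         fit_ids = fit_ids),
    class = "feature_space"
  )
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("<feature_space> D = %d -> K = %d; first PCs explain %s of variance\n",
              nrow(x$components), ncol(x$components),
              paste(sprintf("%.1f%%", 100 * head(x$explained_variance_ratio, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname fit_feature_space
#' @param x A `feature_space`.
#' @param ... Unused.
#' @method tidy feature_space
#' @export
tidy.feature_space <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$scale),
    explained_variance_ratio = x$explained_variance_ratio,
    scale = x$scale
  )
}

#' @rdname fit_feature_space
#' @method glance feature_space
#' @export
glance.feature_space <- function(x, ...) {
  tibble::tibble(
    D = nrow(x$components), K = ncol(x$components),
    total_variance_explained = sum(x$explained_variance_ratio)
  )
}

#' Project embeddings into a fitted feature space
#'
#' Applies the space's centering, rotation and per-dimension normalization:
#' `F = ((embeddings - mean) %*% components) / scale`, row-wise. Held-out
#' stimuli are projected with the fitting set's mean and scale (no refit).
#'
#' @param space A `feature_space`.
#' @param embeddings stimuli x D matrix (D must match the space).
#' @param ids Optional stimulus ids used as row names.
#' @return stimuli x K matrix of normalized features.
#' @export
project_features <- function(space, embeddings, ids = rownames(embeddings)) {
  embeddings <- as.matrix(embeddings)
  if (ncol(embeddings) != nrow(space$components)) {
    abort("embedding dimension does not match the feature space")
  }
  F_ <- sweep(sweep(embeddings, 2, space$mean) %*% space$components,
              2, space$scale, "/")
  rownames(F_) <- ids
  F_
}

#' Highest-density stimulus subsets under per-category Gaussian fits
#'
#' Fits a maximum-likelihood multivariate Gaussian to each category's feature
#' rows and returns, per category, the `n_keep` stimuli with the highest
#' probability density under their own category's fit. Used to control for
#' the shape of the stimulus distribution: the retained subsets are
#' approximately Gaussian-distributed.
#'
#' @param F stimuli x K feature matrix.
#' @param category Per-stimulus labels (length `nrow(F)`).
#' @param n_keep Number of stimuli to keep per category.
#' @param ids Stimulus ids; defaults to row names or indices.
#' @param reg Ridge added to a singular covariance, as a fraction of its mean
#'   diagonal.
#' @return Tibble with `id`, `category`, `log_density`, `kept`.
#' @export
gaussian_subset <- function(F, category, n_keep, ids = rownames(F), reg = 1e-8) {
  F <- as.matrix(F)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(F)))
  category <- as.character(category)
  out <- purrr::map_dfr(unique(category), function(cat) {
    rows <- which(category == cat)
    if (length(rows) < n_keep) abort(sprintf("category '%s' has < n_keep stimuli", cat))
    X <- F[rows, , drop = FALSE]
    mu <- colMeans(X)
    S <- crossprod(sweep(X, 2, mu)) / nrow(X)  # ML covariance
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) {
      S <- S + diag(reg * mean(diag(S)) + 1e-12, ncol(S))
      ch <- tryCatch(chol(S), error = function(e)
        abort(sprintf("covariance of category '%s' singular after regularization", cat)))
    }
    z <- backsolve(ch, t(sweep(X, 2, mu)), transpose = TRUE)
    maha <- colSums(z^2)
    logdet <- 2 * sum(log(diag(ch)))
    ld <- -0.5 * (maha + logdet + ncol(X) * log(2 * pi))
    keep_rank <- rank(-ld, ties.method = "first")
    tibble::tibble(id = ids[rows], category = cat, log_density = ld,
                   kept = keep_rank <= n_keep)
  })
  out
}
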