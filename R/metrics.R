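#' Face-selectivity d-prime time course and summary selectivity
#'
#' For one cell, the selectivity at each 1-ms bin is the standardized mean
#' difference between face and object responses,
#' `d'_t = (E(r_face,t) - E(r_object,t)) / sqrt((var_face,t + var_object,t)/2)`.
#' The peak d-prime is the maximum 20-ms-window mean of `d'_t` with the
#' window start sliding over 80-120 ms (so windows cover 80-140 ms). When
#' both variances vanish, `d'` is 0 for equal means and clipped to +/-10
#' otherwise.
#'
#' @param pop A `response_tensor`.
#' @param cell Cell index.
#' @return Tibble: `time_ms`, `dprime`.
#' @export
dprime_timecourse <- function(pop, cell) {
  faces <- pop$category == "face"; objs <- pop$category == "object"
  if (sum(faces) < 2 || sum(objs) < 2) abort("need >= 2 stimuli per category")
  Rf <- pop$rates[cell, faces, , drop = FALSE][1, , ]
  Ro <- pop$rates[cell, objs, , drop = FALSE][1, , ]
  mf <- colMeans(Rf); mo <- colMeans(Ro)
  vf <- apply(Rf, 2, var); vo <- apply(Ro, 2, var)
  denom <- sqrt((vf + vo) / 2)
  d <- ifelse(denom > 0, (mf - mo) / denom,
              ifelse(mf == mo, 0, sign(mf - mo) * 10))
  tibble::tibble(time_ms = pop$time_ms, dprime = d)
}

#' @rdname dprime_timecourse
#' @param dp Result of `dprime_timecourse()`.
#' @param peak_range Window-start range (ms) scanned for the peak.
#' @param width_ms Averaging window width.
#' @export
peak_dprime <- function(dp, peak_range = c(80, 120), width_ms = 20) {
  starts <- seq(peak_range[1], peak_range[2], by = 1)
  max(vapply(starts, function(s) {
    mean(dp$dprime[dp$time_ms >= s & dp$time_ms < s + width_ms])
  }, numeric(1)))
}

#' Face selectivity index of a cell
#'
#' `FSI = (r_face - r_nonface) / (r_face + r_nonface)` using mean rates in a
#' 50-220 ms window; lies in `[-1, 1]` for non-negative rates.
#'
#' @param pop A `response_tensor`.
#' @param cell Cell index.
#' @param window Averaging window in ms.
#' @export
face_selectivity_index <- function(pop, cell, window = c(50, 220)) {
  R <- window_mean_rates(pop, window)
  rf <- mean(R[cell, pop$category == "face"])
  ro <- mean(R[cell, pop$category == "object"])
  if (rf + ro == 0) return(NA_real_)
  (rf - ro) / (rf + ro)
}

#' Visual responsiveness test
#'
#' Two-sided Student's t-test comparing a cell's activity in the baseline
#' window (-50 to 0 ms) with the response window (50-300 ms), paired across
#' stimuli (both windows come from the same trials). Cells with p < 0.05 are
#' considered visually responsive.
#'
#' @param pop A `response_tensor`.
#' @param cell Cell index.
#' @param baseline,response The two compared windows in ms.
#' @param paired Pair the windows across stimuli (default) or not.
#' @return Two-sided p-value. Degenerate zero-variance cases return 1 when
#'   the window means are identical and 0 when they differ deterministically.
#' @export
responsiveness_test <- function(pop, cell, baseline = c(-50, 0),
                                response = c(50, 300), paired = TRUE) {
  b <- window_mean_rates(pop, baseline)[cell, ]
  r <- window_mean_rates(pop, response)[cell, ]
  if (paired) {
    d <- r - b
    if (sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
    return(t.test(d)$p.value)
  }
  if (sd(b) == 0 && sd(r) == 0) return(if (mean(b) == mean(r)) 1 else 0)
  t.test(r, b)$p.value
}

#' Per-cell selectivity and inclusion metrics
#'
#' Computes, for every cell, the metrics the inclusion rules operate on:
#' peak d-prime, FSI, responsiveness p-value, response variance across
#' stimuli, and the 50-220 ms mean rate.
#'
#' @param pop A `response_tensor`.
#' @return Tibble with one row per cell.
#' @export
cell_selectivity <- function(pop) {
  R <- window_mean_rates(pop, c(50, 220))
  purrr::map_dfr(seq_len(dim(pop$rates)[1]), function(j) {
    tibble::tibble(
      cell = pop$cell_ids[j],
      peak_dprime = peak_dprime(dprime_timecourse(pop, j)),
      fsi = face_selectivity_index(pop, j),
      responsive_p = responsiveness_test(pop, j),
      response_var = var(R[j, ]),
      mean_rate = mean(R[j, ])
    )
  })
}

#' Modified Treves-Rolls population sparseness
#'
#' `S = 1 - (sum r)^2 / (N sum r^2)` across the `N` cells' responses to one
#' stimulus at one time: 0 for uniform activity, `1 - 1/N` for one-hot
#' activity, `NA` for an all-zero population vector.
#'
#' @param r Non-negative rate vector across cells.
#' @export
population_sparseness <- function(r) {
  ss <- sum(r^2)
  if (ss == 0) return(NA_real_)
  1 - sum(r)^2 / (length(r) * ss)
}

#' @rdname population_sparseness
#' @param pop A `response_tensor`.
#' @param cells Optional integer subset of cells.
#' @param smooth_ms Optional boxcar smoothing (ms) of each cell's rates
#'   before the sparseness computation. At low rates and few trial repeats
#'   the 1-ms bins are dominated by spike-count shot noise, which saturates
#'   the statistic; a 20-ms boxcar recovers the rate-level structure.
#' @return For `sparseness_timecourse()`: a tibble `id`, `category`,
#'   `time_ms`, `sparseness` (per stimulus and 1-ms bin).
#' @export
sparseness_timecourse <- function(pop, cells = NULL, smooth_ms = 0) {
  if (is.null(cells)) cells <- seq_len(dim(pop$rates)[1])
  N <- length(cells)
  rt <- pop$rates[cells, , , drop = FALSE]
  if (smooth_ms > 1) {
    kern <- rep(1 / smooth_ms, smooth_ms)
    d <- dim(rt)
    flat <- matrix(aperm(rt, c(3, 1, 2)), d[3])   # time x (cells*stimuli)
    flat <- stats::filter(flat, kern, sides = 2, circular = FALSE)
    # edge bins without full kernel support stay NA
    rt <- aperm(array(as.numeric(flat), c(d[3], d[1], d[2])), c(2, 3, 1))
  }
  s1 <- colSums(rt)                      # stimuli x T: sum of rates
  s2 <- colSums(rt^2)                    # stimuli x T: sum of squares
  S <- ifelse(s2 == 0, NA_real_, 1 - s1^2 / (N * s2))
  tibble::tibble(
    id = rep(pop$ids, length(pop$time_ms)),
    category = rep(as.character(pop$category), length(pop$time_ms)),
    time_ms = rep(pop$time_ms, each = length(pop$ids)),
    sparseness = as.vector(S)
  )
}

#' Population separation index
#'
#' Mean pairwise Euclidean distance between group-mean population vectors,
#' divided by the pooled s.d. of responses across units and items in the
#' window. Unitless, invariant to rescaling and to adding a constant to all
#' rates.
#'
#' @param R cells x items matrix of window-mean rates.
#' @param grouping Per-item group labels (categories, or identities with one
#'   item per group).
#' @return PSI (scalar).
#' @export
psi_index <- function(R, grouping) {
  grouping <- as.character(grouping)
  groups <- unique(grouping)
  if (length(groups) < 2) abort("need >= 2 groups")
  M <- vapply(groups, function(g) rowMeans(R[, grouping == g, drop = FALSE]),
              numeric(nrow(R)))
  dists <- as.vector(dist(t(M)))
  sigma <- sd(as.vector(R))
  if (sigma == 0) abort("pooled response s.d. is zero")
  mean(dists) / sigma
}

#' @rdname psi_index
#' @param pop A `response_tensor`.
#' @param grouping `"category"` (face vs object separation) or `"identity"`
#'   (each face stimulus its own group; restricted to face stimuli).
#' @param windows Window matrix from [sliding_windows()].
#' @param cells Optional integer subset of cells.
#' @param pop2 Optional independent replicate of `pop` (same truth, different
#'   noise seed). With single-item identity groups the plain distance/s.d.
#'   ratio is pinned near `sqrt(2 N)` by trial noise; when a replicate is
#'   supplied, squared distances are estimated by the cross-replicate inner
#'   product `<r1_i - r1_j, r2_i - r2_j>` (unbiased for the signal
#'   distance), so the identity curve starts near 0 and tracks genuine
#'   identity separation.
#' @return For `psi_timecourse()`: tibble `window_start`, `window_end`,
#'   `grouping`, `psi`.
#' @export
psi_timecourse <- function(pop, grouping = c("category", "identity"),
                           windows = sliding_windows(), cells = NULL,
                           pop2 = NULL) {
  grouping <- match.arg(grouping)
  if (is.null(cells)) cells <- seq_len(dim(pop$rates)[1])
  items <- if (grouping == "identity") which(pop$category == "face")
           else seq_along(pop$ids)
  labels <- if (grouping == "identity") pop$ids[items]
            else as.character(pop$category)
  purrr::map_dfr(seq_len(nrow(windows)), function(w) {
    R <- window_mean_rates(pop, windows[w, ])[cells, items, drop = FALSE]
    psi <- if (is.null(pop2)) {
      psi_index(R, labels)
    } else {
      R2 <- window_mean_rates(pop2, windows[w, ])[cells, items, drop = FALSE]
      psi_index_debiased(R, R2)
    }
    tibble::tibble(window_start = windows[w, 1], window_end = windows[w, 2],
                   grouping = grouping, psi = psi)
  })
}

# cross-validated PSI for single-item groups: squared pairwise distances from
# the cross-replicate inner product (noise cancels in expectation), pooled
# s.d. from the replicate-averaged responses
psi_index_debiased <- function(R1, R2) {
  M <- crossprod(R1, R2)                     # items x items
  dg <- diag(M)
  D2 <- outer(dg, dg, "+") - M - t(M)        # <d1_ij, d2_ij>
  md2 <- mean(D2[upper.tri(D2)])
  sigma <- sd(as.vector((R1 + R2) / 2))
  if (sigma == 0) abort("pooled response s.d. is zero")
  sqrt(max(md2, 0)) / sigma
}

#' Dimensionality needed to explain a variance fraction, early vs late
#'
#' PCA on the z-scored cells x stimuli response matrix of each window; the
#' dimensionality is the smallest number of PCs whose cumulative explained
#' variance reaches `q`. Bootstrap resampling of stimuli (shared across
#' windows within each bootstrap sample) gives an s.d. and a paired
#' comparison between the two windows.
#'
#' @param pop A `response_tensor`.
#' @param windows Named list of two `[start, end)` windows (default short
#'   80-100 ms, long 120-140 ms).
#' @param q Variance fraction (default 0.90).
#' @param n_boot Bootstrap samples.
#' @param category Stimulus category analysed (faces, per the emergent-tuning
#'   question).
#' @param cells Optional cell subset.
#' @param seed Integer seed for the bootstrap.
#' @return List: `summary` (tibble per window: `n_dims`, `boot_sd`),
#'   `paired_t` (t-test of long - short across bootstraps), and
#'   `frac_long_gt_short` (fraction of bootstrap pairs with more late
#'   dimensions).
#' @export
dims_for_variance <- function(pop, windows = list(short = c(80, 100),
                                                  long = c(120, 140)),
                              q = 0.90, n_boot = 100, category = "face",
                              cells = NULL, seed = 1) {
  stopifnot(length(windows) == 2)
  if (is.null(cells)) cells <- seq_len(dim(pop$rates)[1])
  items <- which(pop$category == category)
  mats <- purrr::map(windows, function(w) {
    R <- window_mean_rates(pop, w)[cells, items, drop = FALSE]
    sds <- apply(R, 1, sd)
    keep <- sds > 0
    if (!any(keep)) abort("window has no response variance")
    (R[keep, , drop = FALSE] - rowMeans(R[keep, , drop = FALSE])) / sds[keep]
  })
  ndims <- function(X) {
    # PCA with stimuli as observations: re-center each cell across the
    # (possibly resampled) stimuli, then take the singular spectrum
    ev <- svd(X - rowMeans(X), nu = 0, nv = 0)$d^2
    which(cumsum(ev) / sum(ev) >= q)[1]
  }
  point <- vapply(mats, ndims, numeric(1))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample(length(items), replace = TRUE)
      vapply(mats, function(X) ndims(X[, idx, drop = FALSE]), numeric(1))
    }, numeric(2))
  })
  diffs <- boot[2, ] - boot[1, ]
  list(
    summary = tibble::tibble(
      window = names(windows), n_dims = unname(point),
      boot_mean = rowMeans(boot), boot_sd = apply(boot, 1, sd)),
    paired_t = t.test(diffs),
    frac_long_gt_short = mean(diffs > 0)
  )
}

#' Response-PC pseudo-units and their extreme stimuli over time
#'
#' PCA on the time-averaged population response matrix yields PCs in cell
#' space; the first `n_pcs` PC projections are treated as pseudo-unit
#' responses. For each pseudo-unit, face and object axes are fit per sliding
#' window and the top/bottom `k_extremes` stimuli by feature projection onto
#' the axis are reported.
#'
#' @param pop A `response_tensor`.
#' @param F Feature matrix for all stimuli.
#' @param k_extremes Number of extreme stimuli per end.
#' @param windows Sliding-window grid.
#' @param n_pcs Number of response PCs kept as pseudo-units.
#' @param avg_window Window for the time-averaged PCA.
#' @param split Train/test split for the axis fits.
#' @return Tibble: `pc`, `window_start`, `category`, `r2_test`, `top_ids`,
#'   `bottom_ids` (list-columns); attribute `degenerate` flags PCs with
#'   near-zero variance.
#' @export
response_pc_pseudo_units <- function(pop, F, k_extremes = 5,
                                     windows = sliding_windows(), n_pcs = 2,
                                     avg_window = c(50, 220),
                                     split = train_test_split(pop$category)) {
  if (dim(pop$rates)[1] < 2) abort("need >= 2 cells")
  X <- t(window_mean_rates(pop, avg_window))      # stimuli x cells
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  degenerate <- pc$sdev[seq_len(n_pcs)] < 1e-8 * pc$sdev[1]
  loadings <- pc$rotation[, seq_len(n_pcs), drop = FALSE]
  out <- purrr::map_dfr(seq_len(n_pcs), function(p) {
    purrr::map_dfr(seq_len(nrow(windows)), function(w) {
      Rw <- window_mean_rates(pop, windows[w, ])    # cells x stimuli
      pseudo <- as.vector(crossprod(loadings[, p], Rw))
      purrr::map_dfr(c("face", "object"), function(cat) {
        rows <- which(pop$category == cat)
        fit <- fit_axis(pseudo[rows], F[rows, , drop = FALSE],
                        match(intersect(split$train, rows), rows),
                        match(intersect(split$test, rows), rows))
        proj <- as.vector(F[rows, , drop = FALSE] %*% fit$weights)
        ord <- order(proj, decreasing = TRUE)
        k <- min(k_extremes, length(rows))
        tibble::tibble(
          pc = p, window_start = windows[w, 1], category = cat,
          r2_test = fit$r2_test,
          top_ids = list(pop$ids[rows][ord[seq_len(k)]]),
          bottom_ids = list(pop$ids[rows][rev(ord)[seq_len(k)]])
        )
      })
    })
  })
  attr(out, "degenerate") <- degenerate
  out
}

#' Single-stimulus axis-change score
#'
#' For each stimulus, the Pearson correlation between the raw (unnormalized)
#' population response vectors at an early (60-80 ms) and a late (100-120 ms)
#' window across included cells; extreme-firing-rate cells (50-220 ms mean
#' rate outside the population's 1st-99th percentile) are excluded first. A
#' single-feature logistic regression, trained on a stratified split of the
#' face/object labels with inverse-frequency class weights, maps the
#' correlation to a probability of "faceness" — the axis-change score. More
#' negative early-late correlation (a reversed population pattern) gives a
#' higher score.
#'
#' @param pop A `response_tensor`.
#' @param early,late The two compared windows in ms.
#' @param exclude_quantiles Rate percentiles outside which cells are excluded.
#' @param train_frac Fraction of stimuli (stratified) used to fit the
#'   classifier; all stimuli are scored.
#' @param seed Integer seed for the split.
#' @return An `axis_change_score`: `scores` tibble (`id`, `category`,
#'   `early_late_corr`, `score`, `is_train`), `coefficients`
#'   (intercept/slope), `included_cells`.
#' @export
axis_change_score <- function(pop, early = c(60, 80), late = c(100, 120),
                              exclude_quantiles = c(0.01, 0.99),
                              train_frac = 0.5, seed = 1) {
  rate <- rowMeans(window_mean_rates(pop, c(50, 220)))
  qs <- quantile(rate, exclude_quantiles)
  cells <- which(rate >= qs[1] & rate <= qs[2])
  if (length(cells) < 3) abort("fewer than 3 cells after the rate exclusion")
  Re <- window_mean_rates(pop, early)[cells, , drop = FALSE]
  Rl <- window_mean_rates(pop, late)[cells, , drop = FALSE]
  rho <- vapply(seq_along(pop$ids), function(i) {
    suppressWarnings(cor(Re[, i], Rl[, i]))
  }, numeric(1))
  y <- as.integer(pop$category == "face")
  is_train <- rep(FALSE, length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      rows <- which(y == cls & !is.na(rho))
      is_train[sample(rows, max(1, round(train_frac * length(rows))))] <- TRUE
    }
  })
  wts <- ifelse(y == 1, 1 / sum(y[is_train] == 1), 1 / sum(y[is_train] == 0))
  dat <- data.frame(y = y, rho = rho, w = wts)
  fit <- suppressWarnings(
    glm(y ~ rho, family = binomial(), data = dat[is_train, ],
        weights = dat$w[is_train])
  )
  score <- as.numeric(predict(fit, newdata = dat, type = "response"))
  structure(
    list(
      scores = tibble::tibble(
        id = pop$ids, category = as.character(pop$category),
        early_late_corr = rho, score = score, is_train = is_train),
      coefficients = coef(fit),
      included_cells = pop$cell_ids[cells]),
    class = "axis_change_score"
  )
}

#' @export
print.axis_change_score <- function(x, ...) {
  cat(sprintf("<axis_change_score> %d stimuli, slope = %.3f (negative slope => reversed pattern scores 'face')\n",
              nrow(x$scores), x$coefficients[["rho"]]))
  invisible(x)
}

#' @rdname axis_change_score
#' @param x An `axis_change_score`.
#' @param ... Unused.
#' @method tidy axis_change_score
#' @export
tidy.axis_change_score <- function(x, ...) x$scores
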