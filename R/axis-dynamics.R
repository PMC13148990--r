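#' Sliding-window grid
#'
#' Half-open, equal-width windows `[start, start + width)` stepping through
#' the trial, by default non-overlapping 20-ms bins over 0-300 ms.
#'
#' @param start_ms,end_ms Range covered.
#' @param width_ms Window width.
#' @param step_ms Step between window starts.
#' @return Two-column matrix (`start`, `end`), one row per window.
#' @export
sliding_windows <- function(start_ms = 0, end_ms = 300, width_ms = 20,
                            step_ms = width_ms) {
  starts <- seq(start_ms, end_ms - width_ms, by = step_ms)
  cbind(start = starts, end = starts + width_ms)
}

#' Time-resolved preferred axes on a sliding-window grid
#'
#' For every window, averages each cell's rates per stimulus and fits a
#' preferred axis on the stimuli of one category, with a single train/test
#' split held fixed across windows so that axes at different latencies are
#' directly comparable.
#'
#' @param pop A `response_tensor`.
#' @param F stimuli x K feature matrix (all stimuli; the category subset is
#'   taken internally).
#' @param category `"face"` or `"object"`: the stimuli the axes are fit on.
#' @param windows Window matrix from [sliding_windows()].
#' @param split Stratified [train_test_split()] over all stimuli.
#' @return An `axis_timecourse`: `windows`, `axes` (windows x cells x K
#'   array), `mean_rate`, `r2_train`, `r2_test` (windows x cells matrices),
#'   `category`, `cell_ids`.
#' @export
sliding_axes <- function(pop, F, category = "face",
                         windows = sliding_windows(),
                         split = train_test_split(pop$category)) {
  rows <- which(pop$category == category)
  if (length(rows) == 0) abort("no stimuli of the requested category")
  tr <- match(intersect(split$train, rows), rows)
  te <- match(intersect(split$test, rows), rows)
  Fc <- F[rows, , drop = FALSE]
  n_w <- nrow(windows); n_c <- dim(pop$rates)[1]; K <- ncol(F)
  axes <- array(NA_real_, c(n_w, n_c, K))
  mr <- r2tr <- r2te <- matrix(NA_real_, n_w, n_c)
  for (w in seq_len(n_w)) {
    R <- window_mean_rates(pop, windows[w, ])[, rows, drop = FALSE]
    fit <- fit_axes_matrix(R, Fc, tr, te)
    axes[w, , ] <- fit$weights
    mr[w, ] <- fit$mean_rate; r2tr[w, ] <- fit$r2_train; r2te[w, ] <- fit$r2_test
  }
  structure(
    list(windows = windows, axes = axes, mean_rate = mr,
         r2_train = r2tr, r2_test = r2te, category = category,
         cell_ids = pop$cell_ids),
    class = "axis_timecourse"
  )
}

#' @export
print.axis_timecourse <- function(x, ...) {
  cat(sprintf("<axis_timecourse> %s axes: %d windows x %d cells x K = %d\n",
              x$category, nrow(x$windows), length(x$cell_ids), dim(x$axes)[3]))
  invisible(x)
}

#' @rdname sliding_axes
#' @param x An `axis_timecourse`.
#' @param ... Unused.
#' @method tidy axis_timecourse
#' @export
tidy.axis_timecourse <- function(x, ...) {
  n_w <- nrow(x$windows); n_c <- length(x$cell_ids)
  tibble::tibble(
    window_start = rep(x$windows[, 1], n_c),
    window_end = rep(x$windows[, 2], n_c),
    cell = rep(x$cell_ids, each = n_w),
    category = x$category,
    mean_rate = as.vector(x$mean_rate),
    r2_train = as.vector(x$r2_train),
    r2_test = as.vector(x$r2_test)
  )
}

window_index <- function(tc, window) {
  w <- which(tc$windows[, 1] == window[1] & tc$windows[, 2] == window[2])
  if (length(w) != 1) abort("window not on the timecourse grid")
  w
}

# mean cosine across cells between axes at window a of tc1 and window b of tc2
mean_window_cosine <- function(tc1, tc2, a, b, cells) {
  v <- vapply(cells, function(j) cosine_sim(tc1$axes[a, j, ], tc2$axes[b, j, ]),
              numeric(1))
  c(mean = mean(v, na.rm = TRUE),
    sem = sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
}

#' Window-by-window axis similarity matrices
#'
#' Mean cosine similarity across cells between axes at every pair of
#' latencies, for (object, object), (face, face) and (face, object) axis
#' pairs. The diagonal of the (face, object) matrix is the face-object
#' alignment time course: transiently positive while the face axis rides the
#' detection direction, negative after the switch.
#'
#' @param tc_face,tc_obj Face and object `axis_timecourse`s on the same grid.
#' @param cells Optional integer subset of cells to include (e.g. after the
#'   R-squared inclusion rule).
#' @return An `axis_similarity`: matrices `object_object`, `face_face`,
#'   `face_object` (windows x windows), `windows`, and `alignment` (tibble of
#'   the face-object diagonal with s.e.m.).
#' @export
similarity_matrices <- function(tc_face, tc_obj, cells = NULL) {
  if (!isTRUE(all.equal(tc_face$windows, tc_obj$windows))) {
    abort("face and object timecourses use different window grids")
  }
  n_w <- nrow(tc_face$windows)
  if (is.null(cells)) cells <- seq_along(tc_face$cell_ids)
  oo <- ff <- fo <- matrix(NA_real_, n_w, n_w)
  fo_sem <- numeric(n_w)
  for (a in seq_len(n_w)) {
    for (b in seq_len(n_w)) {
      if (b >= a) {
        oo[a, b] <- mean_window_cosine(tc_obj, tc_obj, a, b, cells)[["mean"]]
        ff[a, b] <- mean_window_cosine(tc_face, tc_face, a, b, cells)[["mean"]]
        oo[b, a] <- oo[a, b]; ff[b, a] <- ff[a, b]
      }
      m <- mean_window_cosine(tc_face, tc_obj, a, b, cells)
      fo[a, b] <- m[["mean"]]
      if (a == b) fo_sem[a] <- m[["sem"]]
    }
  }
  structure(
    list(object_object = oo, face_face = ff, face_object = fo,
         windows = tc_face$windows,
         alignment = tibble::tibble(
           window_start = tc_face$windows[, 1],
           window_end = tc_face$windows[, 2],
           face_object_cosine = diag(fo), sem = fo_sem)),
    class = "axis_similarity"
  )
}

#' @export
print.axis_similarity <- function(x, ...) {
  cat(sprintf("<axis_similarity> %d x %d windows; face-object diagonal range [%.2f, %.2f]\n",
              nrow(x$face_object), ncol(x$face_object),
              min(x$alignment$face_object_cosine),
              max(x$alignment$face_object_cosine)))
  invisible(x)
}

#' Alignment of time-varying axes to the trial-wide object axis
#'
#' Cosine similarity between each cell's axis at every latency and that
#' cell's overall object axis (fit across the whole 50-220 ms response).
#' Rows (cells) can be sorted by face selectivity downstream.
#'
#' @param tc An `axis_timecourse` (face or object axes).
#' @param overall_axes cells x K matrix of trial-wide object axes.
#' @return cells x windows matrix of cosines (`NA` where an axis has zero
#'   norm).
#' @export
alignment_to_overall_object_axis <- function(tc, overall_axes) {
  if (ncol(overall_axes) != dim(tc$axes)[3]) abort("feature space mismatch")
  n_w <- nrow(tc$windows); n_c <- length(tc$cell_ids)
  out <- matrix(NA_real_, n_c, n_w,
                dimnames = list(tc$cell_ids, tc$windows[, 1]))
  for (j in seq_len(n_c)) {
    for (w in seq_len(n_w)) {
      out[j, w] <- cosine_sim(tc$axes[w, j, ], overall_axes[j, ])
    }
  }
  out
}

#' Detect tuning flips in the leading two feature dimensions
#'
#' Projects each cell's early- and late-window face axes onto the first two
#' feature dimensions and flags a flip when the 2-D angle between them
#' exceeds `threshold_deg` (default 120 degrees, i.e. a clear reversal rather
#' than mere rotation) and both axes pass the held-out R-squared inclusion
#' rule. The flip time is the first window whose 2-D cosine to the early axis
#' drops below `cos(threshold_deg)`.
#'
#' @param tc_face Face `axis_timecourse`.
#' @param early_window,late_window Windows (on the grid) compared for the
#'   flip flag.
#' @param threshold_deg Angle threshold in degrees.
#' @param r2_min Minimum held-out R-squared at both windows for inclusion.
#' @param dims The two feature dimensions used for the projection.
#' @return A `flip_report` tibble: per cell `cos2d_early_late`, `angle_deg`,
#'   `included`, `flip_flag`, `flip_time_ms`; attribute `flip_fraction` is
#'   the flipped share of included cells (see [glance.flip_report()]).
#' @export
detect_flip <- function(tc_face, early_window = c(80, 100),
                        late_window = c(120, 140), threshold_deg = 120,
                        r2_min = 0, dims = 1:2) {
  if (dim(tc_face$axes)[3] < 2) abort("need at least 2 feature dimensions")
  a <- window_index(tc_face, early_window)
  b <- window_index(tc_face, late_window)
  n_c <- length(tc_face$cell_ids)
  thr_cos <- cos(threshold_deg * pi / 180)
  cos2d <- ang <- flip_time <- rep(NA_real_, n_c)
  incl <- flip <- logical(n_c)
  for (j in seq_len(n_c)) {
    e2 <- tc_face$axes[a, j, dims]; l2 <- tc_face$axes[b, j, dims]
    cos2d[j] <- cosine_sim(e2, l2)
    ang[j] <- acos(pmin(pmax(cos2d[j], -1), 1)) * 180 / pi
    incl[j] <- tc_face$r2_test[a, j] > r2_min && tc_face$r2_test[b, j] > r2_min
    flip[j] <- isTRUE(incl[j] && !is.na(cos2d[j]) && cos2d[j] < thr_cos)
    if (flip[j]) {
      for (w in seq(a, nrow(tc_face$windows))) {
        cw <- cosine_sim(e2, tc_face$axes[w, j, dims])
        if (!is.na(cw) && cw < thr_cos) {
          flip_time[j] <- tc_face$windows[w, 1]
          break
        }
      }
    }
  }
  out <- tibble::tibble(
    cell = tc_face$cell_ids, cos2d_early_late = cos2d, angle_deg = ang,
    included = incl, flip_flag = flip, flip_time_ms = flip_time
  )
  class(out) <- c("flip_report", class(out))
  attr(out, "flip_fraction") <- if (sum(incl) > 0) mean(flip[incl]) else NA_real_
  attr(out, "threshold_deg") <- threshold_deg
  out
}

#' @rdname detect_flip
#' @param x A `flip_report`.
#' @param ... Unused.
#' @method glance flip_report
#' @export
glance.flip_report <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x), n_included = sum(x$included),
    flip_fraction = attr(x, "flip_fraction"),
    median_flip_time_ms = median(x$flip_time_ms, na.rm = TRUE),
    threshold_deg = attr(x, "threshold_deg")
  )
}

#' Adaptive per-cell short-latency window
#'
#' Returns the first 20-ms window (scanning forward from 0) in which a cell's
#' mean response is at least 2 s.d. above its mean baseline activity
#' (baseline window -25 to 25 ms). Accounts for per-cell latency differences
#' when choosing the "short-latency" fit window. A quiet baseline uses an
#' s.d. floor of `sd_floor` Hz to keep the threshold finite.
#'
#' @param psth Per-1-ms-bin mean rate of the cell (averaged over stimuli).
#' @param time_ms Bin times matching `psth`.
#' @param baseline_window Baseline `[start, end)` in ms.
#' @param width_ms,step_ms Scanned window geometry.
#' @param n_sd Threshold in baseline s.d. units.
#' @param sd_floor Minimum baseline s.d. (Hz).
#' @return `c(start, end)` of the first supra-threshold window, or `c(NA, NA)`
#'   if none.
#' @export
adaptive_short_window <- function(psth, time_ms, baseline_window = c(-25, 25),
                                  width_ms = 20, step_ms = 20, n_sd = 2,
                                  sd_floor = 0.1) {
  base_idx <- which(time_ms >= baseline_window[1] & time_ms < baseline_window[2])
  if (length(base_idx) == 0) abort("baseline window not recorded")
  thr <- mean(psth[base_idx]) + n_sd * max(sd(psth[base_idx]), sd_floor)
  starts <- seq(0, max(time_ms) - width_ms + 1, by = step_ms)
  for (s in starts) {
    idx <- which(time_ms >= s & time_ms < s + width_ms)
    if (length(idx) < width_ms) next
    if (mean(psth[idx]) >= thr) return(c(s, s + width_ms))
  }
  c(NA_real_, NA_real_)
}

#' Most- vs least-effective face-stimulus axis comparison
#'
#' Discriminates a true axis switch from the delayed-weak-response artifact.
#' Splits each cell's face stimuli into the 50% most- and 50% least-effective
#' halves by early-window response, fits face axes separately for each half
#' at both an early and a late window, and returns the 4 x 4 cosine matrix.
#' Under a genuine switch the most-effective-early vs most-effective-late
#' cosine is negative; under the latency artifact it stays positive.
#'
#' @param pop A `response_tensor`.
#' @param F Feature matrix for all stimuli.
#' @param cell Cell index.
#' @param early_window,late_window Fit windows in ms.
#' @return List with `cosines` (4 x 4 named matrix over
#'   most/least x early/late axes) and `split` (ids of the most-effective
#'   half).
#' @export
latency_split_control <- function(pop, F, cell, early_window = c(80, 100),
                                  late_window = c(120, 140)) {
  faces <- which(pop$category == "face")
  if (length(faces) < 8) abort("need >= 8 face stimuli")
  Re <- window_mean_rates(pop, early_window)[cell, faces]
  Rl <- window_mean_rates(pop, late_window)[cell, faces]
  ord <- order(Re, decreasing = TRUE)
  half <- floor(length(faces) / 2)
  groups <- list(most = ord[seq_len(half)],
                 least = ord[(half + 1):length(faces)])
  Ff <- F[faces, , drop = FALSE]
  axes <- list(
    most_early = lsq_axis(Ff, Re, groups$most),
    most_late = lsq_axis(Ff, Rl, groups$most),
    least_early = lsq_axis(Ff, Re, groups$least),
    least_late = lsq_axis(Ff, Rl, groups$least)
  )
  nm <- names(axes)
  cm <- matrix(NA_real_, 4, 4, dimnames = list(nm, nm))
  for (i in 1:4) for (j in 1:4) cm[i, j] <- cosine_sim(axes[[i]], axes[[j]])
  list(cosines = cm, split = pop$ids[faces][groups$most])
}
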