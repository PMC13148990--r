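#' Plot methods
#'
#' ggplot2 visualizations of the main result types: similarity matrices and
#' the face-object alignment time course, flip-angle distributions, decoding
#' accuracy curves, PSI time courses, and RNN training loss.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name axisdyn-plots
NULL

#' @rdname axisdyn-plots
#' @param which `"face_object"`, `"face_face"` or `"object_object"`.
#' @method autoplot axis_similarity
#' @export
autoplot.axis_similarity <- function(object, which = "face_object", ...) {
  M <- object[[which]]
  df <- tidyr::expand_grid(a = object$windows[, 1], b = object$windows[, 1])
  df$cosine <- as.vector(t(M))
  ggplot2::ggplot(df, ggplot2::aes(.data$b, .data$a, fill = .data$cosine)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "window start (ms)", y = "window start (ms)",
                  fill = "mean cosine",
                  title = sprintf("%s axis similarity", gsub("_", " vs ", which)))
}

#' @rdname axisdyn-plots
#' @export
plot_alignment <- function(object, ...) {
  stopifnot(inherits(object, "axis_similarity"))
  ggplot2::ggplot(object$alignment,
                  ggplot2::aes(.data$window_start, .data$face_object_cosine)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$face_object_cosine - .data$sem,
      ymax = .data$face_object_cosine + .data$sem), alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time (ms)", y = "face-object axis cosine")
}

#' @rdname axisdyn-plots
#' @method autoplot flip_report
#' @export
autoplot.flip_report <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$angle_deg, fill = .data$flip_flag)) +
    ggplot2::geom_histogram(binwidth = 10, boundary = 0) +
    ggplot2::geom_vline(xintercept = attr(object, "threshold_deg"),
                        linetype = 2) +
    ggplot2::labs(x = "early-late axis angle in PC1-PC2 (deg)", y = "cells")
}

#' @rdname axisdyn-plots
#' @method autoplot rnn_fit
#' @export
autoplot.rnn_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$loss), loss = object$loss)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loss)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(title = sprintf("%s task training", object$target))
}

#' @rdname axisdyn-plots
#' @param curves Tibble from [accuracy_vs_cellcount()] or
#'   [simulated_unit_experiment()].
#' @export
plot_decoding_curves <- function(curves, ...) {
  grp <- if ("window" %in% names(curves)) "window" else "pool"
  df <- dplyr::summarise(
    dplyr::group_by(curves, dplyr::across(dplyr::all_of(c(grp, "n_cells")))),
    mean_acc = mean(.data$accuracy),
    sem = sd(.data$accuracy) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$n_cells, .data$mean_acc,
                                   colour = .data[[grp]])) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_acc - .data$sem,
                                          ymax = .data$mean_acc + .data$sem)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cells", y = "identification accuracy")
}

#' @rdname axisdyn-plots
#' @param psi Tibble from [psi_timecourse()] or
#'   [categorization_discrimination_timecourse()].
#' @export
plot_psi_timecourse <- function(psi, ...) {
  ggplot2::ggplot(psi, ggplot2::aes(.data$window_start, .data$psi,
                                    colour = .data$grouping)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "population separation index")
}
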