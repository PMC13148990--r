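#' Pipeline run configuration
#'
#' Collects every knob of the simulate -> feature-space -> axes -> dynamics ->
#' metrics pipeline with the standard defaults: K = 60 feature dimensions,
#' 20-ms non-overlapping windows over 0-300 ms, switch at 110 ms, inclusion
#' thresholds (responsiveness alpha 0.05, peak d-prime >= 0.2 within 80-140
#' ms, held-out R-squared > 0 for both axes).
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_face,n_object,D Stimulus-set geometry.
#' @param K Feature-space dimensionality.
#' @param n_cells,flip_dims,new_dims,switch_time_ms,gain_hz,noise_model
#'   Ground-truth population parameters.
#' @param n_repeats Trials averaged per cell x stimulus.
#' @param no_switch Build the matched no-switch control instead.
#' @param window_width_ms,window_step_ms Sliding-window grid.
#' @param alpha,dprime_min,r2_min Inclusion thresholds.
#' @param area_offset_ms Latency offset added to the early/late comparison
#'   windows (e.g. 20 for the anterior-medial patch).
#' @param out_dir Optional directory for CSV/JSON artifacts.
#' @return A `run_config` list; `config_hash()` gives its provenance hash.
#' @export
run_config <- function(seed = 1, n_face = 350, n_object = 350, D = 60, K = 60,
                       n_cells = 100, flip_dims = 5, new_dims = K - flip_dims,
                       switch_time_ms = 110, gain_hz = 40,
                       noise_model = "poisson", n_repeats = 10,
                       no_switch = FALSE,
                       window_width_ms = 20, window_step_ms = 20,
                       alpha = 0.05, dprime_min = 0.2, r2_min = 0,
                       area_offset_ms = 0, out_dir = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
config_hash <- function(config) rlang::hash(unclass(config))

#' Apply the cell-inclusion rules
#'
#' Conjunction of the standard inclusion criteria: significant visual
#' responsiveness (p < alpha), non-zero response variance across stimuli,
#' peak d-prime >= `dprime_min` within 80-140 ms, and positive held-out
#' R-squared for both the face and object axes. Rules are order-free; the
#' attrition table counts, per rule, how many otherwise-eligible cells it
#' removes.
#'
#' @param metrics Per-cell tibble from [cell_selectivity()].
#' @param r2_face,r2_object Optional per-cell held-out R-squared (aligned
#'   with `metrics$cell`); the corresponding rule is skipped when `NULL`.
#' @param alpha,dprime_min,r2_min Thresholds; set a threshold to `NULL` to
#'   disable its rule.
#' @return List: `included` (cell ids), `attrition` (tibble rule/n_failed),
#'   `pass` (logical matrix, cells x rules).
#' @export
select_cells <- function(metrics, r2_face = NULL, r2_object = NULL,
                         alpha = 0.05, dprime_min = 0.2, r2_min = 0) {
  rules <- list()
  if (!is.null(alpha)) rules$responsive <- metrics$responsive_p < alpha
  rules$variance <- metrics$response_var > 0
  if (!is.null(dprime_min)) rules$dprime <- metrics$peak_dprime >= dprime_min
  if (!is.null(r2_min) && !is.null(r2_face)) rules$r2_face <- r2_face > r2_min
  if (!is.null(r2_min) && !is.null(r2_object)) rules$r2_object <- r2_object > r2_min
  pass <- do.call(cbind, rules)
  keep <- rowSums(!pass) == 0
  if (!any(keep)) warn("no cells survive the inclusion rules")
  list(
    included = metrics$cell[keep],
    attrition = tibble::tibble(rule = colnames(pass),
                               n_failed = unname(colSums(!pass))),
    pass = pass
  )
}

#' Run the full axis-dynamics pipeline on a synthetic population
#'
#' Chains the stages end to end: stimulus generation, population simulation,
#' feature-space fit and projection, per-cell selectivity metrics and
#' inclusion, trial-wide and sliding-window axis fits, similarity matrices,
#' flip detection, sparseness and PSI time courses. Deterministic given the
#' config; when `config$out_dir` is set, writes the tabular results plus a
#' provenance JSON (config, hash, package version) there.
#'
#' @param config A [run_config()].
#' @return An `axis_pipeline` list with the intermediate objects
#'   (`stimuli`, `truth`, `pop`, `space`, `features`, `metrics`,
#'   `selection`, `tc_face`, `tc_obj`, `similarity`, `flips`, `sparseness`,
#'   `psi`) and a one-row `summary` tibble.
#' @export
run_axis_pipeline <- function(config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  stimuli <- stage("simulate", make_stimulus_set(
    config$n_face, config$n_object, D = config$D, seed = config$seed))
  truth <- stage("simulate", {
    if (config$no_switch) {
      make_no_switch_truth(K = config$K, n_cells = config$n_cells,
                           flip_dims = config$flip_dims, gain_hz = config$gain_hz,
                           noise_model = config$noise_model,
                           seed = config$seed + 1L)
    } else {
      make_switching_truth(K = config$K, n_cells = config$n_cells,
                           flip_dims = config$flip_dims,
                           new_dims = config$new_dims,
                           switch_time_ms = config$switch_time_ms,
                           gain_hz = config$gain_hz,
                           noise_model = config$noise_model,
                           seed = config$seed + 1L)
    }
  })
  pop <- stage("simulate", simulate_population(stimuli, truth,
                                               n_repeats = config$n_repeats,
                                               seed = config$seed + 2L))
  space <- stage("fit-space", fit_feature_space(stimuli$embeddings, K = config$K))
  features <- stage("fit-space", project_features(space, stimuli$embeddings))
  split <- train_test_split(pop$category, seed = config$seed + 3L)
  metrics <- stage("score", cell_selectivity(pop))
  overall <- stage("fit-axes", fit_axes(pop, features, window = c(50, 220),
                                        split = split))
  windows <- sliding_windows(width_ms = config$window_width_ms,
                             step_ms = config$window_step_ms)
  tc_face <- stage("dynamics", sliding_axes(pop, features, "face", windows, split))
  tc_obj <- stage("dynamics", sliding_axes(pop, features, "object", windows, split))
  early <- c(80, 100) + config$area_offset_ms
  late <- c(120, 140) + config$area_offset_ms
  sel <- stage("score", select_cells(
    metrics,
    r2_face = pmax(tc_face$r2_test[window_index(tc_face, early), ],
                   tc_face$r2_test[window_index(tc_face, late), ]),
    r2_object = pmax(tc_obj$r2_test[window_index(tc_obj, early), ],
                     tc_obj$r2_test[window_index(tc_obj, late), ]),
    alpha = config$alpha, dprime_min = config$dprime_min,
    r2_min = config$r2_min))
  incl <- match(sel$included, pop$cell_ids)
  sim <- stage("dynamics", similarity_matrices(tc_face, tc_obj, cells = incl))
  flips <- stage("dynamics", detect_flip(tc_face, early, late))
  sparse <- stage("score", {
    st <- sparseness_timecourse(pop, cells = incl, smooth_ms = 20)
    dplyr::summarise(dplyr::group_by(st, .data$category, .data$time_ms),
                     sparseness = mean(.data$sparseness, na.rm = TRUE),
                     .groups = "drop")
  })
  psi <- stage("score", categorization_discrimination_timecourse(
    pop, windows, cells = incl))
  align <- sim$alignment
  pre <- align$face_object_cosine[align$window_start >= 60 &
                                    align$window_end <= 100]
  post <- align$face_object_cosine[align$window_start >= late[1]]
  summary <- tibble::tibble(
    config_hash = config_hash(config),
    n_cells_included = length(incl),
    flip_fraction = attr(flips, "flip_fraction"),
    median_flip_time_ms = median(flips$flip_time_ms, na.rm = TRUE),
    alignment_pre_switch = mean(pre),
    alignment_post_switch = mean(post),
    median_peak_dprime = median(metrics$peak_dprime)
  )
  out <- structure(
    list(config = config, stimuli = stimuli, truth = truth, pop = pop,
         space = space, features = features, split = split, metrics = metrics,
         overall_axes = overall, tc_face = tc_face, tc_obj = tc_obj,
         selection = sel, similarity = sim, flips = flips,
         sparseness = sparse, psi = psi, summary = summary),
    class = "axis_pipeline"
  )
  if (!is.null(config$out_dir)) write_pipeline_results(out, config$out_dir)
  out
}

#' @export
print.axis_pipeline <- function(x, ...) {
  cat("<axis_pipeline>\n")
  print(x$summary)
  invisible(x)
}

#' @rdname run_axis_pipeline
#' @param x An `axis_pipeline`.
#' @param ... Unused.
#' @method glance axis_pipeline
#' @export
glance.axis_pipeline <- function(x, ...) x$summary

#' Write / read pipeline artifacts as plain-text containers
#'
#' Tabular results go to CSV, the configuration and provenance (config hash,
#' package version, seeds) to JSON. `write_population()` /
#' `read_population()` round-trip a response tensor through a directory of
#' CSVs plus a JSON sidecar; intended for small (fixture-scale) populations.
#'
#' @param x An `axis_pipeline`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_pipeline_results <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(x$metrics, file.path(dir, "cell_metrics.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(x$flips), file.path(dir, "flips.csv"),
                   row.names = FALSE)
  utils::write.csv(x$similarity$alignment, file.path(dir, "alignment.csv"),
                   row.names = FALSE)
  utils::write.csv(x$sparseness, file.path(dir, "sparseness.csv"), row.names = FALSE)
  utils::write.csv(x$psi, file.path(dir, "psi.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(x$config), config_hash = config_hash(x$config),
         package_version = as.character(utils::packageVersion("axisdyn"))),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, null = "null",
    digits = NA)
  invisible(dir)
}

#' @rdname write_pipeline_results
#' @param pop A `response_tensor`.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(pop$rates)
  flat <- matrix(pop$rates, d[1] * d[2], d[3])
  utils::write.csv(flat, file.path(dir, "rates.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(dim = d, time_ms = pop$time_ms, n_repeats = pop$n_repeats,
         category = as.character(pop$category), ids = pop$ids,
         cell_ids = pop$cell_ids),
    file.path(dir, "population.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' @rdname write_pipeline_results
#' @export
read_population <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "population.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(utils::read.csv(file.path(dir, "rates.csv")))
  rates <- array(flat, dim = meta$dim)
  new_response_tensor(rates, meta$time_ms, meta$n_repeats[1],
                      factor(meta$category, levels = c("face", "object")),
                      meta$ids, meta$cell_ids)
}
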