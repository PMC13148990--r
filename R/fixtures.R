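#' Mini switching fixture population
#'
#' A small, fast, fully deterministic switching population (20 cells, 60 face
#' and 60 object stimuli, K = 12 with 3 flipped + 9 new dimensions) used by
#' the test suite and the README walkthrough. Regenerating with the same seed
#' reproduces it bit-identically.
#'
#' @param seed Integer seed.
#' @return List: `stimuli`, `truth`, `pop`, `space`, `features`, `split`.
#' @export
mini_switch_fixture <- function(seed = 42) {
  stimuli <- make_stimulus_set(60, 60, D = 12, seed = seed)
  truth <- make_switching_truth(K = 12, n_cells = 20, flip_dims = 3,
                                new_dims = 9, noise_model = "poisson",
                                seed = seed + 1L)
  pop <- simulate_population(stimuli, truth, time_ms = -50:249, n_repeats = 20,
                             seed = seed + 2L)
  space <- fit_feature_space(stimuli$embeddings, K = 12)
  list(stimuli = stimuli, truth = truth, pop = pop, space = space,
       features = project_features(space, stimuli$embeddings),
       split = train_test_split(pop$category, seed = seed + 3L))
}

#' Summary numbers of the mini fixture
#'
#' The hand-checkable quantities frozen in
#' `inst/extdata/mini_switch_expected.csv`: flip fraction, pre/post-switch
#' face-object alignment, and median peak d-prime.
#'
#' @param fx Result of [mini_switch_fixture()].
#' @return One-row tibble.
#' @export
mini_switch_summary <- function(fx = mini_switch_fixture()) {
  windows <- sliding_windows(0, 240)
  tc_face <- sliding_axes(fx$pop, fx$features, "face", windows, fx$split)
  tc_obj <- sliding_axes(fx$pop, fx$features, "object", windows, fx$split)
  sim <- similarity_matrices(tc_face, tc_obj)
  flips <- detect_flip(tc_face)
  al <- sim$alignment
  tibble::tibble(
    flip_fraction = attr(flips, "flip_fraction"),
    alignment_pre = mean(al$face_object_cosine[al$window_start >= 60 &
                                                 al$window_end <= 100]),
    alignment_post = mean(al$face_object_cosine[al$window_start >= 120]),
    median_peak_dprime = median(cell_selectivity(fx$pop)$peak_dprime)
  )
}

#' Regenerate the frozen fixture expectations
#'
#' Rebuilds the expected-summary CSV from the seed registry (currently the
#' single mini switching fixture). Tests compare a fresh regeneration against
#' the frozen copy shipped under `inst/extdata/`.
#'
#' @param dir Output directory.
#' @param seed Fixture seed.
#' @return Paths of the written files, invisibly.
#' @export
regenerate_fixtures <- function(dir, seed = 42) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "mini_switch_expected.csv")
  s <- mini_switch_summary(mini_switch_fixture(seed))
  utils::write.csv(format(as.data.frame(s), digits = 15), path,
                   row.names = FALSE)
  invisible(path)
}
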