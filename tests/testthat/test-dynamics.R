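test_that("stationary noiseless cells keep the same axis in every window", {
  fx <- fx_stationary()
  windows <- sliding_windows(0, 240)
  tc <- sliding_axes(fx$pop, fx$features, "face", windows, fx$split)
  resp <- which(windows[, 1] >= 80 & windows[, 2] <= 220)  # response period
  for (j in 1:5) {
    for (w in head(resp, -1)) {
      cs <- sum(tc$axes[w, j, ] * tc$axes[w + 1, j, ]) /
        sqrt(sum(tc$axes[w, j, ]^2) * sum(tc$axes[w + 1, j, ]^2))
      expect_gte(cs, 0.99)
    }
  }
})

test_that("similarity matrices are bounded, symmetric and flag the switch", {
  fx <- fx_small()
  windows <- sliding_windows(0, 240)
  tcf <- sliding_axes(fx$pop, fx$features, "face", windows, fx$split)
  tco <- sliding_axes(fx$pop, fx$features, "object", windows, fx$split)
  sim <- similarity_matrices(tcf, tco)
  for (M in sim[c("object_object", "face_face", "face_object")]) {
    expect_true(all(M >= -1 - 1e-12 & M <= 1 + 1e-12))
  }
  expect_equal(sim$object_object, t(sim$object_object), tolerance = 1e-12)
  expect_equal(sim$face_face, t(sim$face_face), tolerance = 1e-12)
  al <- sim$alignment
  expect_gt(mean(al$face_object_cosine[al$window_start >= 60 &
                                         al$window_end <= 100]), 0)
  expect_lt(mean(al$face_object_cosine[al$window_start >= 120 &
                                         al$window_start < 200]), 0)
})

test_that("face axes flip across the switch while control populations do not", {
  fx <- fx_small()
  tcf <- sliding_axes(fx$pop, fx$features, "face",
                      sliding_windows(0, 240), fx$split)
  fl <- detect_flip(tcf)
  expect_gte(attr(fl, "flip_fraction"), 0.9)
  expect_true(all(is.na(fl$flip_time_ms) | fl$flip_time_ms >= 100))

  fx0 <- fx_stationary()
  tcf0 <- sliding_axes(fx0$pop, fx0$features, "face",
                       sliding_windows(0, 240), fx0$split)
  fl0 <- detect_flip(tcf0)
  expect_lte(attr(fl0, "flip_fraction"), 0.05)
})

test_that("alignment to the overall object axis is signed correctly", {
  fx <- fx_small()
  windows <- sliding_windows(0, 240)
  tcf <- sliding_axes(fx$pop, fx$features, "face", windows, fx$split)
  overall <- fit_axes(fx$pop, fx$features, window = c(50, 220),
                      split = fx$split, cross = FALSE)
  W <- do.call(rbind, overall$weights[overall$category == "object"])
  A <- alignment_to_overall_object_axis(tcf, W)
  pre <- which(windows[, 1] %in% c(60, 80))
  post <- which(windows[, 1] %in% c(120, 140))
  expect_gt(mean(A[, pre]), 0)
  expect_lt(mean(A[, post]), 0)
  expect_error(alignment_to_overall_object_axis(tcf, W[, 1:3]), "mismatch")
})

test_that("adaptive short-latency windows find response onset", {
  time_ms <- -50:249
  psth <- rep(2, 300)
  psth[time_ms >= 72] <- 30
  w <- adaptive_short_window(psth, time_ms)
  expect_true(w[1] >= 60 && w[1] < 80)

  expect_true(all(is.na(adaptive_short_window(rep(3, 300), time_ms))))

  # false-positive rate of the 2-s.d. rule on pure baseline noise
  set.seed(5)
  hits <- vapply(1:100, function(i) {
    noise <- rnorm(300, mean = 5, sd = 2)
    !is.na(adaptive_short_window(noise, time_ms)[1])
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("the latency-split control separates switching from the latency artifact", {
  fx <- fx_small()
  cs <- vapply(1:10, function(j) {
    latency_split_control(fx$pop, fx$features, j)$cosines["most_early", "most_late"]
  }, numeric(1))
  expect_lt(median(cs), 0)

  art <- simulate_latency_artifact(fx$stimuli, K = 12, n_cells = 10,
                                   time_ms = -50:249, seed = 3)
  cs_art <- vapply(1:10, function(j) {
    latency_split_control(art, fx$features, j)$cosines["most_early", "most_late"]
  }, numeric(1))
  expect_gt(median(cs_art), 0)
})

test_that("window grids and lookups behave", {
  w <- sliding_windows(0, 100, width_ms = 20, step_ms = 10)
  expect_true(all(w[, 2] - w[, 1] == 20))
  expect_equal(unname(w[2, 1] - w[1, 1]), 10)
  fx <- fx_small()
  tc <- sliding_axes(fx$pop, fx$features, "face", sliding_windows(0, 240),
                     fx$split)
  expect_error(detect_flip(tc, early_window = c(81, 101)), "grid")
})
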