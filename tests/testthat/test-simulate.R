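test_that("switching ground truth reverses the detection loadings", {
  tr <- make_switching_truth(K = 60, n_cells = 100, flip_dims = 5,
                             new_dims = 55, seed = 3)
  cos5 <- vapply(seq_len(100), function(j) {
    a <- tr$early_axis[j, 1:5]; b <- tr$late_face_axis[j, 1:5]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  expect_true(all(cos5 < 0))
  expect_equal(unname(cos5), rep(-1, 100))   # the block is negated exactly
  # unit rows
  expect_equal(rowSums(tr$early_axis^2), rep(1, 100))
  expect_equal(rowSums(tr$late_face_axis^2), rep(1, 100))
})

test_that("full reversal with no high-dimensional noise gives late = -early", {
  tr <- make_switching_truth(K = 6, n_cells = 10, flip_dims = 6, new_dims = 0,
                             highdim_sd = 0, seed = 4)
  expect_equal(tr$late_face_axis, -tr$early_axis)
})

test_that("ground truth is deterministic and rejects the degenerate case", {
  a <- make_switching_truth(K = 8, n_cells = 5, flip_dims = 2, new_dims = 3, seed = 3)
  b <- make_switching_truth(K = 8, n_cells = 5, flip_dims = 2, new_dims = 3, seed = 3)
  expect_identical(a$early_axis, b$early_axis)
  d <- make_switching_truth(K = 8, n_cells = 5, flip_dims = 2, new_dims = 3, seed = 4)
  expect_false(identical(a$early_axis, d$early_axis))
  expect_error(make_switching_truth(K = 8, flip_dims = 0, new_dims = 0),
               "degenerate")
})

test_that("noiseless unit-drive response equals the temporal kernel", {
  tr <- make_switching_truth(K = 6, n_cells = 1, flip_dims = 2, new_dims = 4,
                             seed = 5)
  tr$gain_hz <- 1; tr$baseline_hz <- 0; tr$visual_drive_hz <- 0
  tr$latency_ms <- 50
  f1 <- tr$early_axis[1, ]                     # unit-norm drive vector
  ss <- stimulus_set(unname(rbind(f1, f1, -f1)), c("face", "face", "object"))
  pop <- simulate_population(ss, tr, time_ms = 0:150, n_repeats = 1,
                             noise_override = "none")
  pre <- pop$time_ms < tr$switch_time_ms
  expect_equal(pop$rates[1, 1, pre],
               resp_kernel(pop$time_ms[pre] - 50), tolerance = 1e-12)
})

test_that("reversed late axes anti-correlate pre- and post-switch face patterns", {
  tr <- make_switching_truth(K = 8, n_cells = 6, flip_dims = 8, new_dims = 0,
                             highdim_sd = 0, baseline_hz = 100,
                             late_offset_frac = 0, seed = 6)
  ss <- make_stimulus_set(30, 10, D = 8, seed = 7)
  pop <- simulate_population(ss, tr, time_ms = -50:249, n_repeats = 1,
                             noise_override = "none")
  faces <- pop$category == "face"
  pre <- window_mean_rates(pop, c(80, 100))[, faces]
  post <- window_mean_rates(pop, c(130, 150))[, faces]
  cors <- vapply(1:6, function(j) cor(pre[j, ], post[j, ]), numeric(1))
  expect_true(all(cors < -0.95))

  tr0 <- make_no_switch_truth(K = 8, n_cells = 6, flip_dims = 8,
                              highdim_sd = 0, seed = 6)
  pop0 <- simulate_population(ss, tr0, time_ms = -50:249, n_repeats = 1,
                              noise_override = "none")
  pre0 <- window_mean_rates(pop0, c(80, 100))[, faces]
  post0 <- window_mean_rates(pop0, c(130, 150))[, faces]
  cors0 <- vapply(1:6, function(j) cor(pre0[j, ], post0[j, ]), numeric(1))
  expect_true(all(cors0 > 0.99))
})

test_that("simulation is deterministic and validates its inputs", {
  fx <- fx_small()
  again <- simulate_population(fx$stimuli, fx$truth, time_ms = -50:249,
                               n_repeats = 20, seed = 9)
  expect_identical(fx$pop$rates, again$rates)
  expect_true(all(fx$pop$rates >= 0))
  tr_big <- make_switching_truth(K = 20, n_cells = 2, seed = 1)
  expect_error(simulate_population(fx$stimuli, tr_big), "exceeds")
  expect_error(simulate_population(fx$stimuli, fx$truth, n_repeats = 0), "repeats")
})

test_that("Poisson spike counts have unit Fano factor", {
  tr <- make_switching_truth(K = 4, n_cells = 1, flip_dims = 2, new_dims = 2,
                             seed = 11)
  tr$gain_hz <- 0; tr$baseline_hz <- 20; tr$visual_drive_hz <- 0
  ss <- make_stimulus_set(10, 10, D = 4, seed = 12)
  pop <- simulate_population(ss, tr, time_ms = 0:499, n_repeats = 200, seed = 13)
  counts <- pop$rates[1, , ] * 200 * 0.001    # summed spike counts per bin
  expect_gt(var(as.vector(counts)) / mean(counts), 0.8)
  expect_lt(var(as.vector(counts)) / mean(counts), 1.2)
})

test_that("threshold model responses follow max(0, projection - threshold)", {
  ss <- stimulus_set(matrix(c(-1, 0.5, 2), 3, 1),
                     c("object", "object", "object"))
  expect_equal(threshold_model_responses(1, ss, threshold = 1), c(0, 0, 1))
  expect_equal(threshold_model_responses(1, ss, threshold = 0), c(0, 0.5, 2))
  expect_equal(threshold_model_responses(1, ss, threshold = 10), c(0, 0, 0))
  expect_error(threshold_model_responses(1, ss, threshold = -1))
})

test_that("response tensors round-trip through the plain-text container", {
  fx <- fx_small()
  dir <- withr::local_tempdir()
  write_population(fx$pop, dir)
  back <- read_population(dir)
  expect_equal(back$rates, fx$pop$rates, ignore_attr = TRUE)
  expect_equal(back$time_ms, fx$pop$time_ms)
  expect_equal(as.character(back$category), as.character(fx$pop$category))
})
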