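test_that("window specs have matched duration and support area offsets", {
  durs <- vapply(c("short", "long", "combined"), function(n) {
    w <- window_spec(n)
    sum(vapply(w$sub_windows, diff, numeric(1)))
  }, numeric(1))
  expect_true(all(durs == durs[1]))
  am <- window_spec("short", offset_ms = 20)
  expect_equal(am$sub_windows[[1]], c(70, 95))
  expect_error(window_spec(sub_windows = list(c(0, 10))), "two")
})

test_that("nearest-neighbour identification scores exact, null and tied cases", {
  set.seed(14)
  ref <- matrix(rnorm(50 * 6), 50, 6)
  expect_equal(identify_nearest(ref, ref), 1)

  # random-assignment null: expectation 1/n
  accs <- vapply(1:1000, function(i) {
    identify_nearest(ref[sample(50), ], ref)
  }, numeric(1))
  se <- sqrt(0.02 * 0.98 / (1000 * 50))
  expect_lt(abs(mean(accs) - 1 / 50), 4 * se)

  # equidistant decode ties to the lowest index
  ref2 <- rbind(c(0, 0), c(2, 0))
  dec <- rbind(c(1, 0), c(1, 0))
  expect_equal(identify_nearest(dec, ref2), 0.5)
  expect_error(identify_nearest(dec, ref2[0, , drop = FALSE]), "empty")
})

test_that("noiseless linear populations decode perfectly; shuffles do not", {
  fx <- fx_stationary()
  faces <- which(fx$pop$category == "face")
  set.seed(15)
  te <- sample(faces, 12); tr <- setdiff(faces, te)
  w <- window_spec("short")
  d <- train_decoder(fx$pop, fx$features, w, tr)
  out <- cross_window_decode(d, fx$pop, te, latents = fx$features)
  expect_gt(out$r2_overall, 0.999)
  # training-window decode equals the default decode
  out2 <- cross_window_decode(d, fx$pop, te, window = w)
  expect_equal(out$decoded, out2$decoded)

  shuf <- fx$features[sample(nrow(fx$features)), ]
  d2 <- train_decoder(fx$pop, shuf, w, tr)
  out3 <- cross_window_decode(d2, fx$pop, te, latents = shuf)
  expect_lte(out3$r2_overall, 0.05)
})

test_that("cross-window transfer fails only when the code switches", {
  fx <- fx_small()
  faces <- which(fx$pop$category == "face")
  set.seed(16)
  te <- sample(faces, 15); tr <- setdiff(faces, te)
  ws <- window_spec("short"); wl <- window_spec("long")
  ref <- fx$features[te, ]
  d <- train_decoder(fx$pop, fx$features, ws, tr)
  in_acc <- identify_nearest(cross_window_decode(d, fx$pop, te)$decoded, ref)
  cross_acc <- identify_nearest(
    cross_window_decode(d, fx$pop, te, window = wl)$decoded, ref)
  expect_gt(in_acc, 5 * cross_acc)

  fx0 <- fx_stationary()
  d0 <- train_decoder(fx0$pop, fx0$features, ws, tr)
  cross0 <- identify_nearest(
    cross_window_decode(d0, fx0$pop, te, window = wl)$decoded, ref)
  expect_gt(cross0, 0.9)   # noiseless stationary code transfers
})

test_that("zero cells decode at chance", {
  fx <- fx_small()
  cur <- accuracy_vs_cellcount(fx$pop, fx$features,
                               list(short = window_spec("short")),
                               cell_counts = 0, n_resample = 3, seed = 2)
  expect_true(all(abs(cur$accuracy - 1 / 6) < 1e-12))  # 6 held-out faces
})

test_that("simulated units reproduce the redundancy-diversity crossover", {
  out <- simulated_unit_experiment(cell_counts = c(5, 200), n_resample = 6,
                                   seed = 3)
  m <- tapply(out$accuracy, list(out$pool, out$n_cells), mean)
  expect_gt(m["short", "5"], m["long", "5"])
  expect_gt(m["long", "200"], m["short", "200"])
})

test_that("identity separation rises late even with frozen low dimensions", {
  ss <- make_knockout_stimulus_set(n_face_per_vector = 12, n_vectors = 5,
                                   frozen_dims = 3, n_object = 60, D = 12,
                                   seed = 21)
  tr <- make_switching_truth(K = 12, n_cells = 20, flip_dims = 3, new_dims = 9,
                             seed = 22)
  pop <- simulate_population(ss, tr, time_ms = -50:249, n_repeats = 20, seed = 23)
  pop2 <- simulate_population(ss, tr, time_ms = -50:249, n_repeats = 20, seed = 123)
  psi <- psi_timecourse(pop, "identity", sliding_windows(0, 240), pop2 = pop2)
  late <- mean(psi$psi[psi$window_start %in% c(120, 140)])
  early <- mean(psi$psi[psi$window_start %in% c(60, 80)])
  expect_gt(late, 0.8 * early)   # high-dim tuning sustains identity info
  expect_gt(late, 2 * mean(psi$psi[psi$window_start < 40]))
})
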