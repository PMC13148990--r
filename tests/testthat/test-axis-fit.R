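test_that("the closed-form axis solve matches the normal-equations oracle", {
  set.seed(1)
  for (i in 1:20) {
    n <- sample(30:200, 1); K <- sample(2:20, 1)
    F_ <- matrix(rnorm(n * K), n, K)
    r <- rnorm(n)
    te <- sample(n, 5); tr <- setdiff(seq_len(n), te)
    fit <- fit_axis(r, F_, tr, te)
    expect_equal(unname(fit$weights), oracle_axis(r, F_, tr), tolerance = 1e-8)
  }
})

test_that("an exactly linear response is recovered perfectly", {
  set.seed(2)
  F_ <- matrix(rnorm(80 * 6), 80, 6)
  w_star <- c(2, -1, 0.5, 0, 3, -0.25)
  r <- as.vector(F_ %*% w_star) + 5
  sp <- train_test_split(rep("face", 80), seed = 3)
  fit <- fit_axis(r, F_, sp$train, sp$test)
  expect_equal(unname(fit$weights), w_star, tolerance = 1e-8)
  expect_equal(fit$r2_test, 1, tolerance = 1e-10)
})

test_that("hand-worked three-stimulus case gives weights (1, 0)", {
  F_ <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  r <- c(2, 1, 0, 1)
  fit <- fit_axis(r, F_, 1:3, 4)
  expect_equal(unname(fit$weights), c(1, 0), tolerance = 1e-10)
})

test_that("constant responses give zero weights and the 0/0 R-squared convention", {
  F_ <- matrix(rnorm(40 * 4), 40, 4)
  fit <- fit_axis(rep(7, 40), F_, 1:30, 31:40)
  expect_equal(unname(fit$weights), rep(0, 4), tolerance = 1e-10)
  expect_equal(fit$r2_test, 0)
})

test_that("cross-prediction on the axis's own test set reproduces r2_test", {
  set.seed(4)
  F_ <- matrix(rnorm(100 * 5), 100, 5)
  r <- as.vector(F_ %*% rnorm(5)) + rnorm(100, sd = 0.5)
  sp <- train_test_split(rep("face", 100), seed = 5)
  fit <- fit_axis(r, F_, sp$train, sp$test)
  expect_equal(cross_predict(fit, r, F_, sp$test), fit$r2_test)
  expect_error(cross_predict(fit, r, F_[, 1:3], sp$test), "mismatch")
})

test_that("normalized face-object correlation separates shared from opposed axes", {
  set.seed(6)
  K <- 6
  F_ <- matrix(rnorm(120 * K), 120, K)
  cat_ <- rep(c("face", "object"), each = 60)
  w <- rnorm(K)
  shared <- as.vector(F_ %*% w)
  nfo <- normalized_fo_correlation(shared, F_, cat_)
  expect_equal(nfo$normalized, 1, tolerance = 1e-6)

  opposed <- shared
  opposed[cat_ == "object"] <- -opposed[cat_ == "object"]
  nfo2 <- normalized_fo_correlation(opposed, F_, cat_)
  expect_equal(nfo2$normalized, -1, tolerance = 1e-6)

  # pure-noise cells cannot be normalized: the split-half bound collapses
  flags <- vapply(1:10, function(i) {
    is.na(normalized_fo_correlation(rnorm(120), F_, cat_, split_seed = i)$normalized)
  }, logical(1))
  expect_gte(mean(flags), 0.9)
})

test_that("noiseless linear artificial units have a single axis", {
  fx <- fx_small()
  rep_ <- artificial_unit_control(fx$features, fx$stimuli$category,
                                  n_units = 15, noise_sd = 0, seed = 2)
  expect_true(all(abs(rep_$fo_normalized - 1) < 1e-6))
  expect_true(all(rep_$r2_face > 0.999 & rep_$r2_object > 0.999))
})

test_that("label shuffling destroys held-out prediction", {
  fx <- fx_small()
  R <- window_mean_rates(fx$pop, c(80, 100))
  faces <- which(fx$pop$category == "face")
  set.seed(8)
  r2s <- vapply(seq_len(nrow(R)), function(j) {
    r <- R[j, faces][sample(length(faces))]
    sp <- train_test_split(rep("face", length(faces)), seed = j)
    fit_axis(r, fx$features[faces, ], sp$train, sp$test)$r2_test
  }, numeric(1))
  expect_lte(mean(r2s), 0.05)
})

test_that("effectiveness subsets rank stimuli and report the response ratio", {
  rates <- array(0, dim = c(1, 4, 300))
  rates[1, , ] <- matrix(rep(c(2, 3, 5, 7), 300), 4, 300)
  pop <- response_tensor(rates, time_ms = 0:299,
                         category = c("face", "face", "object", "object"))
  out <- effectiveness_subsets(pop, k = 1, window = c(50, 220))
  expect_equal(out$top_object_ids, pop$ids[4])
  expect_equal(out$bottom_face_ids, pop$ids[1])
  expect_equal(out$response_ratio, 3.5)
  out2 <- effectiveness_subsets(pop, k = 2, window = c(50, 220))
  expect_equal(out2$response_ratio, mean(c(5, 7)) / mean(c(2, 3)))
  expect_error(effectiveness_subsets(pop, k = 3), "category")
})
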