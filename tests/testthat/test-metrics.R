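test_that("population sparseness hits its exact bounds", {
  expect_equal(population_sparseness(rep(3, 7)), 0, tolerance = 1e-12)
  expect_equal(population_sparseness(c(1, 0, 0, 0)), 0.75)
  expect_equal(population_sparseness(c(3, 1)), 0.2)
  expect_true(is.na(population_sparseness(c(0, 0, 0))))
})

test_that("d-prime follows the standardized-difference formula and antisymmetry", {
  d <- sqrt(2)  # half-spread giving variance 4 for two points
  rates <- array(0, dim = c(1, 4, 50))
  rates[1, 1, ] <- 10 + d; rates[1, 2, ] <- 10 - d
  rates[1, 3, ] <- 6 + d;  rates[1, 4, ] <- 6 - d
  pop <- response_tensor(rates, 0:49, c("face", "face", "object", "object"))
  dp <- dprime_timecourse(pop, 1)
  expect_equal(dp$dprime, rep(2, 50))

  swapped <- response_tensor(rates, 0:49, c("object", "object", "face", "face"))
  expect_equal(dprime_timecourse(swapped, 1)$dprime, -dp$dprime)

  # flat d-prime: the peak equals the constant
  rates2 <- array(rep(c(12 + d, 12 - d, 6 + d, 6 - d), 200), c(1, 4, 200))
  pop2 <- response_tensor(rates2, 0:199, c("face", "face", "object", "object"))
  expect_equal(peak_dprime(dprime_timecourse(pop2, 1)), 3)
})

test_that("responsiveness test handles degenerate and strong cases", {
  rates <- array(5, dim = c(1, 30, 350))
  pop <- response_tensor(rates, -50:299, rep(c("face", "object"), 15))
  expect_equal(responsiveness_test(pop, 1), 1)

  rates2 <- rates
  rates2[1, , 101:350] <- 25   # step response from 50 ms on
  rates2[1, , ] <- rates2[1, , ] + array(rnorm(30 * 350, sd = 0.5), c(30, 350))
  pop2 <- response_tensor(rates2, -50:299, rep(c("face", "object"), 15))
  expect_lt(responsiveness_test(pop2, 1), 1e-6)
})

test_that("type-I error of the responsiveness test is near nominal", {
  set.seed(31)
  p <- vapply(1:200, function(i) {
    rates <- array(rnorm(20 * 350, mean = 8, sd = 2), c(1, 20, 350))
    pop <- response_tensor(rates, -50:299, rep(c("face", "object"), 10))
    responsiveness_test(pop, 1)
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.01)
  expect_lt(mean(p < 0.05), 0.10)
})

test_that("PSI matches its definition and is scale/translation invariant", {
  set.seed(12)
  R <- matrix(rexp(8 * 30), 8, 30)
  g <- rep(c("a", "b", "c"), each = 10)
  M <- vapply(unique(g), function(x) rowMeans(R[, g == x]), numeric(8))
  oracle <- mean(dist(t(M))) / sd(as.vector(R))   # direct formula
  expect_equal(psi_index(R, g), oracle)
  expect_equal(psi_index(5 * R, g), psi_index(R, g), tolerance = 1e-12)
  expect_equal(psi_index(R + 7, g), psi_index(R, g), tolerance = 1e-12)
  expect_equal(psi_index(cbind(R[, 1], R[, 1]), c("a", "b")), 0)
  expect_error(psi_index(R, rep("a", 30)), "groups")
})

test_that("debiased identity PSI removes the trial-noise floor", {
  set.seed(13)
  n_cells <- 40; n_id <- 30
  signal <- matrix(rnorm(n_cells * n_id), n_cells)
  noise_only1 <- matrix(rnorm(n_cells * n_id, sd = 2), n_cells)
  noise_only2 <- matrix(rnorm(n_cells * n_id, sd = 2), n_cells)
  # pure noise: plain PSI sits at sqrt(2 N); debiased is near zero
  plain <- psi_index(noise_only1, colnames(noise_only1, do.NULL = FALSE))
  expect_gt(plain, 0.8 * sqrt(2 * n_cells))
  deb <- axisdyn:::psi_index_debiased(noise_only1, noise_only2)
  expect_lt(deb, 0.25 * sqrt(2 * n_cells))
  # with signal the debiased statistic responds
  deb2 <- axisdyn:::psi_index_debiased(signal + 0.5 * noise_only1,
                                       signal + 0.5 * noise_only2)
  expect_gt(deb2, 5 * deb)
})

test_that("dimensionality for 90% variance is 1 for rank-one responses", {
  rates <- array(0, dim = c(6, 40, 300))
  u <- c(1, 2, 3, 4, 5, 6); v <- seq(0.5, 4, length.out = 40)
  for (t in 1:300) rates[, , t] <- outer(u, v)
  pop <- response_tensor(rates, 0:299, rep(c("face", "object"), each = 20))
  out <- dims_for_variance(pop, n_boot = 20, seed = 2)
  expect_equal(out$summary$n_dims, c(1, 1))
})

test_that("emergent tuning inflates late-window dimensionality", {
  fx <- fx_small()
  out <- dims_for_variance(fx$pop, n_boot = 50, seed = 3)
  expect_gt(out$summary$n_dims[2], out$summary$n_dims[1])
  expect_gte(out$frac_long_gt_short, 0.95)
  expect_lt(out$paired_t$p.value, 0.05)
})

test_that("response-PC pseudo-units track the axis switch", {
  fx <- fx_small()
  out <- response_pc_pseudo_units(fx$pop, fx$features, k_extremes = 5,
                                  windows = sliding_windows(60, 200),
                                  split = fx$split)
  pc1_face <- dplyr::filter(out, .data$pc == 1, .data$category == "face")
  early <- pc1_face$top_ids[[which(pc1_face$window_start == 80)]]
  late <- pc1_face$top_ids[[which(pc1_face$window_start == 140)]]
  expect_lt(length(intersect(early, late)), 5)  # membership changes
  # full-category extremes partition the faces
  out2 <- response_pc_pseudo_units(fx$pop, fx$features, k_extremes = 60,
                                   windows = cbind(80, 100), n_pcs = 1,
                                   split = fx$split)
  ids <- sort(unique(c(out2$top_ids[[1]], out2$bottom_ids[[1]])))
  expect_equal(ids, sort(fx$pop$ids[fx$pop$category == "face"]))
})

test_that("the axis-change score maps pattern reversal to faceness", {
  # hand-built population: faces reverse their pattern, objects repeat it
  set.seed(21)
  n_cells <- 12; n_stim <- 40
  early_pat <- matrix(rexp(n_cells * n_stim, rate = 0.1), n_cells)
  late_pat <- early_pat
  faces <- 1:20
  late_pat[, faces] <- max(early_pat) - early_pat[, faces]  # anti-correlated
  rates <- array(1, dim = c(n_cells, n_stim, 350))
  rates[, , 111:130] <- rates[, , 111:130] + rep(early_pat, 20)  # 60-80 ms
  rates[, , 151:170] <- rates[, , 151:170] + rep(late_pat, 20)   # 100-120 ms
  pop <- response_tensor(rates, -50:299,
                         ifelse(seq_len(n_stim) %in% faces, "face", "object"))
  sc <- axis_change_score(pop, seed = 2)
  expect_lt(max(sc$scores$early_late_corr[faces]),
            min(sc$scores$early_late_corr[-faces]))
  expect_gt(min(sc$scores$score[faces]), max(sc$scores$score[-faces]))
  expect_lt(sc$coefficients[["rho"]], 0)
  # invariant to cell order
  pop2 <- pop; pop2$rates <- pop$rates[rev(seq_len(n_cells)), , ]
  sc2 <- axis_change_score(pop2, seed = 2)
  expect_equal(sc2$scores$score, sc$scores$score, tolerance = 1e-10)
})

test_that("cell selectivity metrics support the inclusion rules", {
  fx <- fx_small()
  m <- cell_selectivity(fx$pop)
  expect_true(all(m$responsive_p < 0.05))
  expect_true(all(m$fsi >= -1 & m$fsi <= 1))
  expect_gt(median(m$peak_dprime), 0.2)
})
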