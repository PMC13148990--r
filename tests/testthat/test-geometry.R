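test_that("axis decomposition satisfies its exact identities", {
  d <- decompose_axis(c(1, 0), c(1, 1))
  expect_equal(d$v_par, c(1, 0)); expect_equal(d$v_perp, c(0, 1))

  d2 <- decompose_axis(c(2, 0), c(3, 4))
  expect_equal(d2$v_perp, c(0, 4))   # unit-normalized v1 convention

  d3 <- decompose_axis(c(1, 2, 3), 2 * c(1, 2, 3))
  expect_true(d3$no_new_tuning)

  expect_error(decompose_axis(c(0, 0), c(1, 1)), "zero")

  set.seed(9)
  for (i in 1:25) {
    v1 <- rnorm(8); v2 <- rnorm(8)
    d <- decompose_axis(v1, v2)
    expect_equal(d$v_par + d$v_perp, v2, tolerance = 1e-10)
    expect_lt(abs(sum(d$v_perp * v1)), 1e-10)
    expect_equal(sum(d$v_par^2) + sum(d$v_perp^2), sum(v2^2), tolerance = 1e-10)
  }
})

test_that("decomposition is equivariant to joint rotations", {
  set.seed(10)
  v1 <- rnorm(6); v2 <- rnorm(6)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  d <- decompose_axis(v1, v2)
  dq <- decompose_axis(as.vector(Q %*% v1), as.vector(Q %*% v2))
  expect_equal(dq$v_perp, as.vector(Q %*% d$v_perp), tolerance = 1e-8)
})

test_that("the principal orthogonal direction is orthogonal and variance-optimal", {
  set.seed(11)
  F_ <- matrix(rnorm(300 * 5), 300, 5)
  v <- rnorm(5)
  pod <- principal_orthogonal_direction(F_, v)
  expect_equal(sum(pod^2), 1, tolerance = 1e-10)
  expect_lt(abs(sum(pod * v / sqrt(sum(v^2)))), 1e-8)

  # if v_perp is PC1, the result is PC2 (eigendecomposition oracle)
  F2 <- matrix(rnorm(500 * 4), 500, 4) %*% diag(c(3, 2, 1, 0.5))
  F2 <- sweep(F2, 2, colMeans(F2))
  ev <- eigen(stats::cov(F2), symmetric = TRUE)$vectors
  pod2 <- principal_orthogonal_direction(F2, ev[, 1])
  expect_gt(abs(sum(pod2 * ev[, 2])), 0.999)

  # features confined to a 2-D plane containing v_perp
  basis <- qr.Q(qr(matrix(rnorm(25), 5, 5)))[, 1:2]
  F3 <- matrix(rnorm(200 * 2), 200, 2) %*% t(basis)
  pod3 <- principal_orthogonal_direction(F3, basis[, 1])
  expect_gt(abs(sum(pod3 * basis[, 2])), 0.999)
})

test_that("sampling along a direction uses sigma-scaled multipliers", {
  set.seed(12)
  F_ <- matrix(rnorm(400 * 3), 400, 3)
  v <- c(0, 0, 2)
  out <- sample_along_direction(v, F_)
  expect_equal(nrow(out), 7)
  expect_equal(out$multiplier, c(-4, -2, -1, 0, 1, 2, 4))
  expect_equal(out$point[[4]], c(0, 0, 0))
  sigma <- sd(F_[, 3])
  proj <- vapply(out$point, function(p) sum(p * c(0, 0, 1)), numeric(1))
  expect_equal(proj, c(-4, -2, -1, 0, 1, 2, 4) * sigma, tolerance = 1e-12)
})

test_that("recovered new tuning concentrates on the generating dimensions", {
  fx <- fx_small()
  windows <- sliding_windows(0, 240)
  tcf <- sliding_axes(fx$pop, fx$features, "face", windows, fx$split)
  a <- which(windows[, 1] == 80); b <- which(windows[, 1] == 120)
  truth_late <- truth_axes_in_space(fx$truth, fx$space, "late")
  conc <- vapply(1:20, function(j) {
    d <- decompose_axis(tcf$axes[a, j, ], tcf$axes[b, j, ])
    perp_concentration(d$v_perp, 4:12)   # the generating new-dimension block
  }, numeric(1))
  expect_gte(median(conc), 0.8)
  # and the late axes themselves are recovered
  cl <- vapply(1:20, function(j) {
    abs(sum(tcf$axes[b, j, ] * truth_late[j, ])) /
      sqrt(sum(tcf$axes[b, j, ]^2) * sum(truth_late[j, ]^2))
  }, numeric(1))
  expect_gte(median(cl), 0.8)
})
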