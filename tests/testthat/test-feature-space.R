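test_that("collinear points yield a one-dimensional space", {
  emb <- outer(c(-1, 0, 2), c(1, 2, 3))
  sp <- fit_feature_space(emb, K = 1)
  expect_equal(sp$explained_variance_ratio, 1)
})

test_that("an isotropic cloud spreads variance evenly over components", {
  set.seed(42)
  emb <- matrix(rnorm(10000 * 10), 10000, 10)
  sp <- fit_feature_space(emb, K = 10)
  expect_true(all(abs(sp$explained_variance_ratio - 0.1) < 0.02))
})

test_that("the fit is deterministic, orthonormal and ordered", {
  emb <- fx_small()$stimuli$embeddings
  a <- fit_feature_space(emb, K = 8)
  b <- fit_feature_space(emb, K = 8)
  expect_identical(a$components, b$components)   # sign convention fixes PCA
  gram <- t(a$components) %*% a$components
  expect_equal(gram, diag(8), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(a$explained_variance_ratio) <= 1e-12))
  expect_true(all(a$scale > 0))
})

test_that("projection normalizes the fitting set and centres the mean", {
  emb <- fx_small()$stimuli$embeddings
  sp <- fit_feature_space(emb, K = 6)
  F_ <- project_features(sp, emb)
  expect_lt(max(abs(colMeans(F_))), 1e-6)
  expect_equal(unname(apply(F_, 2, sd)), rep(1, 6), tolerance = 1e-6)
  expect_equal(unname(project_features(sp, rbind(sp$mean))[1, ]), rep(0, 6))
  expect_error(project_features(sp, emb[, 1:3]), "dimension")
})

test_that("rank-K reconstruction matches the eigendecomposition optimum", {
  emb <- matrix(rnorm(200 * 20), 200, 20) %*% diag(seq(2, 0.5, length.out = 20))
  K <- 5
  sp <- fit_feature_space(emb, K = K)
  F_ <- project_features(sp, emb)
  recon <- (F_ %*% diag(sp$scale)) %*% t(sp$components) +
    rep(sp$mean, each = nrow(emb))
  err <- sum((recon - emb)^2)
  ev <- eigen(stats::cov(emb), symmetric = TRUE)$values   # oracle
  expect_equal(err, sum(ev[(K + 1):20]) * (nrow(emb) - 1), tolerance = 1e-8)
})

test_that("rank-deficient embeddings report the attainable dimensionality", {
  emb <- matrix(rnorm(50 * 3), 50, 3) %*% matrix(rnorm(3 * 10), 3, 10)
  expect_error(fit_feature_space(emb, K = 5), "K <= 3")
})

test_that("gaussian subsets drop low-density outliers", {
  F_ <- cbind(c(0, 0.1, -0.1, 10))
  out <- gaussian_subset(F_, rep("face", 4), n_keep = 3,
                         ids = c("a", "b", "c", "d"))
  expect_false(out$kept[out$id == "d"])
  expect_equal(sum(out$kept), 3)

  # spherical cloud: the kept half sits at smaller radius than the dropped half
  X <- matrix(rnorm(400 * 3), 400, 3)
  sub <- gaussian_subset(X, rep("object", 400), n_keep = 200)
  r <- sqrt(rowSums(X^2))
  expect_lt(mean(r[sub$kept]), mean(r[!sub$kept]))

  # exact-size category returns everything
  all_kept <- gaussian_subset(X[1:10, ], rep("object", 10), n_keep = 10)
  expect_true(all(all_kept$kept))
})
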