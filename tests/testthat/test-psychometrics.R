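test_that("KMO has its two-variable and block-diagonal closed forms", {
  R2 <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  expect_equal(kmo(R2)$kmo_overall, 0.5, tolerance = 1e-12)

  # two independent pairs with r = 0.8: within-pair partials equal the
  # correlations, so the overall measure stays at 1/2
  R4 <- diag(4)
  R4[1, 2] <- R4[2, 1] <- 0.8
  R4[3, 4] <- R4[4, 3] <- 0.8
  res <- kmo(R4)
  expect_equal(res$kmo_overall, 0.5, tolerance = 1e-12)
  expect_equal(unname(res$kmo_per_item), rep(0.5, 4), tolerance = 1e-12)

  singular <- matrix(1, 3, 3)
  expect_error(kmo(singular), "singular")
})

test_that("KMO equals the explicit anti-image computation", {
  for (s in 1:30) {
    R <- random_corr(sample(4:8, 1), seed = s)
    expect_equal(kmo(R)$kmo_overall, oracle_kmo(R), tolerance = 1e-10)
  }
})

test_that("Bartlett sphericity follows its closed form", {
  expect_equal(bartlett_sphericity(diag(5), n = 100)$bartlett_chi2, 0)
  expect_equal(bartlett_sphericity(diag(7), n = 454)$bartlett_df, 21L)

  R <- matrix(0.5, 3, 3)
  diag(R) <- 1
  res <- bartlett_sphericity(R, n = 100)
  hand <- -(100 - 1 - (2 * 3 + 5) / 6) * log(det(R))
  expect_equal(res$bartlett_chi2, hand, tolerance = 1e-12)
  expect_equal(res$bartlett_df, 3L)

  # chi-square is zero iff the matrix is the identity
  set.seed(2)
  for (i in 1:10) {
    R <- random_corr(5, seed = 100 + i)
    expect_gt(bartlett_sphericity(R, n = 50)$bartlett_chi2, 0)
  }
})

test_that("Kaiser retention and varimax rotation behave on boundary cases", {
  expect_warning(res <- pca_varimax(diag(7)), "nothing retained")
  expect_equal(res$retained_components, 0L)
  expect_equal(res$eigenvalues, rep(1, 7))

  # two disjoint perfectly correlated pairs span the space with 2 components
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 1
  R[3, 4] <- R[4, 3] <- 1
  res <- pca_varimax(R)
  expect_equal(res$retained_components, 2L)
  expect_equal(res$cumulative_explained_variance, 100, tolerance = 1e-8)
  expect_equal(sum(res$eigenvalues), 4, tolerance = 1e-8)
})

test_that("varimax PCA recovers a planted two-factor structure", {
  set.seed(77)
  n <- 454
  f1 <- rnorm(n)
  f2 <- rnorm(n)
  load <- cbind(c(0.8, 0.8, 0.8, 0.8, 0, 0, 0), c(0, 0, 0, 0, 0.8, 0.8, 0.8))
  X <- cbind(f1, f2) %*% t(load) + matrix(rnorm(n * 7, 0, 0.6), n, 7)
  res <- pca_varimax(X)
  expect_equal(res$retained_components, 2L)
  assign <- apply(abs(res$rotated_loadings), 1, which.max)
  expect_equal(length(unique(assign[1:4])), 1L)
  expect_equal(length(unique(assign[5:7])), 1L)
  expect_false(assign[1] == assign[5])
  # rotation preserves communalities and total retained variance
  eig <- eigen(cor(X), symmetric = TRUE)
  raw_load <- eig$vectors[, 1:2] %*% diag(sqrt(eig$values[1:2]))
  expect_equal(unname(res$communalities), rowSums(raw_load^2),
               tolerance = 1e-8)
  expect_equal(sum(res$rotated_loadings^2), sum(raw_load^2),
               tolerance = 1e-8)
  # reproducible orientation: each column's largest loading is positive
  expect_true(all(apply(res$rotated_loadings, 2,
                        function(col) col[which.max(abs(col))] > 0)))
})

test_that("Cronbach's alpha matches closed forms and the variance ratio", {
  # three parallel items with r = 0.5: alpha = 3r/(1+2r) = 0.75
  R <- matrix(0.5, 3, 3)
  diag(R) <- 1
  X <- exact_corr_data(200, R, seed = 12)
  expect_equal(cronbach_alpha(X), 0.75, tolerance = 1e-10)

  two <- cbind(a = rnorm(50), b = 0)
  two[, "b"] <- two[, "a"]
  expect_equal(cronbach_alpha(two), 1)

  set.seed(13)
  for (i in 1:20) {
    X <- matrix(rnorm(60 * 5), 60, 5) + rnorm(60)
    k <- ncol(X)
    direct <- k / (k - 1) *
      (1 - sum(apply(X, 2, var)) / var(rowSums(X)))
    expect_equal(cronbach_alpha(X), direct, tolerance = 1e-12)
    # invariance under positive rescaling of all items
    expect_equal(cronbach_alpha(3.7 * X + 2), cronbach_alpha(X),
                 tolerance = 1e-10)
  }
  expect_error(cronbach_alpha(matrix(1, 4, 3)), "zero variance")
})
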