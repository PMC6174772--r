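test_that("standardizer centers and scales training columns", {
  s <- fitStandardizer(matrix(c(1, 3), 2, 1))
  expect_equal(applyStandardizer(s, matrix(c(1, 3), 2, 1)),
               matrix(c(-1, 1), 2, 1))

  X <- cbind(a = c(2, 2, 2), b = c(0, 1, 2))
  s2 <- fitStandardizer(X)
  Z <- applyStandardizer(s2, X)
  expect_equal(Z[, 1], rep(0, 3))          # constant column -> zeros
  expect_equal(mean(Z[, 2]), 0)
  expect_equal(sqrt(mean(Z[, 2]^2)), 1)    # unit population sd

  # applying to a training row reproduces its transformed value
  expect_equal(applyStandardizer(s2, X[2, ]), Z[2, ])
  expect_error(fitStandardizer(matrix(numeric(0), 0, 1)), "empty")
  expect_error(applyStandardizer(s2, c(1, 2, 3)), "dimension mismatch")
})

test_that("barycentric weight rows sum to one and reconstruct affine data", {
  set.seed(2)
  B <- matrix(rnorm(20), 2, 10)
  X <- matrix(runif(16, -1, 1), 8, 2) %*% B   # exact 2-D affine subspace
  D2 <- as.matrix(dist(X))^2
  for (i in 1:8) {
    d2 <- D2[i, ]; d2[i] <- Inf
    nb <- order(d2)[1:4]
    w <- elrdd:::lleWeights(X[i, ], X[nb, , drop = FALSE])
    expect_lt(abs(sum(w) - 1), 1e-10)
    res <- sqrt(sum((X[i, ] - drop(w %*% X[nb, , drop = FALSE]))^2))
    expect_lt(res, 1e-8)
  }

  # generic full-rank neighbourhoods still satisfy the sum constraint
  Xg <- matrix(rnorm(100), 10, 10)
  D2g <- as.matrix(dist(Xg))^2
  for (i in 1:10) {
    d2 <- D2g[i, ]; d2[i] <- Inf
    nb <- order(d2)[1:5]
    w <- elrdd:::lleWeights(Xg[i, ], Xg[nb, , drop = FALSE])
    expect_lt(abs(sum(w) - 1), 1e-10)
  }
})

test_that("embedding of affine data is an affine chart of the data", {
  # knn = 5 of 7 keeps the neighbour graph connected; a sparser graph can
  # split into components whose indicators enter the null space of M
  for (s in c(2, 4)) {
    set.seed(s)
    B <- matrix(rnorm(20), 2, 10)
    X <- matrix(runif(16, -1, 1), 8, 2) %*% B
    map <- fitLLE(X, knn = 5, d = 2)
    fit <- lm.fit(cbind(1, map@coords), X)   # brute-force affine fit
    expect_lt(max(abs(fit$residuals)), 1e-6)
  }
})

test_that("embedding matches an independent dense eigendecomposition", {
  set.seed(7)
  X6 <- matrix(rnorm(6 * 4), 6, 4)
  m6 <- fitLLE(X6, knn = 3, d = 1)
  expect_equal_up_to_sign(m6@coords, oracleLLE(X6, 3, 1), 1e-6)

  X8 <- matrix(rnorm(8 * 5), 8, 5)
  m8 <- fitLLE(X8, knn = 4, d = 3)
  expect_equal_up_to_sign(m8@coords, oracleLLE(X8, 4, 3), 1e-6)

  # embedding coordinates are centered with unit variance
  expect_lt(max(abs(colMeans(m8@coords))), 1e-8)
  expect_equal(apply(m8@coords, 2, sd), rep(1, 3))
})

test_that("out-of-sample transform extends the training embedding", {
  set.seed(9)
  X <- matrix(rnorm(20 * 6), 20, 6)
  map <- fitLLE(X, knn = 5, d = 2)

  # a duplicate of a training point gets that point's coordinates
  expect_lt(max(abs(transformLLE(map, X[7, ]) - map@coords[7, ])), 1e-8)

  # transforming all training points reproduces the training embedding
  expect_lt(max(abs(transformLLE(map, X) - map@coords)), 1e-6)

  # midpoint of two adjacent points on a line maps to the midpoint of
  # their embeddings (knn = 2: symmetric exact weight system)
  Xl <- matrix(seq(0, 1, length.out = 10), ncol = 1)
  ml <- fitLLE(Xl, knn = 2, d = 1)
  mid <- transformLLE(ml, matrix(mean(Xl[4:5, 1]), 1, 1))
  expect_lt(abs(mid - mean(ml@coords[4:5, 1])), 1e-6)

  expect_error(transformLLE(map, rnorm(5)), "dimension mismatch")
})

test_that("embedding is rotation-invariant up to coordinate signs", {
  set.seed(13)
  X <- matrix(rnorm(15 * 8), 15, 8)
  Q <- qr.Q(qr(matrix(rnorm(64), 8, 8)))
  m1 <- fitLLE(X, knn = 5, d = 2)
  m2 <- fitLLE(X %*% Q, knn = 5, d = 2)
  expect_equal_up_to_sign(m1@coords, m2@coords, 1e-6)
})

test_that("degenerate and invalid embedding inputs are rejected", {
  X <- matrix(rnorm(12), 6, 2)
  expect_error(fitLLE(X, knn = 6, d = 1), "knn")
  expect_error(fitLLE(X, knn = 3, d = 6), "d")
  expect_error(fitLLE(matrix(1, 5, 3), knn = 2, d = 1), "identical")
})
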