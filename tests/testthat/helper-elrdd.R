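# Shared fixtures (built in code) and independent oracles.

# tiny 92-feature schema for fast unit tests
tinySchema <- function() {
  FeatureSchema(data.frame(
    category = c("MFCC", "PROS", "PROS", "SPEC", "SPEC", "GLOT"),
    subcategory = c("m1", "p1", "p2", "s1", "s2", "g1"),
    count = c(24L, 24L, 12L, 12L, 12L, 8L)))
}

# quarter-scale schema keeping the real category-width proportions
# (MFCC 630 : PROS 952 : SPEC 378 : GLOT 32); used for the simulation suites
quarterSchema <- function() {
  FeatureSchema(data.frame(
    category = c("MFCC", "PROS", "PROS", "PROS", "SPEC", "SPEC", "GLOT"),
    subcategory = c("m1", "p1", "p2", "p3", "s1", "s2", "g1"),
    count = c(158L, 120L, 80L, 38L, 52L, 42L, 8L)))
}

tinyDataset <- function(seed = 3L, perCell = 4L, recordings = 10L,
                        schema = tinySchema(), ...) {
  generateDataset(syntheticConfig(
    counts = c(maleControl = perCell, femaleControl = perCell,
               maleDepressed = perCell, femaleDepressed = perCell),
    recordingsPerSubject = recordings, schema = schema, seed = seed, ...))
}

# Independent dense LLE oracle: neighbour search by full sort, weights by
# the same regularized Gram rule re-derived here, embedding by explicit
# projection onto the complement of the constant vector followed by an SVD
# of the projected quadratic form (instead of the package's rank-1
# deflation + eigen route).
oracleLLE <- function(X, knn, d) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D[i, ]
    di[i] <- Inf
    nb <- order(di)[seq_len(knn)]
    Q <- sweep(X[nb, , drop = FALSE], 2L, X[i, ], "-")
    C <- Q %*% t(Q)
    tr <- sum(diag(C))
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    lam <- if (min(ev) < tr * 1e-9) tr * 1e-12 else tr * 1e-3 / knn
    w <- solve(C + diag(lam, knn), rep(1, knn))
    W[i, nb] <- w / sum(w)
  }
  M <- t(diag(n) - W) %*% (diag(n) - W)
  ones <- rep(1 / sqrt(n), n)
  P <- diag(n) - ones %*% t(ones)
  Mp <- P %*% M %*% P
  sv <- svd(Mp)
  # ascending singular values; the very smallest is the projected-out
  # constant direction, the next d are the embedding
  ord <- order(sv$d)
  Y <- sv$u[, ord[2:(d + 1L)], drop = FALSE]
  Y <- sweep(Y, 2L, colMeans(Y), "-")
  sweep(Y, 2L, apply(Y, 2L, sd), "/")
}

# compare embeddings coordinate-wise up to sign
expect_equal_up_to_sign <- function(A, B, tolerance = 1e-6) {
  for (j in seq_len(ncol(A))) {
    err <- min(max(abs(A[, j] - B[, j])), max(abs(A[, j] + B[, j])))
    expect_lt(err, tolerance)
  }
}

# replace every base-classifier weight vector of a fitted model with zeros
zeroWeightModel <- function(model) {
  model@classifiers <- lapply(model@classifiers, function(b) {
    b@weights <- rep(0, length(b@weights))
    b
  })
  model
}
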