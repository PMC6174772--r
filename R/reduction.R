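#' Fit / apply a per-column standardizer
#'
#' Columns are centered to their training mean and scaled to unit training
#' standard deviation; standard deviations are floored at 1e-8, so constant
#' columns map to exactly zero after centering.
#'
#' @param X numeric training matrix (observations in rows), non-empty and
#'   finite.
#' @return \code{fitStandardizer} returns a \linkS4class{Standardizer}.
#' @export
fitStandardizer <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty input")
  if (any(!is.finite(X))) stop("input must be finite")
  ctr <- colMeans(X)
  # population standard deviation: a two-point column {1, 3} maps to {-1, 1}
  scl <- sqrt(colMeans(sweep(X, 2L, ctr, "-")^2))
  scl <- pmax(scl, 1e-8)
  new("Standardizer", center = as.numeric(ctr), scale = as.numeric(scl))
}

#' @rdname fitStandardizer
#' @param s a fitted \linkS4class{Standardizer}.
#' @param x numeric vector or matrix (rows = observations) with the same
#'   number of columns the standardizer was fitted on.
#' @return \code{applyStandardizer} returns the transformed vector/matrix.
#' @export
applyStandardizer <- function(s, x) {
  if (is.null(dim(x))) {
    if (length(x) != length(s@center)) stop("dimension mismatch")
    return((x - s@center) / s@scale)
  }
  if (ncol(x) != length(s@center)) stop("dimension mismatch")
  sweep(sweep(x, 2L, s@center, "-"), 2L, s@scale, "/")
}

# Solve the barycentric reconstruction weights of x against the rows of
# `nbrs` (its k nearest neighbours).  Minimizes ||x - sum w_j n_j|| subject
# to sum(w) = 1 through the local Gram system C = Q Q', Q = rows (n_j - x).
# Regularization is adaptive: the standard trace ridge tr(C)*1e-3/k when C
# is numerically full rank, and a vanishing ridge tr(C)*1e-12 when C is
# rank-deficient -- the latter makes the solution collapse onto an exact
# affine reconstruction (duplicate points, data on a low-dimensional affine
# subspace) instead of smearing weight across all neighbours.
lleWeights <- function(x, nbrs) {
  k <- nrow(nbrs)
  Q <- sweep(nbrs, 2L, x, "-")
  C <- tcrossprod(Q)
  tr <- sum(diag(C))
  if (tr <= 0) return(rep(1 / k, k))        # all neighbours identical to x
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  lam <- if (min(ev) < tr * 1e-9) tr * 1e-12 else tr * 1e-3 / k
  w <- solve(C + diag(lam, k), rep(1, k))
  w / sum(w)
}

# k nearest training rows to x (Euclidean), ties broken by lowest index.
# `d2` is the vector of squared distances to all training rows.
nearestIdx <- function(d2, k) order(d2)[seq_len(k)]

#' Fit a locally linear embedding
#'
#' Classic LLE: for each training point, barycentric reconstruction weights
#' over its \code{knn} Euclidean nearest neighbours (regularized local Gram
#' solve, ties broken by lowest training index), then the embedding
#' coordinates are eigenvectors of \eqn{M = (I-W)'(I-W)} for the \code{d}
#' smallest eigenvalues after deflating the trivial constant direction.
#' Each coordinate is scaled to unit variance over the training points, and
#' its sign is fixed by making the largest-magnitude loading positive.
#'
#' @param X standardized training matrix (n x p), n > knn.
#' @param knn neighbour count (1 <= knn < n).
#' @param d target dimension (1 <= d < n).
#' @return an \linkS4class{EmbeddingMap}.
#' @export
fitLLE <- function(X, knn = 12L, d = min(30L, nrow(X) - 2L)) {
  X <- as.matrix(X)
  n <- nrow(X)
  knn <- as.integer(knn); d <- as.integer(d)
  if (knn < 1L || knn >= n) stop("need 1 <= knn < n")
  if (d < 1L || d >= n) stop("need 1 <= d < n")
  if (all(apply(X, 2L, function(col) max(col) == min(col))))
    stop("degenerate input: all points identical")

  D2 <- squaredDistances(X, X)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d2 <- D2[i, ]
    d2[i] <- Inf
    nb <- nearestIdx(d2, knn)
    W[i, nb] <- lleWeights(X[i, ], X[nb, , drop = FALSE])
  }

  IW <- diag(n) - W
  M <- crossprod(IW)
  # deflate the constant eigenvector (M 1 = 0) by lifting it with a rank-1
  # term; M is symmetric with 1 as an exact eigenvector, so the remaining
  # spectrum on the orthogonal complement is untouched
  shift <- sum(diag(M)) + 1
  M <- M + (shift / n) * matrix(1, n, n)
  es <- eigen(M, symmetric = TRUE)
  sel <- seq.int(n, by = -1L, length.out = d)   # ascending eigenvalue order
  Y <- es$vectors[, sel, drop = FALSE]
  Y <- sweep(Y, 2L, colMeans(Y), "-")
  sdY <- apply(Y, 2L, sd)
  sdY[sdY < 1e-12] <- 1
  Y <- sweep(Y, 2L, sdY, "/")
  for (j in seq_len(d)) {
    top <- which.max(abs(Y[, j]))
    if (Y[top, j] < 0) Y[, j] <- -Y[, j]
  }
  new("EmbeddingMap", points = X, knn = knn, dim = d, coords = Y)
}

#' Out-of-sample LLE transform
#'
#' Deterministic nonparametric extension: each new point is assigned the
#' barycentric-weight combination of its \code{knn} nearest training
#' points' embedding coordinates, with the same neighbour rule and local
#' Gram regularization used at fit time.  A point that coincides with a
#' training point therefore reproduces that point's coordinates.
#'
#' @param map a fitted \linkS4class{EmbeddingMap}.
#' @param x numeric vector (one standardized point) or matrix of points in
#'   rows.
#' @return embedding coordinates: a length-\code{d} vector for vector input,
#'   an m x d matrix for matrix input.
#' @export
transformLLE <- function(map, x) {
  single <- is.null(dim(x))
  Xn <- if (single) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(Xn) != ncol(map@points)) stop("dimension mismatch")
  D2 <- squaredDistances(Xn, map@points)
  out <- matrix(0, nrow(Xn), map@dim)
  for (i in seq_len(nrow(Xn))) {
    nb <- nearestIdx(D2[i, ], map@knn)
    w <- lleWeights(Xn[i, ], map@points[nb, , drop = FALSE])
    out[i, ] <- drop(w %*% map@coords[nb, , drop = FALSE])
  }
  if (single) drop(out) else out
}

# pairwise squared Euclidean distances between rows of A and rows of B,
# clipped at zero against cancellation
squaredDistances <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

setMethod("show", "EmbeddingMap", function(object) {
  cat(sprintf("EmbeddingMap: %d training points, %d -> %d dims, knn = %d\n",
              nrow(object@points), ncol(object@points), object@dim,
              object@knn))
})
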