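#' Bernoulli log-likelihood of a logistic model
#'
#' Computes \eqn{\sum_i [ y_i (w \cdot z_i) - \log(1 + e^{w \cdot z_i}) ]}
#' overflow-safely for large linear predictors.
#'
#' @param w weight vector (length = ncol(Z); if the model has an intercept
#'   it must be a column of ones inside \code{Z}).
#' @param Z design matrix (n x length(w)).
#' @param y binary response in \{0, 1\}.
#' @return the scalar log-likelihood.
#' @examples
#' Z <- cbind(rnorm(10), 1)
#' baseLogLikelihood(c(0, 0), Z, rbinom(10, 1, 0.5))   # -10 log 2
#' @export
baseLogLikelihood <- function(w, Z, y) {
  Z <- as.matrix(Z)
  if (ncol(Z) != length(w)) stop("dimension mismatch: ncol(Z) != length(w)")
  if (nrow(Z) != length(y)) stop("dimension mismatch: nrow(Z) != length(y)")
  eta <- drop(Z %*% w)
  # log(1 + e^eta) = max(eta, 0) + log1p(exp(-|eta|))
  sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

# penalized log-likelihood; `pen` masks the intercept out of the ridge term
penalizedLL <- function(w, Z, y, lambda, pen) {
  baseLogLikelihood(w, Z, y) - lambda / 2 * sum((w * pen)^2)
}

#' Fit one logistic base classifier by penalized maximum likelihood
#'
#' Maximizes the Bernoulli log-likelihood minus a ridge penalty
#' \eqn{(\lambda/2)\|w\|^2} on the non-intercept weights, by Newton-Raphson
#' with step halving (gradient-ascent fallback when the Hessian solve
#' fails).  Convergence is declared when the gradient infinity-norm drops
#' below 1e-8; after 200 iterations the best iterate is returned with a
#' warning.
#'
#' @param Z numeric matrix of predictors (n x d), without an intercept
#'   column; a constant-1 coordinate is appended internally so the intercept
#'   is the last weight and is never penalized.
#' @param y binary response in \{0, 1\}; both classes must be present.
#' @param lambda ridge penalty (>= 0) on the non-intercept weights.
#' @return list with \code{weights} (length d + 1, intercept last),
#'   \code{converged}, \code{iterations} and the final penalized
#'   log-likelihood \code{value}.
#' @export
fitBaseClassifier <- function(Z, y, lambda = 1) {
  Z <- as.matrix(Z)
  y <- as.numeric(y)
  n <- nrow(Z)
  if (n < 2L) stop("need at least 2 observations")
  if (length(y) != n) stop("dimension mismatch")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("single-class response: both depressed (1) and control (0) ",
         "examples are required to fit a base classifier")
  if (lambda < 0) stop("lambda must be >= 0")

  Zi <- cbind(Z, 1)
  p1 <- ncol(Zi)
  pen <- c(rep(1, p1 - 1L), 0)
  w <- numeric(p1)
  f <- penalizedLL(w, Zi, y, lambda, pen)
  converged <- FALSE
  iter <- 0L
  while (iter < 200L) {
    iter <- iter + 1L
    mu <- plogis(drop(Zi %*% w))
    g <- drop(crossprod(Zi, y - mu)) - lambda * (w * pen)
    if (max(abs(g)) < 1e-8) { converged <- TRUE; break }
    wt <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Zi * wt, Zi) + diag(lambda * pen + 1e-12, p1)
    step <- tryCatch(solve(H, g), error = function(e) g / max(abs(g)))
    ok <- FALSE
    for (h in 0:30) {
      wNew <- w + step / 2^h
      fNew <- penalizedLL(wNew, Zi, y, lambda, pen)
      if (is.finite(fNew) && fNew > f) { w <- wNew; f <- fNew; ok <- TRUE; break }
    }
    if (!ok) {  # no ascent possible along the Newton direction; stop here
      mu <- plogis(drop(Zi %*% w))
      g <- drop(crossprod(Zi, y - mu)) - lambda * (w * pen)
      converged <- max(abs(g)) < 1e-6
      break
    }
  }
  if (!converged && iter >= 200L)
    warning("logistic fit did not converge in 200 iterations; ",
            "returning best iterate")
  list(weights = w, converged = converged, iterations = iter, value = f)
}
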