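#' Configuration of the synthetic speech-feature generator
#'
#' Describes the hierarchical generative model that stands in for the
#' clinical corpus: gender-by-label subject cells, a fixed number of
#' recordings per subject, and a per-category low-rank latent structure
#' through which the class signal and the subject random effect enter the
#' feature blocks.  The default cell counts, recordings per subject and the
#' ordering of the per-category effect sizes (glottal weakest) mirror the
#' reference corpus composition (see
#' \code{\link{referenceDatabaseSummary}}).
#'
#' @param counts named subject counts per gender x label cell; defaults:
#'   maleControl 34, femaleControl 51, maleDepressed 32, femaleDepressed 53.
#' @param recordingsPerSubject recordings per subject (default 29).
#' @param schema \linkS4class{FeatureSchema} to generate under (default the
#'   1992-feature schema).
#' @param delta named standardized class effect size per category, on the
#'   latent signal coordinate; defaults MFCC 0.3, PROS 0.5, SPEC 0.5,
#'   GLOT 0.1.
#' @param sigmaSubject sd of the scalar subject random effect (default 0.5).
#' @param sigmaNoise sd of the per-feature recording noise (default 1).
#' @param latentDim latent manifold dimension per category (default 5).
#' @param seed integer seed; generation is fully reproducible from
#'   (config, seed).
#' @return named configuration list.
#' @export
syntheticConfig <- function(counts = c(maleControl = 34L, femaleControl = 51L,
                                       maleDepressed = 32L,
                                       femaleDepressed = 53L),
                            recordingsPerSubject = 29L,
                            schema = defaultSchema(),
                            delta = c(MFCC = 0.3, PROS = 0.5, SPEC = 0.5,
                                      GLOT = 0.1),
                            sigmaSubject = 0.5, sigmaNoise = 1,
                            latentDim = 5L, seed = 1L) {
  need <- c("maleControl", "femaleControl", "maleDepressed", "femaleDepressed")
  stopifnot(all(need %in% names(counts)), all(counts >= 0),
            recordingsPerSubject >= 1L, latentDim >= 1L,
            sigmaSubject >= 0, sigmaNoise >= 0)
  cats <- unique(schema@table$category)
  if (!all(cats %in% names(delta)))
    stop("delta must name every schema category")
  list(counts = vapply(counts[need], as.integer, integer(1)),
       recordingsPerSubject = as.integer(recordingsPerSubject),
       schema = schema, delta = delta[cats],
       sigmaSubject = sigmaSubject, sigmaNoise = sigmaNoise,
       latentDim = as.integer(latentDim), seed = as.integer(seed))
}

#' Generate a synthetic speech-feature dataset
#'
#' Hierarchical generative model.  Each subject s with label y gets a
#' scalar random effect \eqn{b_s \sim N(0, \sigma_b^2)}.  For each feature
#' category c and each recording, an m-dimensional latent vector is drawn
#' as \eqn{t \sim N(y \delta_c u + b_s v, I_m)} with fixed orthogonal unit
#' vectors u (class-signal direction) and v (subject-effect direction, when
#' m >= 2); the latent vector is mapped into the category's feature block
#' by a fixed random loading matrix and independent N(0, sigmaNoise^2)
#' feature noise is added.  The class signal therefore lives on a low-rank
#' latent structure inside each block rather than on raw feature means,
#' which puts the dimensionality-reduction step on the critical path of any
#' successful classification.
#'
#' @param config from \code{\link{syntheticConfig}}.
#' @return list with \code{dataset} (a \linkS4class{SpeechFeatureSet}) and
#'   \code{truth} (the generative parameters actually drawn: per-category
#'   loadings, u/v directions, effect sizes, subject effects, config).
#' @export
generateDataset <- function(config) {
  schema <- config$schema
  cats <- unique(schema@table$category)
  m <- config$latentDim
  cnt <- config$counts
  nSub <- sum(cnt)
  R <- config$recordingsPerSubject

  subj <- data.frame(
    subject_id = sprintf("S%03d", seq_len(nSub)),
    gender = rep(c("male", "female", "male", "female"), cnt),
    label = rep(c(0L, 0L, 1L, 1L), cnt),
    stringsAsFactors = FALSE)

  withSeed(config$seed, {
    loadings <- lapply(cats, function(cc) {
      p <- unname(categoryTotals(schema)[cc])
      matrix(rnorm(p * m), nrow = p, ncol = m)
    })
    names(loadings) <- cats
    u <- c(1, rep(0, m - 1L))
    v <- if (m >= 2L) c(0, 1, rep(0, m - 2L)) else u
    b <- rnorm(nSub, 0, config$sigmaSubject)

    nRec <- nSub * R
    recSubj <- rep(seq_len(nSub), each = R)
    y <- subj$label[recSubj]
    blocks <- lapply(cats, function(cc) {
      mu <- outer(y * config$delta[[cc]], u) + outer(b[recSubj], v)
      Tlat <- mu + matrix(rnorm(nRec * m), nRec, m)
      Tlat %*% t(loadings[[cc]]) +
        matrix(rnorm(nRec * categoryTotals(schema)[[cc]],
                     0, config$sigmaNoise),
               nrow = nRec)
    })
    features <- do.call(cbind, blocks)
    colnames(features) <- featureNames(schema)
    dataset <- SpeechFeatureSet(features,
                                subject_id = subj$subject_id[recSubj],
                                gender = subj$gender[recSubj],
                                label = y,
                                task_id = rep(seq_len(R), nSub),
                                schema = schema)
    S4Vectors::metadata(dataset)$seed <- config$seed
    truth <- list(loadings = loadings, u = u, v = v, delta = config$delta,
                  subjectEffects = setNames(b, subj$subject_id),
                  config = config)
    list(dataset = dataset, truth = truth)
  })
}

#' Recover the generative class effect sizes from a synthetic dataset
#'
#' For each category the latent coordinates are re-estimated by
#' least-squares inversion of the known loading matrix, and the effect size
#' is the difference of the class means of the latent signal coordinate
#' (the u-direction).  Because the subject-effect direction v is orthogonal
#' to u, the estimate is unbiased for the configured delta.
#'
#' @param dataset a synthetic \linkS4class{SpeechFeatureSet}.
#' @param truth the matching truth object from \code{\link{generateDataset}}.
#' @return named numeric vector of recovered per-category effect sizes.
#' @export
recoverEffects <- function(dataset, truth) {
  schema <- featureSchema(dataset)
  fm <- featureMatrix(dataset)
  y <- labels(dataset)
  cats <- unique(schema@table$category)
  vapply(cats, function(cc) {
    A <- truth$loadings[[cc]]
    X <- fm[, categoryColumns(schema, cc), drop = FALSE]
    That <- X %*% A %*% solve(crossprod(A))
    tu <- drop(That %*% truth$u)
    mean(tu[y == 1]) - mean(tu[y == 0])
  }, numeric(1))
}
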