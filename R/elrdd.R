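#' Training configuration for the ensemble
#'
#' @param knn LLE neighbour count (default 12).
#' @param dim LLE embedding dimension; \code{NULL} means
#'   \code{min(30, n_train - 2)} resolved at fit time.
#' @param lambda ridge penalty on non-intercept logistic weights (default 1;
#'   0 gives the unpenalized maximum-likelihood fit).
#' @param threshold decision threshold on the normalized ensemble
#'   probability s1/K (default 0.5; ties classified depressed).
#' @param seed integer seed recorded in the model metadata (the fit itself
#'   is deterministic).
#' @param genderMode "gdm" (gender-dependent: one model per gender) or
#'   "combined".
#' @param fusion subject-level fusion rule: "prob_sum" (sum of ensemble
#'   probability masses) or "majority" (vote over per-recording labels).
#' @return a named configuration list.
#' @export
elrddConfig <- function(knn = 12L, dim = NULL, lambda = 1, threshold = 0.5,
                        seed = 1L, genderMode = c("gdm", "combined"),
                        fusion = c("prob_sum", "majority")) {
  stopifnot(knn >= 1L, is.null(dim) || dim >= 1L, lambda >= 0,
            threshold > 0, threshold < 1)
  list(knn = as.integer(knn),
       dim = if (is.null(dim)) NULL else as.integer(dim),
       lambda = lambda, threshold = threshold, seed = as.integer(seed),
       genderMode = match.arg(genderMode), fusion = match.arg(fusion))
}

#' Fit the ensemble logistic regression model
#'
#' For each of the enumerated feature subspaces (15 for the default
#' four-category schema): select the subspace columns of the training
#' recordings, fit a standardizer, fit a locally linear embedding on the
#' standardized block, and fit a penalized logistic regression on the
#' embedded coordinates with the recording labels (1 = depressed,
#' 0 = control).  The fit is deterministic for identical data and
#' configuration.
#'
#' @param x a \linkS4class{SpeechFeatureSet} of training recordings.
#' @param config configuration from \code{\link{elrddConfig}}.
#' @param gender "male"/"female" to subset that stratum before fitting, or
#'   "combined" (default) to use all recordings.
#' @return an \linkS4class{EnsembleModel} with one
#'   \linkS4class{BaseClassifier} per subspace.
#' @export
fitELRDD <- function(x, config = elrddConfig(), gender = "combined") {
  stopifnot(is(x, "SpeechFeatureSet"))
  if (gender != "combined") {
    keep <- genders(x) == gender
    if (!any(keep)) stop("no recordings with gender ", gender)
    x <- x[, keep]
  }
  schema <- featureSchema(x)
  fm <- featureMatrix(x)
  y <- labels(x)
  if (length(unique(y)) < 2L)
    stop("single-class training data: both depressed (1) and control (0) ",
         "recordings are required")
  n <- nrow(fm)
  d <- if (is.null(config$dim)) min(30L, n - 2L) else config$dim
  subs <- enumerateSubspaces(schema)
  classifiers <- lapply(subs, function(sp) {
    tryCatch({
      block <- fm[, sp@columns, drop = FALSE]
      std <- fitStandardizer(block)
      map <- fitLLE(applyStandardizer(std, block), knn = config$knn, d = d)
      fit <- fitBaseClassifier(map@coords, y, lambda = config$lambda)
      new("BaseClassifier", subspace = sp, standardizer = std,
          embedding = map, weights = fit$weights, converged = fit$converged)
    }, error = function(e)
      stop("subspace ", sp@id, " (", paste(sp@categories, collapse = "+"),
           "): ", conditionMessage(e), call. = FALSE))
  })
  cfg <- config
  cfg$dim <- d
  new("EnsembleModel", gender = gender, schema = schema,
      classifiers = classifiers, config = cfg)
}

#' Fit gender-dependent models
#'
#' Trains one \linkS4class{EnsembleModel} per gender stratum (the default
#' modelling mode: males and females are modelled independently).
#'
#' @inheritParams fitELRDD
#' @return named list with elements \code{male} and \code{female}.
#' @export
fitELRDDByGender <- function(x, config = elrddConfig()) {
  list(male = fitELRDD(x, config, gender = "male"),
       female = fitELRDD(x, config, gender = "female"))
}

#' Probability-mass sums of an ensemble probability vector
#'
#' Given the K per-subspace class-1 probabilities of one recording, returns
#' the unnormalized ensemble scores: \code{s1} = sum of the class-1
#' probabilities and \code{s0} = sum of the class-0 probabilities, so that
#' \code{s1 + s0 = K} identically.
#'
#' @param p numeric vector of per-subspace probabilities in (0, 1).
#' @return list with \code{s1}, \code{s0} and \code{p}.
#' @export
scorePair <- function(p) {
  stopifnot(all(p > 0), all(p < 1))
  list(s1 = sum(p), s0 = sum(1 - p), p = p)
}

# per-subspace class-1 probabilities for a matrix of raw recordings
subspaceProbabilities <- function(model, fm) {
  K <- length(model@classifiers)
  P <- matrix(NA_real_, nrow(fm), K)
  for (k in seq_len(K)) {
    b <- model@classifiers[[k]]
    block <- fm[, b@subspace@columns, drop = FALSE]
    Zk <- transformLLE(b@embedding, applyStandardizer(b@standardizer, block))
    if (is.null(dim(Zk))) Zk <- matrix(Zk, nrow = nrow(fm))
    P[, k] <- plogis(drop(cbind(Zk, 1) %*% b@weights))
  }
  colnames(P) <- paste0("p.", seq_len(K))
  P
}

#' Ensemble scores for recordings
#'
#' Applies every subspace pipeline (standardize, embed out-of-sample,
#' logistic) to each recording and returns the per-subspace class-1
#' probabilities together with the ensemble probability sums \code{s1} and
#' \code{s0} (\code{s1 + s0 = K}).
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param x a \linkS4class{SpeechFeatureSet}, a feature matrix (recordings
#'   in rows), or a single feature vector.
#' @return data.frame with one row per recording: columns \code{p.1} ..
#'   \code{p.K}, \code{s1}, \code{s0} (plus \code{subject_id},
#'   \code{task_id}, \code{label} when \code{x} is a SpeechFeatureSet).
#' @export
ensembleScores <- function(model, x) {
  meta <- NULL
  if (is(x, "SpeechFeatureSet")) {
    cd <- SummarizedExperiment::colData(x)
    meta <- data.frame(subject_id = cd$subject_id, task_id = cd$task_id,
                       label = cd$label, stringsAsFactors = FALSE)
    fm <- featureMatrix(x)
  } else if (is.null(dim(x))) fm <- matrix(x, nrow = 1L)
  else fm <- as.matrix(x)
  if (ncol(fm) != schemaTotal(model@schema))
    stop("feature length ", ncol(fm), " does not match model schema total ",
         schemaTotal(model@schema))
  P <- subspaceProbabilities(model, fm)
  out <- data.frame(P, s1 = rowSums(P), s0 = rowSums(1 - P))
  if (!is.null(meta)) out <- cbind(meta, out)
  out
}

#' Per-recording depression call
#'
#' Classifies each recording as depressed (1) when its normalized ensemble
#' probability s1/K reaches the threshold; ties go to the positive
#' (depressed) class.
#'
#' @inheritParams ensembleScores
#' @param tau decision threshold in (0, 1), default 0.5.
#' @return data.frame with columns \code{probability} (= s1/K) and
#'   \code{label} per recording (plus metadata for SpeechFeatureSet input,
#'   where \code{label} from the data is kept as \code{label_true}).
#' @export
predictRecording <- function(model, x, tau = 0.5) {
  stopifnot(tau > 0, tau < 1)
  sc <- ensembleScores(model, x)
  K <- length(model@classifiers)
  prob <- sc$s1 / K
  out <- data.frame(probability = prob, label = as.integer(prob >= tau))
  if ("subject_id" %in% names(sc))
    out <- cbind(sc[c("subject_id", "task_id")],
                 data.frame(label_true = sc$label), out)
  out
}

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel (%s): %d base classifiers, embedding dim %d, knn %d, lambda %g\n",
              object@gender, length(object@classifiers),
              object@config$dim, object@config$knn, object@config$lambda))
  nc <- sum(!vapply(object@classifiers, slot, logical(1), name = "converged"))
  if (nc) cat("  note:", nc, "base fit(s) hit the iteration cap\n")
})
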