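#' @import methods
#' @importFrom stats sd var rnorm runif setNames pf pt plogis
#' @importFrom utils combn head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' FeatureSchema: the acoustic feature layout
#'
#' Describes how the columns of a per-recording feature vector are organised
#' into the four acoustic categories (MFCC, PROS, SPEC, GLOT) and their
#' subcategories.  Column order in the full vector follows the schema row
#' order: the MFCC block comes first and the GLOT block last, and a
#' category's columns are contiguous.  All column indices in this package
#' are 1-based.
#'
#' @slot table a data.frame with columns \code{category}, \code{subcategory}
#'   and \code{count} (positive integer feature counts), rows in column-block
#'   order.
#' @export
setClass("FeatureSchema", representation(table = "data.frame"))

setValidity("FeatureSchema", function(object) {
  tab <- object@table
  msgs <- character()
  need <- c("category", "subcategory", "count")
  if (!all(need %in% names(tab)))
    return(paste("schema table must have columns", paste(need, collapse = ", ")))
  cats <- unique(tab$category)
  if (!identical(cats, intersect(c("MFCC", "PROS", "SPEC", "GLOT"), cats)))
    msgs <- c(msgs, "categories must appear in the order MFCC, PROS, SPEC, GLOT")
  if (length(cats) != 4L)
    msgs <- c(msgs, "schema must contain exactly the 4 categories MFCC, PROS, SPEC, GLOT")
  if (any(rle(as.character(tab$category))$lengths != table(tab$category)[unique(tab$category)]))
    msgs <- c(msgs, "rows of one category must be contiguous")
  cnt <- tab$count
  if (!is.numeric(cnt) || any(!is.finite(cnt)) || any(cnt <= 0) || any(cnt != round(cnt)))
    msgs <- c(msgs, "all counts must be positive integers")
  if (anyDuplicated(paste(tab$category, tab$subcategory)))
    msgs <- c(msgs, "duplicate category/subcategory rows")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Subspace: one category-combination feature subspace
#'
#' A non-empty subset of the four feature categories together with the
#' 1-based column indices of its features in the full vector.
#'
#' @slot id integer subspace number (1-15 for the default enumeration).
#' @slot categories character vector of member category names.
#' @slot columns strictly increasing integer vector of 1-based column indices.
#' @export
setClass("Subspace", representation(id = "integer",
                                    categories = "character",
                                    columns = "integer"))

setValidity("Subspace", function(object) {
  msgs <- character()
  if (length(object@categories) < 1L)
    msgs <- c(msgs, "subspace must contain at least one category")
  if (length(object@columns) < 1L || is.unsorted(object@columns, strictly = TRUE))
    msgs <- c(msgs, "columns must be a non-empty strictly increasing index vector")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' SpeechFeatureSet: recordings x features with subject metadata
#'
#' A \linkS4class{SummarizedExperiment} holding one assay \code{"features"}
#' (features in rows, recordings in columns) with per-recording metadata in
#' \code{colData}: \code{subject_id}, \code{gender} ("male"/"female"),
#' \code{label} (1 = depressed, 0 = control) and \code{task_id} (recording
#' task number).  The \linkS4class{FeatureSchema} lives in
#' \code{metadata(x)$schema}.
#'
#' @export
setClass("SpeechFeatureSet", contains = "SummarizedExperiment")

setValidity("SpeechFeatureSet", function(object) {
  msgs <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject_id", "gender", "label", "task_id")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msgs <- c(msgs, paste("colData is missing column(s):", paste(miss, collapse = ", ")))
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'features' is required")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Standardizer: per-column centering and scaling fitted on training data
#'
#' @slot center per-column training means.
#' @slot scale per-column training standard deviations, floored at 1e-8 so
#'   that constant columns map to zero after centering.
#' @export
setClass("Standardizer", representation(center = "numeric", scale = "numeric"))

setValidity("Standardizer", function(object) {
  if (length(object@center) != length(object@scale))
    return("center and scale must have equal length")
  if (any(object@scale < 1e-8)) return("scale entries must be >= 1e-8")
  TRUE
})

#' EmbeddingMap: a fitted locally linear embedding
#'
#' Stores the standardized training points, the neighbourhood size, the
#' target dimension and the training embedding coordinates; the
#' out-of-sample transform re-solves the barycentric weight system for new
#' points against these training points.
#'
#' @slot points standardized training matrix (n x p).
#' @slot knn neighbour count used for the local weight systems.
#' @slot dim embedding dimension d (0 < d < n).
#' @slot coords training embedding (n x d), each coordinate unit-variance
#'   and (numerically) zero-mean over training points.
#' @export
setClass("EmbeddingMap", representation(points = "matrix", knn = "integer",
                                        dim = "integer", coords = "matrix"))

setValidity("EmbeddingMap", function(object) {
  n <- nrow(object@points)
  msgs <- character()
  if (object@knn >= n) msgs <- c(msgs, "knn must be < number of training points")
  if (object@dim < 1L || object@dim >= n) msgs <- c(msgs, "dim must satisfy 0 < d < n")
  if (!identical(dim(object@coords), c(n, as.integer(object@dim))))
    msgs <- c(msgs, "coords must be n x dim")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' BaseClassifier: one per-subspace pipeline of the ensemble
#'
#' Standardizer -> embedding map -> logistic weights for a single feature
#' subspace.  The weight vector has length d + 1; the last entry is the
#' intercept.
#'
#' @slot subspace the \linkS4class{Subspace} this classifier works on.
#' @slot standardizer fitted \linkS4class{Standardizer} for the subspace columns.
#' @slot embedding fitted \linkS4class{EmbeddingMap}.
#' @slot weights numeric weight vector of length \code{dim(embedding) + 1}
#'   (intercept last).
#' @slot converged logical; FALSE if the likelihood maximizer hit the
#'   iteration cap.
#' @export
setClass("BaseClassifier", representation(subspace = "Subspace",
                                          standardizer = "Standardizer",
                                          embedding = "EmbeddingMap",
                                          weights = "numeric",
                                          converged = "logical"))

setValidity("BaseClassifier", function(object) {
  d <- object@embedding@dim
  if (length(object@weights) != d + 1L)
    return("weights must have length embedding dim + 1 (intercept last)")
  if (any(!is.finite(object@weights))) return("weights must be finite")
  TRUE
})

#' EnsembleModel: the full ensemble of per-subspace logistic classifiers
#'
#' @slot gender which stratum the model was trained on: "male", "female" or
#'   "combined".
#' @slot schema the \linkS4class{FeatureSchema} the model expects.
#' @slot classifiers list of \linkS4class{BaseClassifier}, one per enumerated
#'   subspace (K = 15 for the default schema).
#' @slot config the training configuration (see \code{\link{elrddConfig}}).
#' @export
setClass("EnsembleModel", representation(gender = "character",
                                         schema = "FeatureSchema",
                                         classifiers = "list",
                                         config = "list"))

setValidity("EnsembleModel", function(object) {
  msgs <- character()
  if (!object@gender %in% c("male", "female", "combined"))
    msgs <- c(msgs, "gender must be male, female or combined")
  if (!all(vapply(object@classifiers, is, logical(1), class2 = "BaseClassifier")))
    msgs <- c(msgs, "classifiers must all be BaseClassifier objects")
  ids <- vapply(object@classifiers, function(b) b@subspace@id, integer(1))
  if (!identical(ids, seq_along(ids)))
    msgs <- c(msgs, "classifiers must be ordered by subspace id 1..K")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' FoldPlan: a speaker-independent stratified fold assignment
#'
#' @slot nFolds number of folds.
#' @slot seed RNG seed the plan was built with.
#' @slot assignments data.frame with columns \code{subject_id}, \code{label}
#'   and \code{fold}; every recording of a subject belongs to the subject's
#'   fold.
#' @export
setClass("FoldPlan", representation(nFolds = "integer", seed = "integer",
                                    assignments = "data.frame"))

setValidity("FoldPlan", function(object) {
  a <- object@assignments
  msgs <- character()
  if (!all(c("subject_id", "label", "fold") %in% names(a)))
    msgs <- c(msgs, "assignments needs columns subject_id, label, fold")
  else {
    if (anyDuplicated(a$subject_id)) msgs <- c(msgs, "subjects must appear once")
    if (length(a$fold) && (any(a$fold < 1L) || any(a$fold > object@nFolds)))
      msgs <- c(msgs, "fold numbers out of range")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
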