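#' Fuse one subject's recordings into a single diagnostic call
#'
#' Subject-level extension of the ensemble: the per-recording ensemble
#' probability masses are summed over all of the subject's recordings,
#' S1 = sum of s1(r) and S0 = sum of s0(r), and the subject is called
#' depressed when S1 >= S0 (ties positive).  Equivalently, the mean
#' normalized recording probability is thresholded at 0.5.  With the
#' \code{"majority"} fusion rule the call is instead a majority vote over
#' the per-recording labels (ties positive); the probability column always
#' reports S1/(S1+S0).
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param x a \linkS4class{SpeechFeatureSet} containing the recordings of
#'   exactly one subject (>= 1 recording).
#' @param fusion "prob_sum" (default) or "majority".
#' @return one-row data.frame: \code{subject_id}, \code{n_recordings},
#'   \code{S1}, \code{S0}, \code{probability} = S1/(S1+S0), \code{label}.
#' @export
aggregateSubject <- function(model, x, fusion = c("prob_sum", "majority")) {
  fusion <- match.arg(fusion)
  stopifnot(is(x, "SpeechFeatureSet"))
  if (ncol(x) == 0L) stop("no recordings supplied")
  sid <- unique(subjectIds(x))
  if (length(sid) != 1L)
    stop("recordings belong to more than one subject: ",
         paste(sid, collapse = ", "))
  sc <- ensembleScores(model, x)
  K <- length(model@classifiers)
  S1 <- sum(sc$s1)
  S0 <- sum(sc$s0)
  label <- fuseScores(sc$s1, K, fusion, model@config$threshold)
  data.frame(subject_id = sid, n_recordings = nrow(sc), S1 = S1, S0 = S0,
             probability = S1 / (S1 + S0), label = label,
             stringsAsFactors = FALSE)
}

# subject call from the per-recording ensemble sums s1 (each in (0, K)):
# prob_sum compares the summed probability masses (tie -> depressed);
# majority votes over per-recording labels at `threshold` (tie -> depressed)
fuseScores <- function(s1, K, fusion = c("prob_sum", "majority"),
                       threshold = 0.5) {
  fusion <- match.arg(fusion)
  if (fusion == "prob_sum") as.integer(sum(s1) >= sum(K - s1))
  else as.integer(mean(as.integer(s1 / K >= threshold)) >= 0.5)
}

#' Subject-level classification of a dataset
#'
#' Applies \code{\link{aggregateSubject}} to every distinct subject in the
#' dataset.  The result is ordered by subject id and is invariant to the
#' order of recordings within a subject.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param x a \linkS4class{SpeechFeatureSet}.
#' @param fusion "prob_sum" (default) or "majority".
#' @return data.frame with one row per subject (see
#'   \code{\link{aggregateSubject}}), plus the subject's true \code{label_true}.
#' @export
classifySubjects <- function(model, x, fusion = c("prob_sum", "majority")) {
  fusion <- match.arg(fusion)
  sids <- sort(unique(subjectIds(x)))
  if (!length(sids))
    return(data.frame(subject_id = character(), n_recordings = integer(),
                      S1 = numeric(), S0 = numeric(), probability = numeric(),
                      label = integer(), label_true = integer(),
                      stringsAsFactors = FALSE))
  rows <- lapply(sids, function(sid) {
    xi <- x[, subjectIds(x) == sid]
    dec <- aggregateSubject(model, xi, fusion = fusion)
    dec$label_true <- labels(xi)[1L]
    dec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
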