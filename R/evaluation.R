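#' Build a speaker-independent stratified fold plan
#'
#' Partitions subjects (never individual recordings) into \code{nFolds}
#' folds, stratified by class label: within each label the subjects are
#' shuffled with the given seed and dealt round-robin, so per-fold class
#' counts differ by at most one.  All recordings of a subject share the
#' subject's fold, which is what makes downstream cross-validation
#' speaker-independent.
#'
#' @param x a \linkS4class{SpeechFeatureSet}.
#' @param nFolds number of folds (default 10).
#' @param seed RNG seed; the same seed always yields the same plan.
#' @return a \linkS4class{FoldPlan}.
#' @export
makeFolds <- function(x, nFolds = 10L, seed = 1L) {
  nFolds <- as.integer(nFolds); seed <- as.integer(seed)
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  subj <- unique(cd[c("subject_id", "label")])
  perLabel <- table(subj$label)
  if (length(perLabel) < 2L || any(perLabel < nFolds))
    stop("need at least ", nFolds, " subjects per label for ", nFolds,
         " folds")
  rows <- withSeed(seed, {
    do.call(rbind, lapply(sort(unique(subj$label)), function(l) {
      ids <- sort(subj$subject_id[subj$label == l])
      ids <- sample(ids)
      data.frame(subject_id = ids, label = l,
                 fold = rep_len(seq_len(nFolds), length(ids)),
                 stringsAsFactors = FALSE)
    }))
  })
  rows <- rows[order(rows$subject_id), ]
  rownames(rows) <- NULL
  new("FoldPlan", nFolds = nFolds, seed = seed, assignments = rows)
}

# run expr under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Confusion-matrix metrics with depressed as the positive class
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP) and accuracy =
#' (TP+TN)/total, each in percent; a metric whose denominator is zero is
#' reported as \code{NA} (undefined), not as 0.
#'
#' @param yTrue true labels in \{0, 1\} (1 = depressed).
#' @param yPred predicted labels in \{0, 1\}.
#' @return list with \code{TP}, \code{FP}, \code{TN}, \code{FN},
#'   \code{sensitivity}, \code{specificity}, \code{accuracy} (percent).
#' @examples
#' confusionMetrics(c(1,1,1,1,0,0,0,0), c(1,1,1,0,0,0,1,1))
#' @export
confusionMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (!all(yTrue %in% c(0, 1)) || !all(yPred %in% c(0, 1)))
    stop("labels must be binary 0/1")
  TP <- sum(yTrue == 1 & yPred == 1)
  FN <- sum(yTrue == 1 & yPred == 0)
  TN <- sum(yTrue == 0 & yPred == 0)
  FP <- sum(yTrue == 0 & yPred == 1)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       sensitivity = pct(TP, TP + FN),
       specificity = pct(TN, TN + FP),
       accuracy = pct(TP + TN, length(yTrue)))
}

metricsFromCounts <- function(TP, FP, TN, FN) {
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       sensitivity = pct(TP, TP + FN), specificity = pct(TN, TN + FP),
       accuracy = pct(TP + TN, TP + FP + TN + FN))
}

#' Speaker-independent cross-validation of the ensemble
#'
#' For each fold of a stratified speaker-independent plan, the full
#' pipeline (standardizers, embeddings, base classifiers) is refit on the
#' training-fold recordings only, and the held-out fold is scored at both
#' granularities: per recording (threshold on s1/K) and per subject
#' (decision fusion over the subject's recordings).  No quantity derived
#' from test-fold recordings enters any fit; \code{\link{checkLeakage}} can
#' verify this on the returned report.
#'
#' @param x a \linkS4class{SpeechFeatureSet}.
#' @param config configuration from \code{\link{elrddConfig}}.
#' @param nFolds number of folds (default 10).
#' @param seed seed for the fold plan.
#' @param gender "combined" (default) to use all of \code{x}, or
#'   "male"/"female" to evaluate one stratum.
#' @return list of class \code{"elrddCV"}: \code{foldPlan}, \code{config},
#'   \code{folds} (per fold: train/test subject ids, recording-level scores
#'   with per-subspace probabilities, recording- and subject-level metric
#'   sets, subject decisions, the fitted subspace-1 standardizer), and
#'   pooled \code{recording} / \code{subject} metrics whose confusion
#'   counts are the sums of the per-fold counts.
#' @export
crossValidate <- function(x, config = elrddConfig(), nFolds = 10L, seed = 1L,
                          gender = "combined") {
  if (gender != "combined") x <- x[, genders(x) == gender]
  plan <- makeFolds(x, nFolds = nFolds, seed = seed)
  a <- plan@assignments
  folds <- lapply(seq_len(plan@nFolds), function(f) {
    testSubj <- a$subject_id[a$fold == f]
    trainSubj <- a$subject_id[a$fold != f]
    tr <- x[, subjectIds(x) %in% trainSubj]
    te <- x[, subjectIds(x) %in% testSubj]
    model <- tryCatch(fitELRDD(tr, config),
                      error = function(e) stop("fold ", f, ": ",
                                               conditionMessage(e),
                                               call. = FALSE))
    sc <- ensembleScores(model, te)
    K <- length(model@classifiers)
    recPred <- as.integer(sc$s1 / K >= config$threshold)
    recMet <- confusionMetrics(sc$label, recPred)
    dec <- classifySubjects(model, te, fusion = config$fusion)
    subjMet <- confusionMetrics(dec$label_true, dec$label)
    list(fold = f, trainSubjects = trainSubj, testSubjects = testSubj,
         scores = sc, recording = recMet,
         subjectDecisions = dec, subject = subjMet,
         standardizer1 = model@classifiers[[1L]]@standardizer)
  })
  pool <- function(level) {
    counts <- Reduce(`+`, lapply(folds, function(f)
      unlist(f[[level]][c("TP", "FP", "TN", "FN")])))
    metricsFromCounts(unname(counts["TP"]), unname(counts["FP"]),
                      unname(counts["TN"]), unname(counts["FN"]))
  }
  structure(list(foldPlan = plan, config = config, folds = folds,
                 recording = pool("recording"), subject = pool("subject")),
            class = "elrddCV")
}

#' @export
print.elrddCV <- function(x, ...) {
  fmt <- function(m) sprintf("sens %.2f%% / spec %.2f%% / acc %.2f%%",
                             m$sensitivity, m$specificity, m$accuracy)
  cat("Speaker-independent cross-validation,", length(x$folds), "folds\n")
  cat("  recording level:", fmt(x$recording), "\n")
  cat("  subject level:  ", fmt(x$subject), "\n")
  invisible(x)
}

#' Leakage self-test for a cross-validation report
#'
#' Verifies on the finished report that (a) no subject appears in both the
#' train and test sides of any fold and (b) each fold's stored subspace-1
#' standardizer equals a standardizer refit on that fold's training
#' recordings only -- a standardizer fitted on all recordings (train +
#' test) fails this comparison.
#'
#' @param cv result of \code{\link{crossValidate}}.
#' @param x the \linkS4class{SpeechFeatureSet} that was cross-validated.
#' @return data.frame of findings (\code{fold}, \code{type},
#'   \code{message}); zero rows when no leakage is detected.
#' @export
checkLeakage <- function(cv, x) {
  schema <- featureSchema(x)
  cols1 <- enumerateSubspaces(schema)[[1L]]@columns
  findings <- list()
  for (f in cv$folds) {
    overlap <- intersect(f$trainSubjects, f$testSubjects)
    if (length(overlap))
      findings[[length(findings) + 1L]] <-
        data.frame(fold = f$fold, type = "subject_overlap",
                   message = paste("subjects in both train and test:",
                                   paste(overlap, collapse = ", ")))
    tr <- x[, subjectIds(x) %in% f$trainSubjects]
    ref <- fitStandardizer(featureMatrix(tr)[, cols1, drop = FALSE])
    same <- isTRUE(all.equal(ref@center, f$standardizer1@center,
                             tolerance = 1e-8)) &&
      isTRUE(all.equal(ref@scale, f$standardizer1@scale, tolerance = 1e-8))
    if (!same)
      findings[[length(findings) + 1L]] <-
        data.frame(fold = f$fold, type = "standardizer_mismatch",
                   message = "standardizer does not match a training-only fit (possible test-data leakage)")
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(fold = integer(), type = character(), message = character())
}

#' One-way fixed-effects analysis of variance
#'
#' Classical one-way ANOVA of k independent groups: F is the ratio of the
#' between-group to the pooled within-group mean square, with p from the
#' F(k-1, N-k) distribution.
#'
#' @param groups list of numeric vectors, >= 2 groups with >= 2 values each.
#' @return list with \code{F}, \code{p}, \code{df1}, \code{df2},
#'   \code{MSE} (pooled within-group mean square), group \code{means} and
#'   sizes \code{n}.
#' @examples
#' oneWayAnova(list(c(1, 2, 3), c(4, 5, 6)))$F   # 13.5
#' @export
oneWayAnova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs at least 2 values")
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  ns <- vapply(groups, length, integer(1))
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1))) /
    (length(values) - length(groups))
  Fv <- unname(ht$statistic)
  pv <- unname(ht$p.value)
  if (mse == 0 && Fv %in% c(NaN, NA)) { Fv <- 0; pv <- 1 }  # degenerate: all values equal
  list(F = Fv, p = pv,
       df1 = unname(ht$parameter[1L]), df2 = unname(ht$parameter[2L]),
       MSE = mse, means = vapply(groups, mean, numeric(1)), n = ns)
}

#' Fisher's least significant difference post-hoc test
#'
#' Pairwise comparisons of the group means using the pooled ANOVA
#' mean-square error: \eqn{t = (\bar x_i - \bar x_j) /
#' \sqrt{MSE (1/n_i + 1/n_j)}} on N - k degrees of freedom, declared
#' significant when the two-sided p-value is below \code{alpha}.
#'
#' @param groups list of numeric vectors (as \code{\link{oneWayAnova}}).
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per unordered pair: \code{group_i},
#'   \code{group_j}, \code{diff}, \code{t}, \code{df}, \code{p},
#'   \code{significant}.
#' @export
lsdTest <- function(groups, alpha = 0.05) {
  av <- oneWayAnova(groups)
  ns <- av$n
  pairs <- combn(length(groups), 2L)
  rows <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    diff <- av$means[i] - av$means[j]
    se <- sqrt(av$MSE * (1 / ns[i] + 1 / ns[j]))
    t <- if (se == 0) { if (diff == 0) 0 else Inf * sign(diff) } else diff / se
    p <- 2 * pt(-abs(t), df = av$df2)
    data.frame(group_i = i, group_j = j, diff = diff, t = t, df = av$df2,
               p = p, significant = p < alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d folds over %d subjects (seed %d)\n",
              object@nFolds, nrow(object@assignments), object@seed))
})
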