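#' Construct a SpeechFeatureSet
#'
#' @param features numeric matrix of per-recording feature vectors,
#'   recordings in rows and features in columns (transposed internally to
#'   the features-in-rows assay convention).
#' @param subject_id character vector of subject identifiers, one per
#'   recording.
#' @param gender "male"/"female" per recording.
#' @param label 1 = depressed, 0 = control, per recording.
#' @param task_id integer recording/task number per recording.
#' @param schema the \linkS4class{FeatureSchema} describing the columns.
#' @return a \linkS4class{SpeechFeatureSet}.
#' @export
SpeechFeatureSet <- function(features, subject_id, gender, label, task_id,
                             schema = defaultSchema()) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(subject_id) == n, length(gender) == n,
            length(label) == n, length(task_id) == n)
  assay <- t(features)
  if (is.null(rownames(assay)) && ncol(features) == schemaTotal(schema))
    rownames(assay) <- featureNames(schema)
  colnames(assay) <- sprintf("%s_r%02d", subject_id, as.integer(task_id))
  cd <- S4Vectors::DataFrame(subject_id = as.character(subject_id),
                             gender = tolower(as.character(gender)),
                             label = as.integer(label),
                             task_id = as.integer(task_id),
                             row.names = colnames(assay))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = assay), colData = cd,
    metadata = list(schema = schema))
  new("SpeechFeatureSet", se)
}

#' Recording feature matrix (recordings x features)
#'
#' @param x a \linkS4class{SpeechFeatureSet}.
#' @export
featureMatrix <- function(x) t(SummarizedExperiment::assay(x, "features"))

#' @rdname featureMatrix
#' @export
subjectIds <- function(x) SummarizedExperiment::colData(x)$subject_id

#' @rdname featureMatrix
#' @export
genders <- function(x) SummarizedExperiment::colData(x)$gender

#' @rdname featureMatrix
#' @export
labels <- function(x) SummarizedExperiment::colData(x)$label

#' @rdname featureMatrix
#' @export
taskIds <- function(x) SummarizedExperiment::colData(x)$task_id

#' @rdname featureMatrix
#' @export
featureSchema <- function(x) S4Vectors::metadata(x)$schema

#' Validate a dataset against its schema and subject structure
#'
#' Diagnostic check of the dataset invariants: feature vector length matches
#' the schema, all feature values are finite, every subject carries a single
#' gender and a single label across its recordings, and task ids are unique
#' within a subject.  Never throws on bad data; all violations are collected
#' into the returned report.
#'
#' @param x a \linkS4class{SpeechFeatureSet}.
#' @return data.frame with columns \code{type} and \code{message}; zero rows
#'   if and only if the dataset is valid.
#' @export
validateManifest <- function(x) {
  findings <- list()
  add <- function(type, message)
    findings[[length(findings) + 1L]] <<- data.frame(type = type,
                                                     message = message)
  sc <- featureSchema(x)
  fm <- SummarizedExperiment::assay(x, "features")
  if (!is.null(sc) && nrow(fm) != schemaTotal(sc))
    add("length_mismatch",
        sprintf("feature vector length %d does not match schema total %d",
                nrow(fm), schemaTotal(sc)))
  bad <- which(!is.finite(fm))
  if (length(bad)) {
    rec <- unique(((bad - 1L) %/% nrow(fm)) + 1L)
    add("non_finite",
        sprintf("%d non-finite feature value(s) in recording(s): %s",
                length(bad), paste(utils::head(rec, 5L), collapse = ", ")))
  }
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  for (sid in unique(cd$subject_id)) {
    rows <- cd[cd$subject_id == sid, , drop = FALSE]
    if (length(unique(rows$gender)) > 1L)
      add("inconsistent_gender",
          sprintf("subject %s has multiple genders: %s", sid,
                  paste(unique(rows$gender), collapse = ", ")))
    if (length(unique(rows$label)) > 1L)
      add("inconsistent_label",
          sprintf("subject %s has multiple labels: %s", sid,
                  paste(unique(rows$label), collapse = ", ")))
    if (anyDuplicated(rows$task_id))
      add("duplicate_task",
          sprintf("subject %s has duplicated task_id(s): %s", sid,
                  paste(unique(rows$task_id[duplicated(rows$task_id)]),
                        collapse = ", ")))
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(type = character(), message = character())
}

#' Read / write a per-recording feature table
#'
#' The on-disk format is a UTF-8 CSV with header columns \code{subject_id},
#' \code{gender}, \code{label}, \code{task_id} followed by one column per
#' feature named \code{<category>.<subcategory>.<index>}.  The write/read
#' round trip preserves metadata exactly and feature values to full double
#' precision; the schema is reconstructed from the feature column names.
#'
#' @param path CSV file path.
#' @param x a \linkS4class{SpeechFeatureSet} (for writing).
#' @return \code{readFeatureTable} returns a \linkS4class{SpeechFeatureSet};
#'   \code{writeFeatureTable} returns \code{path} invisibly.
#' @export
readFeatureTable <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  meta <- c("subject_id", "gender", "label", "task_id")
  miss <- setdiff(meta, names(dt))
  if (length(miss))
    stop("feature table is missing required column(s): ",
         paste(miss, collapse = ", "))
  featCols <- setdiff(names(dt), meta)
  if (!length(featCols)) stop("feature table contains no feature columns")

  gender <- tolower(as.character(dt$gender))
  badg <- which(!gender %in% c("male", "female"))
  if (length(badg))
    stop(sprintf("unknown gender token '%s' at row %d", dt$gender[badg[1L]],
                 badg[1L]))
  lab <- dt$label
  if (!all(lab %in% c(0, 1)))
    stop(sprintf("label must be 0 or 1; offending row %d",
                 which(!lab %in% c(0, 1))[1L]))

  for (fc in featCols) {
    col <- dt[[fc]]
    if (!is.numeric(col)) {
      conv <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(conv) & !is.na(col))
      stop(sprintf("non-numeric feature cell in column '%s' at row %d", fc,
                   if (length(bad)) bad[1L] else 1L))
    }
    bad <- which(!is.finite(col))
    if (length(bad))
      stop(sprintf("non-finite feature value in column '%s' at row %d", fc,
                   bad[1L]))
  }

  schema <- schemaFromFeatureNames(featCols)
  SpeechFeatureSet(as.matrix(dt[featCols]), dt$subject_id, gender,
                   as.integer(lab), as.integer(dt$task_id), schema)
}

#' @rdname readFeatureTable
#' @export
writeFeatureTable <- function(x, path) {
  fm <- featureMatrix(x)
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  out <- data.frame(subject_id = cd$subject_id, gender = cd$gender,
                    label = cd$label, task_id = cd$task_id,
                    stringsAsFactors = FALSE)
  # 17 significant digits: enough to reproduce any double exactly on read
  txt <- matrix(sprintf("%.17g", fm), nrow = nrow(fm),
                dimnames = dimnames(fm))
  out <- cbind(out, as.data.frame(txt, stringsAsFactors = FALSE))
  data.table::fwrite(out, path, row.names = FALSE)
  invisible(path)
}

# Reconstruct a schema from "<category>.<subcategory>.<index>" column names;
# categories/subcategories keep their column order.
schemaFromFeatureNames <- function(nms) {
  parts <- strsplit(nms, ".", fixed = TRUE)
  ok <- lengths(parts) >= 3L
  if (!all(ok))
    stop("feature column name not of the form <category>.<subcategory>.<index>: ",
         nms[which(!ok)[1L]])
  cat <- vapply(parts, `[[`, character(1), 1L)
  sub <- vapply(parts, function(p) paste(p[2:(length(p) - 1L)], collapse = "."),
                character(1))
  key <- paste(cat, sub, sep = "\r")
  runs <- rle(key)
  first <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  FeatureSchema(data.frame(category = cat[first], subcategory = sub[first],
                           count = runs$lengths, stringsAsFactors = FALSE))
}

#' Composition of the reference clinical speech corpus
#'
#' The fixed composition of the clinical database this package's synthetic
#' generator emulates: 85 controls (34 male, 51 female) and 85 depressed
#' subjects (32 male, 53 female), 29 recordings per subject across
#' interview, picture-description and reading tasks, and the published
#' total speech durations per task.  The derived quantities (total
#' recordings, total duration, mean recording duration in seconds) are
#' computed from those inputs.
#'
#' @return list with elements \code{subjects} (gender x label counts),
#'   \code{nSubjects}, \code{recordingsPerSubject}, \code{nRecordings},
#'   \code{taskDurations} (seconds), \code{totalDuration} and
#'   \code{meanRecordingDuration} (seconds).
#' @examples
#' referenceDatabaseSummary()$meanRecordingDuration   # ~18.3 s
#' @export
referenceDatabaseSummary <- function() {
  subjects <- matrix(c(34L, 51L, 32L, 53L), nrow = 2L,
                     dimnames = list(gender = c("male", "female"),
                                     label = c("control", "depressed")))
  recPer <- 29L
  nSub <- sum(subjects)
  nRec <- nSub * recPer
  dur <- c(interview = 52427, picture = 16203, reading = 21425)
  list(subjects = subjects,
       nSubjects = nSub,
       recordingsPerSubject = recPer,
       nRecordings = nRec,
       taskDurations = dur,
       totalDuration = sum(dur),
       meanRecordingDuration = sum(dur) / nRec)
}

#' Summarize a dataset
#'
#' @param x a \linkS4class{SpeechFeatureSet}.
#' @return list with \code{cells} (gender x label recording-level subject
#'   counts), \code{recordingsPerSubject} (data.frame subject_id, gender,
#'   label, n), and \code{blockStats} (per-category feature block mean/sd by
#'   class).
#' @export
summarizeDataset <- function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  if (nrow(cd) == 0L)
    return(list(cells = table(gender = character(), label = integer()),
                recordingsPerSubject = data.frame(subject_id = character(),
                                                  gender = character(),
                                                  label = integer(),
                                                  n = integer()),
                blockStats = data.frame(category = character(),
                                        label = integer(),
                                        mean = numeric(), sd = numeric())))
  subj <- unique(cd[c("subject_id", "gender", "label")])
  cells <- table(gender = subj$gender, label = subj$label)
  rp <- as.data.frame(table(subject_id = cd$subject_id),
                      stringsAsFactors = FALSE)
  names(rp)[2L] <- "n"
  rp <- merge(subj, rp, by = "subject_id", sort = TRUE)

  sc <- featureSchema(x)
  fm <- SummarizedExperiment::assay(x, "features")
  blocks <- lapply(unique(sc@table$category), function(cc) {
    idx <- categoryColumns(sc, cc)
    do.call(rbind, lapply(sort(unique(cd$label)), function(l) {
      vals <- fm[idx, cd$label == l, drop = FALSE]
      data.frame(category = cc, label = l, mean = mean(vals), sd = sd(vals))
    }))
  })
  list(cells = cells, recordingsPerSubject = rp,
       blockStats = do.call(rbind, blocks))
}

setMethod("show", "SpeechFeatureSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("SpeechFeatureSet: %d recordings x %d features, %d subjects\n",
              ncol(object), nrow(object),
              length(unique(cd$subject_id))))
  if (ncol(object))
    cat(sprintf("  labels: %d depressed / %d control recordings\n",
                sum(cd$label == 1L), sum(cd$label == 0L)))
})
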