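#' Construct a FeatureSchema
#'
#' @param table data.frame with columns \code{category}, \code{subcategory},
#'   \code{count}.  Categories must appear in the order MFCC, PROS, SPEC,
#'   GLOT with contiguous rows; counts are positive integers.
#' @return a \linkS4class{FeatureSchema}.
#' @examples
#' sc <- FeatureSchema(data.frame(
#'   category = c("MFCC", "PROS", "SPEC", "GLOT"),
#'   subcategory = c("mfcc", "pros", "spec", "glot"),
#'   count = c(8L, 12L, 6L, 4L)))
#' schemaTotal(sc)
#' @export
FeatureSchema <- function(table) {
  table$category <- as.character(table$category)
  table$subcategory <- as.character(table$subcategory)
  table$count <- as.integer(table$count)
  rownames(table) <- NULL
  new("FeatureSchema", table = table)
}

#' The default 1992-feature acoustic schema
#'
#' The standard layout of the per-recording feature vector: 630 MFCC
#' features (coefficients 0-14 with deltas and statistical functionals),
#' 952 prosodic features, 378 spectral features and 32 glottal features,
#' 1992 in total.  Subcategory counts:
#' MFCC (0-14) = 630; spectral flux/centroid/entropy = 42 each, roll-off =
#' 168, band energies = 84; PCM loudness = 42, log mel-frequency bands
#' (0-7) = 336, LSP frequencies (0-7) = 336, F0 envelope = 42, voicing
#' probability = 42, F0final + local shimmer = 76, local jitter + jitter
#' DDP = 76, pitch onsets/duration = 2; glottal time-domain (GLT) = 27 and
#' frequency-domain (GLF) = 5 parameters.
#'
#' The full feature vector is laid out category-block-wise in the order
#' MFCC, PROS, SPEC, GLOT, which keeps every subspace's columns a
#' concatenation of contiguous blocks.
#'
#' @return a \linkS4class{FeatureSchema} with 4 categories, 16 subcategories
#'   and 1992 features.
#' @examples
#' schemaTotal(defaultSchema())     # 1992
#' categoryTotals(defaultSchema())
#' @export
defaultSchema <- function() {
  FeatureSchema(data.frame(
    category = c("MFCC",
                 rep("PROS", 8L),
                 rep("SPEC", 5L),
                 rep("GLOT", 2L)),
    subcategory = c("mfcc0_14",
                    "pcm_loudness", "log_mel_band", "lsp_freq", "f0_envelope",
                    "voicing_prob", "f0final_shimmer", "jitter",
                    "pitch_onsets_duration",
                    "flux", "centroid", "entropy", "rolloff", "band_energies",
                    "glt", "glf"),
    count = c(630L,
              42L, 336L, 336L, 42L, 42L, 76L, 76L, 2L,
              42L, 42L, 42L, 168L, 84L,
              27L, 5L),
    stringsAsFactors = FALSE))
}

#' @describeIn FeatureSchema total number of features in the schema.
#' @param schema a \linkS4class{FeatureSchema}.
#' @export
schemaTotal <- function(schema) sum(schema@table$count)

#' Per-category feature totals
#'
#' @param schema a \linkS4class{FeatureSchema}.
#' @return named integer vector of feature counts in category order.
#' @export
categoryTotals <- function(schema) {
  tab <- schema@table
  cats <- unique(tab$category)
  setNames(vapply(cats, function(cc) sum(tab$count[tab$category == cc]),
                  numeric(1)), cats)
}

#' 1-based column indices of one category's block
#'
#' @param schema a \linkS4class{FeatureSchema}.
#' @param category category name.
#' @return integer vector of column indices into the full feature vector.
#' @export
categoryColumns <- function(schema, category) {
  tot <- categoryTotals(schema)
  if (!category %in% names(tot))
    stop("unknown category: ", category)
  ends <- cumsum(tot)
  starts <- ends - tot + 1L
  seq.int(starts[[category]], ends[[category]])
}

#' Canonical feature column names
#'
#' Names each feature column \code{<category>.<subcategory>.<index>}, in
#' full-vector order.
#'
#' @param schema a \linkS4class{FeatureSchema}.
#' @return character vector of length \code{schemaTotal(schema)}.
#' @export
featureNames <- function(schema) {
  tab <- schema@table
  unlist(lapply(seq_len(nrow(tab)), function(i)
    paste(tab$category[i], tab$subcategory[i], seq_len(tab$count[i]),
          sep = ".")), use.names = FALSE)
}

#' Enumerate the category-combination feature subspaces
#'
#' Forms all non-empty subsets of the schema's feature categories, ordered
#' by subset size and then lexicographically by category position, which for
#' the four default categories yields the standard 15-subspace table:
#' 1 MFCC, 2 PROS, 3 SPEC, 4 GLOT, 5 MFCC+PROS, ..., 15
#' MFCC+PROS+SPEC+GLOT.  Each subspace's columns are the concatenation of
#' its member categories' column blocks in schema order.
#'
#' @param schema a \linkS4class{FeatureSchema}.
#' @return list of \linkS4class{Subspace} objects (length \code{2^4 - 1 = 15}
#'   for the default schema).
#' @examples
#' subs <- enumerateSubspaces(defaultSchema())
#' length(subs)                 # 15
#' subs[[8]]@categories         # PROS, SPEC
#' @export
enumerateSubspaces <- function(schema) {
  validObject(schema)
  cats <- unique(schema@table$category)
  sets <- unlist(lapply(seq_along(cats), function(m)
    combn(cats, m, simplify = FALSE)), recursive = FALSE)
  lapply(seq_along(sets), function(i) {
    members <- sets[[i]]
    cols <- unlist(lapply(members, categoryColumns, schema = schema),
                   use.names = FALSE)
    new("Subspace", id = as.integer(i), categories = members,
        columns = as.integer(cols))
  })
}

#' Write / read a schema as YAML
#'
#' Serialized as an ordered mapping category -> subcategory -> count.
#'
#' @param schema a \linkS4class{FeatureSchema}.
#' @param path file path.
#' @return \code{readSchemaYaml} returns a \linkS4class{FeatureSchema};
#'   \code{writeSchemaYaml} returns \code{path} invisibly.
#' @export
writeSchemaYaml <- function(schema, path) {
  tab <- schema@table
  obj <- lapply(split(tab, factor(tab$category, levels = unique(tab$category))),
                function(d) as.list(setNames(as.integer(d$count), d$subcategory)))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writeSchemaYaml
#' @export
readSchemaYaml <- function(path) {
  obj <- yaml::read_yaml(path)
  rows <- do.call(rbind, lapply(names(obj), function(cc)
    data.frame(category = cc, subcategory = names(obj[[cc]]),
               count = as.integer(unlist(obj[[cc]])),
               stringsAsFactors = FALSE)))
  FeatureSchema(rows)
}

setMethod("show", "FeatureSchema", function(object) {
  tot <- categoryTotals(object)
  cat("FeatureSchema:", sum(tot), "features,",
      length(tot), "categories,", nrow(object@table), "subcategories\n")
  cat(" ", paste(sprintf("%s=%d", names(tot), tot), collapse = ", "), "\n")
})

setMethod("show", "Subspace", function(object) {
  cat(sprintf("Subspace %d: %s (%d columns)\n", object@id,
              paste(object@categories, collapse = " + "),
              length(object@columns)))
})
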