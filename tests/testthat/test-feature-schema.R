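test_that("default schema matches the published feature layout", {
  sc <- defaultSchema()
  expect_equal(schemaTotal(sc), 1992)
  expect_equal(categoryTotals(sc),
               c(MFCC = 630, PROS = 952, SPEC = 378, GLOT = 32))
  expect_equal(length(unique(sc@table$category)), 4L)
  expect_equal(nrow(sc@table), 16L)
  expect_equal(sum(sc@table$count), schemaTotal(sc))
  expect_length(featureNames(sc), 1992L)
  expect_false(anyDuplicated(featureNames(sc)) > 0)
})

test_that("subspace enumeration equals brute-force subset enumeration", {
  sc <- defaultSchema()
  subs <- enumerateSubspaces(sc)
  expect_length(subs, 15L)

  # brute force: all non-empty subsets of the 4 categories, by size then
  # lexicographically by category position
  cats <- c("MFCC", "PROS", "SPEC", "GLOT")
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 4))[-1, ]
  sets <- apply(grid, 1L, function(m) cats[as.logical(m)], simplify = FALSE)
  key <- function(s) c(length(s), match(s, cats), rep(0, 4 - length(s)))
  sets <- sets[order(vapply(sets, function(s) sum(key(s) * 10^(4:0)),
                            numeric(1)))]
  for (i in seq_along(subs))
    expect_identical(subs[[i]]@categories, sets[[i]])

  expect_identical(subs[[8]]@categories, c("PROS", "SPEC"))
  expect_length(subs[[15]]@columns, 1992L)
  expect_length(subs[[7]]@columns, 662L)   # MFCC + GLOT

  # singleton subspaces partition the full column range
  singles <- sort(unlist(lapply(subs[1:4], slot, "columns")))
  expect_identical(singles, 1:1992)

  tot <- categoryTotals(sc)
  for (sp in subs) {
    expect_equal(length(sp@columns), sum(tot[sp@categories]))
    expect_identical(sp@columns,
                     unlist(lapply(sp@categories, categoryColumns,
                                   schema = sc)))
    expect_false(is.unsorted(sp@columns, strictly = TRUE))
  }
})

test_that("schema YAML round trip preserves the layout", {
  sc <- tinySchema()
  path <- withr::local_tempfile(fileext = ".yaml")
  writeSchemaYaml(sc, path)
  back <- readSchemaYaml(path)
  expect_equal(back@table, sc@table)
})

test_that("feature table CSV round trip is lossless", {
  sc <- tinySchema()
  set.seed(11)
  feats <- matrix(rnorm(3 * schemaTotal(sc)) * 10^sample(-8:8, 3 * 92, TRUE),
                  nrow = 3)
  x <- SpeechFeatureSet(feats, c("A1", "A1", "B2"),
                        c("male", "male", "female"), c(1L, 1L, 0L),
                        c(1L, 2L, 1L), sc)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(x, path)
  back <- readFeatureTable(path)
  expect_equal(featureMatrix(back), featureMatrix(x), tolerance = 0)
  expect_identical(subjectIds(back), subjectIds(x))
  expect_identical(genders(back), genders(x))
  expect_identical(labels(back), labels(x))
  expect_identical(taskIds(back), taskIds(x))
  expect_equal(featureSchema(back)@table, sc@table)
})

test_that("malformed feature tables give located parse errors", {
  sc <- tinySchema()
  x <- SpeechFeatureSet(matrix(rnorm(2 * 92), 2), c("A", "B"),
                        c("male", "female"), c(1L, 0L), c(1L, 1L), sc)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(x, path)

  tab <- read.csv(path, check.names = FALSE)
  noTask <- tab[setdiff(names(tab), "task_id")]
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(noTask, p2, row.names = FALSE)
  expect_error(readFeatureTable(p2), "task_id")

  bad <- tab
  bad[[6L]][2L] <- NaN
  write.csv(bad, p2, row.names = FALSE)
  expect_error(readFeatureTable(p2), "row 2")

  bad <- tab
  bad$gender[1L] <- "unknown"
  write.csv(bad, p2, row.names = FALSE)
  expect_error(readFeatureTable(p2), "gender token 'unknown' at row 1")

  bad <- tab
  bad[[7L]] <- as.character(bad[[7L]])
  bad[[7L]][1L] <- "oops"
  write.csv(bad, p2, row.names = FALSE)
  expect_error(readFeatureTable(p2), "row 1")
})

test_that("gender tokens are case-insensitive on read", {
  sc <- tinySchema()
  x <- SpeechFeatureSet(matrix(rnorm(2 * 92), 2), c("A", "B"),
                        c("male", "female"), c(1L, 0L), c(1L, 1L), sc)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(x, path)
  tab <- read.csv(path, check.names = FALSE)
  tab$gender <- c("Male", "FEMALE")
  write.csv(tab, path, row.names = FALSE)
  expect_identical(genders(readFeatureTable(path)), c("male", "female"))
})

test_that("validateManifest reports violations without throwing", {
  sc <- tinySchema()
  good <- tinyDataset(seed = 5L, perCell = 2L, recordings = 3L)$dataset
  expect_identical(nrow(validateManifest(good)), 0L)

  # feature vectors one short of the schema total
  short <- SpeechFeatureSet(matrix(rnorm(2 * 91), 2), c("A", "B"),
                            c("male", "male"), c(1L, 0L), c(1L, 1L),
                            schema = sc)
  rep1 <- validateManifest(short)
  expect_true("length_mismatch" %in% rep1$type)

  # same subject with both labels, duplicated task, and a NaN feature
  bad <- SpeechFeatureSet(matrix(c(rnorm(3 * 92 - 1), NaN), 3, byrow = TRUE),
                          c("A", "A", "A"), c("male", "male", "female"),
                          c(1L, 0L, 1L), c(1L, 1L, 2L), schema = sc)
  rep2 <- validateManifest(bad)
  expect_setequal(rep2$type, c("inconsistent_label", "inconsistent_gender",
                               "duplicate_task", "non_finite"))
})
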