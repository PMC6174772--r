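test_that("fold plans are stratified, speaker-independent and reproducible", {
  gd <- tinyDataset(seed = 19L, perCell = 5L, recordings = 3L)  # 10/10 subjects
  plan <- makeFolds(gd$dataset, nFolds = 10, seed = 2)
  a <- plan@assignments
  # every fold holds exactly one case and one control
  counts <- table(a$fold, a$label)
  expect_true(all(counts == 1L))
  # subjects partition across folds; a subject appears exactly once
  expect_identical(sort(a$subject_id), sort(unique(subjectIds(gd$dataset))))
  # reproducible for a given seed, different for another
  plan2 <- makeFolds(gd$dataset, nFolds = 10, seed = 2)
  expect_identical(plan@assignments, plan2@assignments)
  expect_error(makeFolds(gd$dataset, nFolds = 11, seed = 1), "at least 11")
})

test_that("stratification balances class counts within one of each other", {
  gd <- tinyDataset(seed = 23L, perCell = 4L, recordings = 2L)  # 8/8 subjects
  plan <- makeFolds(gd$dataset, nFolds = 3, seed = 5)
  counts <- table(plan@assignments$fold, plan@assignments$label)
  expect_true(all(apply(counts, 2, function(cl) max(cl) - min(cl) <= 1L)))
})

test_that("confusion metrics follow the depressed-positive convention", {
  m <- confusionMetrics(c(1, 1, 1, 1, 0, 0, 0, 0), c(1, 1, 1, 0, 0, 0, 1, 1))
  expect_identical(c(m$TP, m$FN, m$TN, m$FP), c(3L, 1L, 2L, 2L))
  expect_equal(m$sensitivity, 75)
  expect_equal(m$specificity, 50)
  expect_equal(m$accuracy, 62.5)

  perfect <- confusionMetrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$accuracy),
               c(100, 100, 100))

  allPos <- confusionMetrics(c(1, 0, 1, 0), c(1, 1, 1, 1))
  expect_equal(allPos$sensitivity, 100)
  expect_equal(allPos$specificity, 0)

  # undefined metrics are NA, never zero
  onlyPos <- confusionMetrics(c(1, 1), c(1, 0))
  expect_true(is.na(onlyPos$specificity))
  expect_error(confusionMetrics(c(1, 0), c(1)), "length mismatch")
  expect_error(confusionMetrics(c(1, 2), c(1, 0)), "binary")
})

test_that("one-way ANOVA matches hand-computed references", {
  av <- oneWayAnova(list(c(1, 2, 3), c(4, 5, 6)))
  # between SS 13.5 on 1 df, within SS 4 on 4 df -> F = 13.5
  expect_equal(av$F, 13.5, tolerance = 1e-12)
  expect_equal(av$df1, 1)
  expect_equal(av$df2, 4)
  expect_equal(av$MSE, 1)

  same <- oneWayAnova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  shifted <- oneWayAnova(list(c(1, 2, 3) + 100, c(4, 5, 6) + 100))
  expect_equal(shifted$F, av$F)

  expect_error(oneWayAnova(list(c(1, 2))), "2 groups")
  expect_error(oneWayAnova(list(c(1, 2), c(3))), "at least 2 values")
})

test_that("LSD pairwise tests use the pooled ANOVA mean square", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  av <- oneWayAnova(g)
  tab <- lsdTest(g)
  expect_identical(nrow(tab), 1L)
  # two-group case: t^2 equals the ANOVA F
  expect_equal(tab$t^2, av$F, tolerance = 1e-10)
  expect_equal(abs(tab$t), sqrt(13.5), tolerance = 1e-10)
  expect_identical(tab$df, av$df2)

  sameTab <- lsdTest(list(c(1, 2, 3), c(1, 2, 3)))
  expect_false(sameTab$significant)

  g4 <- list(rnorm(5), rnorm(5), rnorm(5), rnorm(5))
  expect_identical(nrow(lsdTest(g4)), 6L)   # C(4, 2) pairs
})

test_that("cross-validation refits per fold without test-data leakage", {
  gd <- tinyDataset(seed = 27L, perCell = 4L, recordings = 6L)
  cv <- crossValidate(gd$dataset, elrddConfig(knn = 6, dim = 4),
                      nFolds = 2, seed = 3)
  expect_length(cv$folds, 2L)
  # pooled confusion counts equal the sums of the per-fold counts
  for (lvl in c("recording", "subject"))
    for (cnt in c("TP", "FP", "TN", "FN"))
      expect_equal(cv[[lvl]][[cnt]],
                   sum(vapply(cv$folds, function(f) f[[lvl]][[cnt]],
                              numeric(1))))
  # every test subject of a fold is absent from its training side
  for (f in cv$folds)
    expect_length(intersect(f$trainSubjects, f$testSubjects), 0L)
  # the built-in self-test sees no leakage in an honest report
  expect_identical(nrow(checkLeakage(cv, gd$dataset)), 0L)

  # a standardizer fitted on all recordings (train + test) is flagged
  leaky <- cv
  cols1 <- enumerateSubspaces(featureSchema(gd$dataset))[[1]]@columns
  leaky$folds[[1]]$standardizer1 <-
    fitStandardizer(featureMatrix(gd$dataset)[, cols1])
  flagged <- checkLeakage(leaky, gd$dataset)
  expect_true("standardizer_mismatch" %in% flagged$type)
  expect_identical(flagged$fold, 1L)
})
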