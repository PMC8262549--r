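test_that("readTabularCSV reads typed columns, assigns 0-based row ids, and maps empty cells to missing", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,job,y", "31,clerk,0", ",nurse,1", "45,clerk,1"), path)
  sch <- TabularSchema(c(age = "continuous", job = "categorical"),
                       target = "y",
                       levels = list(job = c("clerk", "nurse")))
  ds <- readTabularCSV(path, sch)
  expect_equal(nRows(ds), 3L)
  expect_equal(ncol(features(ds)), 2L)
  expect_identical(rowIds(ds), 0:2)
  expect_true(is.na(features(ds)$age[2]))
  expect_identical(features(ds)$job, c(1L, 2L, 1L))
  expect_identical(labels(ds), c(0L, 1L, 1L))
})

test_that("readTabularCSV rejects malformed headers", {
  sch <- TabularSchema(c(age = "continuous"), target = "y")
  no_target <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age", "1"), no_target)
  expect_error(readTabularCSV(no_target, sch), "missing declared column")
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,age,y", "1,2,0"), dup)
  expect_error(readTabularCSV(dup, sch), "duplicate")
  # unparseable continuous cell becomes missing, not an error
  odd <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,y", "not-a-number,1"), odd)
  expect_true(is.na(features(readTabularCSV(odd, sch))$age[1]))
})

test_that("dataset CSV round-trips through write + read", {
  ds <- fx_dataset(25L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeTabularCSV(ds, path)
  back <- readTabularCSV(path, schema(ds))
  expect_equal(features(back), features(ds), tolerance = 1e-12)
  expect_identical(labels(back), labels(ds))
})

test_that("undersampling equalizes classes, keeps all minority rows, and preserves order", {
  ds <- fx_dataset(120L)
  y <- c(rep(0L, 90), rep(1L, 30))
  ds@labels <- y
  bal <- balanceByUndersampling(ds, seed = 5L)
  yb <- labels(bal)
  expect_equal(sum(yb == 0L), 30L)
  expect_equal(sum(yb == 1L), 30L)
  expect_equal(nRows(bal), 60L)
  # every minority row id retained
  expect_true(all(rowIds(ds)[y == 1L] %in% rowIds(bal)))
  # relative order preserved
  expect_identical(rowIds(bal), sort(rowIds(bal)))
  # determinism
  expect_identical(rowIds(balanceByUndersampling(ds, seed = 5L)),
                   rowIds(bal))
})

test_that("undersampling is the identity on balanced data and rejects degenerate labels", {
  ds <- fx_dataset(20L)
  ds@labels <- rep_len(c(0L, 1L), 20L)
  bal <- balanceByUndersampling(ds, seed = 1L)
  expect_identical(features(bal), features(ds))
  expect_identical(rowIds(bal), rowIds(ds))
  ds@labels <- rep(1L, 20L)
  expect_error(balanceByUndersampling(ds, 1L), "degenerate")
})

test_that("filterRows applies a strict nonnull threshold and its exclusion counts add up", {
  sch <- TabularSchema(c(a = "continuous", b = "continuous",
                         c = "continuous"), target = "y")
  feats <- data.frame(a = c(1, NA, NA, 4, 5), b = c(1, 2, NA, NA, 5),
                      c = c(1, 3, 3, NA, 5))
  ds <- TabularDataset(sch, feats, labels = c(0L, 1L, NA, 1L, 0L))
  # rows have 3, 2, 1, 1, 3 nonnull cells; "more than 1" keeps rows 1, 2, 5
  out <- filterRows(ds, minNonnull = 1L)
  expect_identical(rowIds(out), c(0L, 1L, 4L))
  expect_identical(attr(out, "exclusions"),
                   c(nonnull = 2L, unlabeled = 0L))
  # boundary: a row with exactly minNonnull nonmissing cells is dropped
  out2 <- filterRows(ds, minNonnull = 2L)
  expect_identical(rowIds(out2), c(0L, 4L))
  # label rule applies after the nonnull rule and the counts always sum
  ds2 <- TabularDataset(sch, feats, labels = c(0L, NA, NA, 1L, NA))
  out3 <- filterRows(ds2, minNonnull = 1L, requireLabel = TRUE)
  ex <- attr(out3, "exclusions")
  expect_equal(nRows(ds2) - nRows(out3), sum(ex))
  expect_identical(ex, c(nonnull = 2L, unlabeled = 2L))
  # identity on complete labeled data
  full <- fx_dataset(15L)
  expect_identical(rowIds(filterRows(full, 0L, TRUE)), rowIds(full))
  expect_error(filterRows(full, minNonnull = 99L), "exceeds")
})

test_that("stratified split is exact, label-stratified and seed-deterministic", {
  ds <- fx_dataset(100L)
  sp <- splitTrainTest(ds, 0.2, seed = 9L)
  expect_equal(nRows(sp$train), 80L)
  expect_equal(nRows(sp$test), 20L)
  expect_equal(sum(labels(sp$test) == 0L), 10L)
  expect_equal(sum(labels(sp$test) == 1L), 10L)
  # exact partition
  expect_setequal(c(rowIds(sp$train), rowIds(sp$test)), rowIds(ds))
  expect_length(intersect(rowIds(sp$train), rowIds(sp$test)), 0)
  # determinism
  sp2 <- splitTrainTest(ds, 0.2, seed = 9L)
  expect_identical(rowIds(sp2$test), rowIds(sp$test))
  # tiny case: 4 rows, fraction 0.5, one of each class per side
  tiny <- fx_dataset(4L)
  tiny@labels <- c(0L, 1L, 0L, 1L)
  sp3 <- splitTrainTest(tiny, 0.5, seed = 0L)
  expect_equal(nRows(sp3$train), 2L)
  expect_equal(sort(labels(sp3$test)), c(0L, 1L))
  # stratification error
  tiny@labels <- c(0L, 1L, 1L, 1L)
  expect_error(splitTrainTest(tiny, 0.5, 0L), "stratify")
  expect_error(splitTrainTest(ds, 1.2, 0L), "testFraction")
})

test_that("vertical split honors the plan, strips labels, and round-trips column-wise", {
  ds <- fx_dataset(40L)
  plan <- VerticalPlan(list(c("grade", "age"), c("job", "bmi")))
  parts <- verticalSplit(ds, plan)
  expect_length(parts, 2L)
  expect_identical(featureNames(schema(parts[[1]])), c("grade", "age"))
  expect_identical(vapply(parts, siteIndex, integer(1)), c(0L, 1L))
  # no labels anywhere; row ids identical across partitions
  for (p in parts) {
    expect_null(labels(p@dataset))
    expect_identical(rowIds(p), rowIds(ds))
  }
  # round-trip identity: reassembling the slices reproduces the grid
  reassembled <- cbind(features(parts[[1]]), features(parts[[2]]))
  expect_identical(reassembled[, colnames(features(ds))], features(ds))
})

test_that("invalid plans are rejected", {
  ds <- fx_dataset(10L)
  expect_error(verticalSplit(ds, VerticalPlan(list(c("job", "ghost"),
                                                   c("age", "bmi", "grade")))),
               "nonexistent")
  expect_error(verticalSplit(ds, VerticalPlan(list(c("job", "age")))),
               "omits")
  expect_error(VerticalPlan(list(c("a", "b"), c("b", "c"))), "at most one")
  expect_error(VerticalPlan(list(character(0), "a")), "empty")
})

test_that("schema YAML round-trips", {
  sch <- fx_schema()
  path <- withr::local_tempfile(fileext = ".yaml")
  writeSchemaYAML(sch, path)
  back <- readSchemaYAML(path)
  expect_identical(featureNames(back), featureNames(sch))
  expect_identical(featureKinds(back), featureKinds(sch))
  expect_identical(cardinalities(back), cardinalities(sch))
  expect_identical(targetName(back), targetName(sch))
})

test_that("schema invariants are enforced", {
  expect_error(TabularSchema(c(a = "continuous", a = "continuous"),
                             target = "y"), "unique")
  expect_error(TabularSchema(c(a = "continuous"), target = "a"),
               "must not be among")
  expect_error(TabularSchema(c(a = "categorical"), target = "y",
                             levels = list(a = "only")), ">= 2")
})
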