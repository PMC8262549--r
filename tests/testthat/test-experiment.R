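test_that("relative percent difference matches its reporting convention", {
  expect_equal(relativeDifference(0.83, 0.82), -1.20)
  expect_equal(relativeDifference(0.90, 0.82), -8.89)
  expect_equal(relativeDifference(0.67, 0.76), 13.43)
  expect_equal(relativeDifference(0.5, 0.5), 0)
  expect_equal(relativeDifference(0.83, 0.82, digits = Inf),
               100 * (0.82 - 0.83) / 0.83)
  expect_error(relativeDifference(0, 0.5), "non-positive")
})

small_benchmark <- function() {
  memo_fixture("bench_small", {
    ds <- generateTabular(fx_spec_small(n = 900L))
    runBenchmark(ds, fx_plan_small(),
                 fx_ae_config_small(epochs = 6L),
                 ClassifierConfig(epochs = 4L), seed = 11L)
  })
}

test_that("a k-site benchmark produces one EvalResult per arm and phase", {
  rep_ <- small_benchmark()
  expect_s4_class(rep_, "BenchmarkReport")
  expect_length(rep_@evals, 6L)  # (central + 2 sites) x (before, after)
  g <- benchmarkGrid(rep_)
  expect_setequal(unique(g$arm), c("central", "site_0", "site_1"))
  expect_setequal(unique(g$phase), c("before", "after"))
  expect_true(all(g$accuracy >= 0 & g$accuracy <= 1))
  expect_true(all(g$auroc >= 0 & g$auroc <= 1))
  # every arm evaluated on the same held-out rows
  n_test <- length(rep_@metadata$test_row_ids)
  for (ev in rep_@evals) expect_equal(ev@nEval, n_test)
})

test_that("a 3-site plan yields exactly 8 evaluation results", {
  spec <- SyntheticSpec(
    nRows = 400L,
    contDeltas = stats::setNames(rep(0.8, 6), sprintf("cont_%02d", 1:6)),
    catSpecs = stats::setNames(
      lapply(c(3L, 4L), function(card) list(cardinality = card,
                                            signal = 0.2)),
      c("cat_01", "cat_02")),
    seed = 21L)
  ds <- generateTabular(spec)
  rep_ <- runBenchmark(ds, defaultPlan(spec, dims = c(3L, 3L, 2L)),
                       AutoencoderConfig(hiddenDims = c(8L, 16L, 8L),
                                         epochs = 3L),
                       ClassifierConfig(epochs = 2L), seed = 21L)
  expect_length(rep_@evals, 8L)
  expect_equal(nrow(benchmarkGrid(rep_)), 8L)
  expect_equal(nrow(benchmarkDifferences(rep_)), 4L)
})

test_that("stored differences are exactly recomputable from the stored metrics", {
  rep_ <- small_benchmark()
  g <- benchmarkGrid(rep_)
  d <- benchmarkDifferences(rep_)
  for (a in d$arm) {
    b <- g[g$arm == a & g$phase == "before", ]
    f <- g[g$arm == a & g$phase == "after", ]
    expect_identical(d$accuracy_diff[d$arm == a],
                     relativeDifference(b$accuracy, f$accuracy))
    expect_identical(d$auroc_diff[d$arm == a],
                     relativeDifference(b$auroc, f$auroc))
  }
})

test_that("a single-site plan makes central/before coincide with site_0/before", {
  ds <- generateTabular(fx_spec_small(n = 400L))
  plan <- VerticalPlan(list(featureNames(schema(ds))))
  rep_ <- runBenchmark(ds, plan, fx_ae_config_small(epochs = 2L),
                       ClassifierConfig(epochs = 2L), seed = 3L)
  expect_identical(rep_@evals[["central.before"]]@scores,
                   rep_@evals[["site_0.before"]]@scores)
  expect_equal(rep_@evals[["central.before"]]@accuracy,
               rep_@evals[["site_0.before"]]@accuracy)
})

test_that("benchmark reports serialize to JSON and CSV", {
  rep_ <- small_benchmark()
  js <- withr::local_tempfile(fileext = ".json")
  cs <- withr::local_tempfile(fileext = ".csv")
  writeBenchmarkJSON(rep_, js, cs)
  obj <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(obj$grid), 6L)
  expect_equal(obj$plan_dims, c(3L, 2L))
  expect_equal(obj$grid$accuracy,
               benchmarkGrid(rep_)$accuracy, tolerance = 1e-12)
  expect_equal(nrow(utils::read.csv(cs)), 6L)
})

test_that("the code-dimension sweep returns ordered rows and skips undercomplete widths", {
  ds <- generateTabular(fx_spec_small(n = 600L))
  # widest site input here is 4 (cat4->2 + two continuous)
  tbl <- suppressWarnings(
    sweepCodeDim(ds, fx_plan_small(), codeDims = c(16L, 2L, 8L),
                 clfConfig = ClassifierConfig(epochs = 2L), seed = 5L,
                 aeConfig = fx_ae_config_small(epochs = 2L)))
  expect_equal(tbl$code_dim, c(8L, 16L))
  expect_identical(attr(tbl, "skipped"), 2L)
  expect_warning(
    sweepCodeDim(ds, fx_plan_small(), codeDims = c(2L, 8L),
                 clfConfig = ClassifierConfig(epochs = 2L), seed = 5L,
                 aeConfig = fx_ae_config_small(epochs = 2L)),
    "skipping")
})

test_that("latent utility does not degrade as the code layer widens (strong signal)", {
  spec <- SyntheticSpec(
    nRows = 1600L,
    contDeltas = stats::setNames(rep(1.2, 4), sprintf("cont_%02d", 1:4)),
    seed = 13L)
  ds <- generateTabular(spec)
  plan <- defaultPlan(spec, dims = c(2L, 2L))
  tbl <- sweepCodeDim(ds, plan, codeDims = c(2L, 4L, 8L, 16L),
                      clfConfig = ClassifierConfig(epochs = 6L), seed = 13L,
                      aeConfig = AutoencoderConfig(epochs = 8L))
  expect_equal(nrow(tbl), 4L)
  rho <- stats::cor(tbl$code_dim, tbl$accuracy, method = "spearman")
  expect_gte(rho, 0)
})
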