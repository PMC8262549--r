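test_that("embedding widths follow the registered rule and sum to the input width", {
  # cardinality 2 -> width 1 under the default min(50, ceiling(card/2))
  sch2 <- TabularSchema(c(a = "categorical"), target = "y",
                        levels = list(a = c("x", "z")))
  expect_identical(unname(embeddingWidths(sch2)["a"]), 1L)
  # all-continuous site: widths all 1, n = column count
  sch3 <- TabularSchema(c(u = "continuous", v = "continuous",
                          w = "continuous"), target = "y")
  expect_equal(attr(embeddingWidths(sch3), "n_input"), 3L)
  # mixed site with cardinalities (9, 16) and 3 continuous: 5 + 8 + 3 = 16
  sch <- TabularSchema(
    kinds = c(a = "categorical", b = "categorical", x = "continuous",
              y = "continuous", z = "continuous"),
    target = "out",
    levels = list(a = paste0("L", 1:9), b = paste0("L", 1:16)))
  w <- embeddingWidths(sch)
  expect_identical(unname(w[c("a", "b")]), c(5L, 8L))
  expect_equal(attr(w, "n_input"), 16L)
  expect_error(embeddingWidths(sch, rule = "no-such-rule"), "unknown")
  # rules are swappable through the registry
  registerEmbeddingRule("flat2", function(card) 2L)
  expect_equal(attr(embeddingWidths(sch, "flat2"), "n_input"), 7L)
})

test_that("overcompleteness (code width >= post-embedding input width) is enforced", {
  ds <- generateTabular(fx_spec_small())
  parts <- verticalSplit(ds, fx_plan_small())
  # site 0 has post-embedding width 2 + 1 + 1 = 4
  expect_error(
    trainAutoencoder(parts[[1]], AutoencoderConfig(
      hiddenDims = c(2L, 3L, 2L), epochs = 1L), seed = 1L),
    "overcompleteness")
  # the m == n boundary is accepted
  fit <- trainAutoencoder(parts[[1]], AutoencoderConfig(
    hiddenDims = c(4L, 4L, 4L), epochs = 1L, batchSize = 256L), seed = 1L)
  expect_s4_class(fit, "AutoencoderModel")
  expect_equal(codeDim(fit), 4L)
})

test_that("training is deterministic given (partition, config, seed) and records its schedule", {
  parts <- fx_trained_ae()$parts
  cfg <- fx_ae_config_small(epochs = 4L)
  a <- trainAutoencoder(parts[[2]], cfg, seed = 9L)
  b <- trainAutoencoder(parts[[2]], cfg, seed = 9L)
  expect_identical(lossHistory(a), lossHistory(b))
  expect_identical(a@params, b@params)
  # learning-rate schedule: lr(t) = 0.01 * 0.99^(t-1), ratio exactly 0.99
  expect_identical(lrHistory(a), 0.01 * 0.99^(0:3))
  r <- lrHistory(a)[-1] / lrHistory(a)[-4]
  expect_equal(r, rep(0.99, 3), tolerance = 1e-14)
  # a different seed changes the fit
  expect_false(identical(lossHistory(trainAutoencoder(parts[[2]], cfg,
                                                      seed = 10L)),
                         lossHistory(a)))
})

test_that("reconstruction loss falls over training on synthetic data", {
  spec <- SyntheticSpec(
    nRows = 1000L,
    contDeltas = stats::setNames(rep(0.8, 5), sprintf("cont_%02d", 1:5)),
    seed = 4L)
  ds <- generateTabular(spec)
  part <- verticalSplit(ds, VerticalPlan(list(featureNames(schema(ds)))))[[1]]
  fit <- trainAutoencoder(part, AutoencoderConfig(
    hiddenDims = c(8L, 16L, 8L), epochs = 50L), seed = 4L)
  h <- lossHistory(fit)
  expect_length(h, 50L)
  # epoch-averaged loss over the last 10 epochs below the first epoch's
  expect_lt(mean(utils::tail(h, 10)), h[1])
  # and the generic trend property: final 20% below first 20%
  expect_lt(mean(utils::tail(h, 10)), mean(utils::head(h, 10)))
})

test_that("a constant-column site collapses to a flat code with near-floor loss", {
  sch <- TabularSchema(c(c1 = "continuous", c2 = "continuous"),
                       target = "y")
  ds <- TabularDataset(sch, data.frame(c1 = rep(3.5, 200),
                                       c2 = rep(-1, 200)))
  part <- verticalSplit(ds, VerticalPlan(list(c("c1", "c2"))))[[1]]
  fit <- trainAutoencoder(part, AutoencoderConfig(
    hiddenDims = c(4L, 8L, 4L), epochs = 40L), seed = 1L)
  # standardized constant input is all-zero, so the reconstruction target is
  # reachable and the loss should approach the weight-decay-only floor
  expect_lt(reconstructionLoss(fit, part), 1e-2)
  codes <- latentCodes(encodeLatent(fit, part))
  expect_equal(unname(apply(codes, 2, stats::var)), rep(0, ncol(codes)))
})

test_that("encoding preserves shape, row order, and is a pure per-row function", {
  fx <- fx_trained_ae()
  lat <- encodeLatent(fx$model, fx$parts[[1]])
  expect_equal(dim(latentCodes(lat)), c(nRows(fx$parts[[1]]), 32L))
  expect_identical(rowIds(lat), rowIds(fx$parts[[1]]))
  expect_true(all(is.finite(latentCodes(lat))))
  # repeat calls identical
  expect_identical(latentCodes(encodeLatent(fx$model, fx$parts[[1]])),
                   latentCodes(lat))
  # single-row partition
  one <- verticalSplit(vflsim:::.take_rows(fx$ds, 1L), fx_plan_small())[[1]]
  expect_equal(dim(latentCodes(encodeLatent(fx$model, one))), c(1L, 32L))
  # row order and duplicates never affect per-row codes
  perm <- c(5L, 1L, 5L, 2L)
  permuted <- verticalSplit(
    TabularDataset(schema(fx$ds), features(fx$ds)[perm, , drop = FALSE]),
    fx_plan_small())[[1]]
  expect_equal(latentCodes(encodeLatent(fx$model, permuted)),
               latentCodes(lat)[perm, , drop = FALSE],
               ignore_attr = TRUE)
  # schema mismatch is an encode error
  expect_error(encodeLatent(fx$model, fx$parts[[2]]), "schema")
})

test_that("trained codes are not an identity copy of the inputs", {
  fx <- fx_trained_ae()
  lat <- encodeLatent(fx$model, fx$parts[[1]])
  expect_false(ncol(latentCodes(lat)) ==
                 ncol(features(fx$parts[[1]])))
  rep_ <- assessPerturbation(fx$parts[[1]], lat)
  expect_true(rep_@featureSpaceChanged)
  expect_false(rep_@identityFlag)
})

test_that("reconstruction loss matches hand-computed closed forms on a degenerate model", {
  sch <- TabularSchema(c(g = "categorical", u = "continuous",
                         v = "continuous"),
                       target = "y", levels = list(g = paste0("L", 1:5)))
  feats <- data.frame(g = c(1L, 3L), u = c(2, 6), v = c(-1, 3))
  ds <- TabularDataset(sch, feats)
  part <- verticalSplit(ds, VerticalPlan(list(c("g", "u", "v"))))[[1]]
  model <- trainAutoencoder(part, AutoencoderConfig(
    hiddenDims = c(8L, 8L, 8L), epochs = 1L, batchSize = 2L), seed = 1L)
  # zero every parameter except a chosen continuous-head bias: the decoder
  # then outputs a constant, and the loss has an exact closed form
  p <- model@params
  p$layers <- lapply(p$layers, function(l) list(W = l$W * 0, b = l$b * 0))
  p$emb <- lapply(p$emb, function(e) e * 0)
  p$cont_head$W <- p$cont_head$W * 0
  p$cont_head$b <- c(0.5, -0.25)
  p$cat_heads <- lapply(p$cat_heads,
                        function(h) list(W = h$W * 0, b = h$b * 0))
  model@params <- p
  # standardized inputs (median-imputed, mean/sd over the 2 rows)
  zu <- scale(c(2, 6))[, 1]
  zv <- scale(c(-1, 3))[, 1]
  expected <- mean((0.5 - zu)^2 + (-0.25 - zv)^2) + log(5)
  expect_equal(reconstructionLoss(model, part), expected,
               tolerance = 1e-9)
})

test_that("site models survive an archive round-trip", {
  fx <- fx_trained_ae()
  path <- withr::local_tempfile(fileext = ".rds")
  saveAutoencoder(fx$model, path)
  back <- loadAutoencoder(path)
  expect_identical(back@params, fx$model@params)
  expect_identical(latentCodes(encodeLatent(back, fx$parts[[1]])),
                   latentCodes(encodeLatent(fx$model, fx$parts[[1]])))
})
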