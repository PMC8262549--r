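#' Signed relative percent difference between two metric values
#'
#' `100 * (after - before) / before`, rounded for reporting (default 2
#' decimals): the form in which before/after utility changes are quoted
#' (e.g. accuracy 0.83 -> 0.82 is -1.20, not -1.00).
#'
#' @param before baseline metric value, strictly positive.
#' @param after comparison metric value.
#' @param digits decimals for reporting (use `Inf` for full precision).
#' @return signed percent difference.
#' @export
relativeDifference <- function(before, after, digits = 2) {
  if (any(before <= 0))
    stop("relative difference undefined for a non-positive baseline")
  d <- 100 * (after - before) / before
  if (is.finite(digits)) round(d, digits) else d
}

.arm_names <- function(k) c("central", sprintf("site_%d", seq_len(k) - 1L))

#' Run the full before/after-VFL benchmark on one dataset
#'
#' Executes the complete protocol on a labeled, balanced dataset:
#' \enumerate{
#'   \item one stratified train/test split, fixed before any site sees data,
#'     shared by every arm;
#'   \item \emph{central/before}: classifier on all original features;
#'   \item \emph{site_i/before}: classifier on site i's raw slice;
#'   \item per site: autoencoder trained on the site's training rows only,
#'     then train and test rows encoded;
#'   \item \emph{site_i/after}: classifier on site i's latent codes;
#'   \item \emph{central/after}: classifier on the relay-aggregated latent
#'     matrix (the vertical-federated arm);
#'   \item every model evaluated (accuracy, AUROC) on the same held-out
#'     rows, plus signed relative percent differences per arm.
#' }
#'
#' @param ds labeled (and ideally class-balanced) [TabularDataset-class].
#' @param plan a [VerticalPlan-class] over the dataset's feature columns.
#' @param aeConfig an [AutoencoderConfig-class] shared by all sites.
#' @param clfConfig a [ClassifierConfig-class] shared by all arms.
#' @param seed master seed; split, autoencoder and classifier seeds are
#'   fixed offsets of it.
#' @param testFraction held-out proportion for the shared split.
#' @param keepModels retain the trained per-site autoencoders in the report
#'   metadata (`ae_models`), e.g. to encode further rows afterwards.
#' @return a [BenchmarkReport-class].
#' @export
runBenchmark <- function(ds, plan, aeConfig = AutoencoderConfig(),
                         clfConfig = ClassifierConfig(), seed = 0L,
                         testFraction = 0.2, keepModels = FALSE) {
  if (is.null(labels(ds))) stop("benchmark needs a labeled dataset")
  validatePlan(plan, schema(ds))
  t0 <- proc.time()[["elapsed"]]
  k <- length(plan@assignments)
  sp <- splitTrainTest(ds, testFraction, seed)
  y_train <- labels(sp$train)
  y_test <- labels(sp$test)

  evals <- list()
  run_arm <- function(arm, phase, x_train, x_test, clf_seed) {
    model <- tryCatch(
      trainClassifier(x_train, y_train, clfConfig, clf_seed),
      error = function(e) stop(sprintf("arm %s/%s: %s", arm, phase,
                                       conditionMessage(e)), call. = FALSE))
    evals[[paste(arm, phase, sep = ".")]] <<-
      evaluateClassifier(model, x_test, y_test)
  }

  # one classifier seed per phase: arms differ only in their input, so the
  # k = 1 degenerate plan makes central/before and site_0/before coincide
  run_arm("central", "before", sp$train, sp$test, seed + 1000L)
  parts_train <- verticalSplit(sp$train, plan)
  parts_test <- verticalSplit(sp$test, plan)
  for (i in seq_len(k))
    run_arm(sprintf("site_%d", i - 1L), "before",
            parts_train[[i]]@dataset, parts_test[[i]]@dataset,
            seed + 1000L)

  ae_models <- lapply(parts_train, function(p)
    tryCatch(trainAutoencoder(p, aeConfig, seed),
             error = function(e) stop(sprintf("arm site_%d/autoencoder: %s",
                                              siteIndex(p),
                                              conditionMessage(e)),
                                      call. = FALSE)))
  lat_train <- lapply(seq_len(k), function(i)
    encodeLatent(ae_models[[i]], parts_train[[i]]))
  lat_test <- lapply(seq_len(k), function(i)
    encodeLatent(ae_models[[i]], parts_test[[i]]))

  for (i in seq_len(k))
    run_arm(sprintf("site_%d", i - 1L), "after",
            lat_train[[i]], lat_test[[i]], seed + 2000L)
  run_arm("central", "after",
          aggregateLatents(lat_train), aggregateLatents(lat_test),
          seed + 2000L)

  arms <- .arm_names(k)
  grid <- do.call(rbind, lapply(arms, function(a)
    do.call(rbind, lapply(c("before", "after"), function(ph) {
      ev <- evals[[paste(a, ph, sep = ".")]]
      data.frame(arm = a, phase = ph, accuracy = ev@accuracy,
                 auroc = ev@auroc)
    }))))
  differences <- do.call(rbind, lapply(arms, function(a) {
    b <- evals[[paste(a, "before", sep = ".")]]
    f <- evals[[paste(a, "after", sep = ".")]]
    data.frame(arm = a,
               accuracy_diff = relativeDifference(b@accuracy, f@accuracy),
               auroc_diff = relativeDifference(b@auroc, f@auroc))
  }))

  new("BenchmarkReport", grid = grid, differences = differences,
      evals = evals,
      metadata = list(
        plan = plan, aeConfig = aeConfig, clfConfig = clfConfig,
        seed = seed, testFraction = testFraction,
        test_row_ids = rowIds(sp$test),
        ae_loss_histories = lapply(ae_models, lossHistory),
        ae_models = if (keepModels) ae_models,
        elapsed_seconds = proc.time()[["elapsed"]] - t0))
}

#' @describeIn runBenchmark the (arm, phase, accuracy, auroc) grid.
#' @param x a `BenchmarkReport`.
#' @export
setMethod("benchmarkGrid", "BenchmarkReport", function(x) x@grid)

#' @describeIn runBenchmark per-arm relative percent differences.
#' @export
setMethod("benchmarkDifferences", "BenchmarkReport",
          function(x) x@differences)

setMethod("show", "BenchmarkReport", function(object) {
  g <- object@grid
  d <- object@differences
  cat("BenchmarkReport (accuracy / AUROC)\n")
  for (a in unique(g$arm)) {
    b <- g[g$arm == a & g$phase == "before", ]
    f <- g[g$arm == a & g$phase == "after", ]
    dd <- d[d$arm == a, ]
    cat(sprintf("  %-8s before %.2f / %.2f   after %.2f / %.2f   diff %+.2f%% / %+.2f%%\n",
                a, b$accuracy, b$auroc, f$accuracy, f$auroc,
                dd$accuracy_diff, dd$auroc_diff))
  }
  cat(sprintf("  (%d held-out rows; %.1f s)\n",
              length(object@metadata$test_row_ids),
              object@metadata$elapsed_seconds))
})

#' Serialize a benchmark report
#'
#' JSON keeps full-precision metrics plus run metadata; the optional CSV is
#' the metric grid rounded to 2 decimals for tabulation.
#'
#' @param report a [BenchmarkReport-class].
#' @param path JSON output path.
#' @param csvPath optional CSV path for the rounded metric grid.
#' @return `path`, invisibly.
#' @export
writeBenchmarkJSON <- function(report, path, csvPath = NULL) {
  obj <- list(
    grid = report@grid,
    differences = report@differences,
    seed = report@metadata$seed,
    test_fraction = report@metadata$testFraction,
    n_test = length(report@metadata$test_row_ids),
    plan_dims = lengths(report@metadata$plan@assignments),
    elapsed_seconds = report@metadata$elapsed_seconds)
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(csvPath)) {
    g <- report@grid
    g$accuracy <- round(g$accuracy, 2)
    g$auroc <- round(g$auroc, 2)
    utils::write.csv(g, csvPath, row.names = FALSE)
  }
  invisible(path)
}

#' Sweep the code-layer width
#'
#' Re-runs the vertical-federated arm (per-site autoencoders, relay
#' aggregation, central classifier on the aggregate) for each candidate code
#' width, with autoencoder hidden layers rescaled to
#' `[code_dim/2, code_dim, code_dim/2]`. Widths violating overcompleteness
#' for any site are skipped with a warning and recorded.
#'
#' @param ds labeled [TabularDataset-class].
#' @param plan a [VerticalPlan-class].
#' @param codeDims integer candidate code widths.
#' @param clfConfig a [ClassifierConfig-class].
#' @param seed master seed (same split protocol as [runBenchmark()]).
#' @param aeConfig template [AutoencoderConfig-class] supplying the training
#'   regime (lr, decay, epochs, ...); its hidden dims are replaced per
#'   sweep point.
#' @param testFraction held-out proportion.
#' @return data.frame with one row per evaluated code width (`code_dim`,
#'   `accuracy`, `auroc`), ordered by code width; skipped widths in
#'   attribute `skipped`.
#' @export
sweepCodeDim <- function(ds, plan, codeDims, clfConfig = ClassifierConfig(),
                         seed = 0L, aeConfig = AutoencoderConfig(),
                         testFraction = 0.2) {
  validatePlan(plan, schema(ds))
  codeDims <- sort(as.integer(codeDims))
  widths <- vapply(plan@assignments, function(cols) {
    w <- embeddingWidths(subsetSchema(schema(ds), cols),
                         aeConfig@embeddingRule)
    attr(w, "n_input")
  }, integer(1))
  max_n <- max(widths)
  ok <- codeDims >= max_n
  if (any(!ok))
    warning(sprintf(
      "skipping code dim(s) %s: below the widest site input (%d)",
      paste(codeDims[!ok], collapse = ", "), max_n))

  sp <- splitTrainTest(ds, testFraction, seed)
  parts_train <- verticalSplit(sp$train, plan)
  parts_test <- verticalSplit(sp$test, plan)
  rows <- lapply(codeDims[ok], function(m) {
    cfg <- aeConfig
    cfg@hiddenDims <- as.integer(c(max(1L, m %/% 2L), m, max(1L, m %/% 2L)))
    lat_train <- list()
    lat_test <- list()
    for (i in seq_along(parts_train)) {
      ae <- trainAutoencoder(parts_train[[i]], cfg, seed)
      lat_train[[i]] <- encodeLatent(ae, parts_train[[i]])
      lat_test[[i]] <- encodeLatent(ae, parts_test[[i]])
    }
    model <- trainClassifier(aggregateLatents(lat_train), labels(sp$train),
                             clfConfig, seed + 2000L)
    ev <- evaluateClassifier(model, aggregateLatents(lat_test),
                             labels(sp$test))
    data.frame(code_dim = m, accuracy = ev@accuracy, auroc = ev@auroc)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(code_dim = integer(0), accuracy = numeric(0),
               auroc = numeric(0))
  attr(out, "skipped") <- codeDims[!ok]
  out
}
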