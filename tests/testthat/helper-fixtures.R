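# Shared fixtures. Expensive objects (full-scale benchmarks) are memoized in
# an environment that persists across test files within one test run.

.fx <- new.env(parent = emptyenv())

memo_fixture <- function(key, expr) {
  if (!exists(key, envir = .fx, inherits = FALSE))
    assign(key, force(expr), envir = .fx)
  get(key, envir = .fx, inherits = FALSE)
}

fx_schema <- function() {
  TabularSchema(
    kinds = c(job = "categorical", grade = "categorical",
              age = "continuous", bmi = "continuous"),
    target = "y",
    levels = list(job = c("a", "b", "c"), grade = paste0("g", 1:4)))
}

fx_dataset <- function(n = 60L, seed = 42L) {
  withr::with_seed(seed, TabularDataset(
    fx_schema(),
    data.frame(job = sample(1:3, n, TRUE), grade = sample(1:4, n, TRUE),
               age = stats::rnorm(n), bmi = stats::rnorm(n)),
    labels = sample(rep_len(c(0L, 1L), n))))
}

# small mixed-type cohort with a clear label signal, 2 sites
fx_spec_small <- function(n = 1200L, seed = 7L) {
  SyntheticSpec(
    nRows = as.integer(n),
    contDeltas = c(cont_01 = 1, cont_02 = 0.8, cont_03 = 0.5),
    catSpecs = list(cat_01 = list(cardinality = 4L, signal = 0.3),
                    cat_02 = list(cardinality = 6L, signal = 0.2)),
    seed = as.integer(seed))
}

fx_plan_small <- function() {
  VerticalPlan(list(c("cat_01", "cont_01", "cont_03"),
                    c("cat_02", "cont_02")))
}

fx_ae_config_small <- function(epochs = 10L) {
  AutoencoderConfig(hiddenDims = c(16L, 32L, 16L), epochs = epochs)
}

# one trained small autoencoder, reused by several files
fx_trained_ae <- function() {
  memo_fixture("trained_ae_small", {
    ds <- generateTabular(fx_spec_small())
    parts <- verticalSplit(ds, fx_plan_small())
    list(ds = ds, parts = parts,
         model = trainAutoencoder(parts[[1]], fx_ae_config_small(), seed = 3L))
  })
}

# reduced-epoch configs used for full-scale (23k-row) runs in tests
fx_ae_config_reduced <- function() {
  AutoencoderConfig(epochs = 12L, batchSize = 128L)
}

fx_clf_config_reduced <- function() {
  ClassifierConfig(epochs = 8L, batchSize = 256L)
}

fx_adult_benchmark_reduced <- function(seed) {
  memo_fixture(paste0("adult_reduced_", seed), {
    spec <- syntheticPreset("adult_like", seed = seed)
    runBenchmark(generateTabular(spec), defaultPlan(spec),
                 fx_ae_config_reduced(), fx_clf_config_reduced(),
                 seed = seed)
  })
}

# the full default-parameter benchmark on the largest fixture (one run)
fx_adult_benchmark_default <- function() {
  memo_fixture("adult_default", {
    spec <- syntheticPreset("adult_like", seed = 101L)
    runBenchmark(generateTabular(spec), defaultPlan(spec),
                 AutoencoderConfig(), ClassifierConfig(), seed = 101L)
  })
}

# brute-force all-pairs AUROC oracle (independent of the package's midrank
# implementation)
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}
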