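#' @import methods
NULL

## ---- core tabular containers -------------------------------------------

#' TabularSchema: typed column metadata for a mixed-type table
#'
#' Ordered feature columns, each either `"categorical"` (with an explicit
#' level set, cardinality >= 2) or `"continuous"`, plus the name of the
#' binary target column. The schema is the contract every dataset, vertical
#' plan and model in the package is checked against.
#'
#' @slot featureNames character vector of feature column names, in order.
#' @slot featureKinds parallel vector, each `"categorical"` or `"continuous"`.
#' @slot levels named list; one character vector of levels per categorical
#'   column.
#' @slot target name of the binary target column (never a feature).
#' @export
setClass("TabularSchema", representation(
  featureNames = "character",
  featureKinds = "character",
  levels       = "list",
  target       = "character"
))

setValidity("TabularSchema", function(object) {
  msgs <- character()
  nms <- object@featureNames
  kinds <- object@featureKinds
  if (length(nms) == 0L) msgs <- c(msgs, "schema has no feature columns")
  if (anyDuplicated(nms)) msgs <- c(msgs, "feature names must be unique")
  if (length(kinds) != length(nms))
    msgs <- c(msgs, "featureKinds length differs from featureNames")
  if (!all(kinds %in% c("categorical", "continuous")))
    msgs <- c(msgs, "kinds must be 'categorical' or 'continuous'")
  if (length(object@target) != 1L || !nzchar(object@target))
    msgs <- c(msgs, "target must be a single non-empty column name")
  if (object@target %in% nms)
    msgs <- c(msgs, "target must not be among the feature columns")
  cat_cols <- nms[kinds == "categorical"]
  if (!setequal(names(object@levels), cat_cols))
    msgs <- c(msgs, "levels must be named by exactly the categorical columns")
  for (nm in cat_cols) {
    lv <- object@levels[[nm]]
    if (!is.character(lv) || length(lv) < 2L || anyDuplicated(lv))
      msgs <- c(msgs, sprintf(
        "categorical column '%s' needs >= 2 distinct levels", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' TabularDataset: row-aligned feature grid with stable row IDs
#'
#' Features are stored as a data.frame in schema column order: categorical
#' cells as integer level codes (1..cardinality, `NA` = missing), continuous
#' cells as doubles (`NA` = missing). Labels, when present, are 0/1 (or `NA`
#' before filtering); encoded/latent-side datasets carry no labels.
#'
#' @slot schema a [TabularSchema-class].
#' @slot rowIds integer row identifiers, unique, aligned to feature rows.
#' @slot features data.frame, columns in schema order.
#' @slot labels integer vector of length 0 (absent) or `nrow(features)`.
#' @export
setClass("TabularDataset", representation(
  schema   = "TabularSchema",
  rowIds   = "integer",
  features = "data.frame",
  labels   = "integer"
))

setValidity("TabularDataset", function(object) {
  msgs <- character()
  n <- nrow(object@features)
  if (length(object@rowIds) != n)
    msgs <- c(msgs, "rowIds length must equal the number of rows")
  if (anyDuplicated(object@rowIds)) msgs <- c(msgs, "rowIds must be unique")
  if (!identical(colnames(object@features), object@schema@featureNames))
    msgs <- c(msgs, "feature column order must match the schema")
  nl <- length(object@labels)
  if (nl != 0L && nl != n)
    msgs <- c(msgs, "labels must be absent or one per row")
  if (nl && !all(object@labels %in% c(0L, 1L, NA_integer_)))
    msgs <- c(msgs, "labels must be 0, 1 or NA")
  kinds <- object@schema@featureKinds
  for (j in seq_along(kinds)) {
    col <- object@features[[j]]
    nm <- object@schema@featureNames[j]
    if (kinds[j] == "categorical") {
      card <- length(object@schema@levels[[nm]])
      if (!is.integer(col))
        msgs <- c(msgs, sprintf("categorical column '%s' must hold integer codes", nm))
      else if (n && !all(is.na(col) | (col >= 1L & col <= card)))
        msgs <- c(msgs, sprintf("codes in '%s' outside 1..%d", nm, card))
    } else if (!is.numeric(col)) {
      msgs <- c(msgs, sprintf("continuous column '%s' must be numeric", nm))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' VerticalPlan: assignment of feature columns to sites
#'
#' @slot assignments list of disjoint character vectors of column names,
#'   one per site, in site order. Validated against a schema at use time
#'   (union must equal the schema's feature set exactly).
#' @export
setClass("VerticalPlan", representation(assignments = "list"))

setValidity("VerticalPlan", function(object) {
  msgs <- character()
  a <- object@assignments
  if (length(a) == 0L) msgs <- c(msgs, "plan must have at least one site")
  if (!all(vapply(a, is.character, logical(1))))
    msgs <- c(msgs, "assignments must be character vectors of column names")
  if (any(lengths(a) == 0L)) msgs <- c(msgs, "no site may be empty")
  all_cols <- unlist(a, use.names = FALSE)
  if (anyDuplicated(all_cols))
    msgs <- c(msgs, "a column may be assigned to at most one site")
  if (length(msgs)) msgs else TRUE
})

#' SitePartition: one site's vertical slice of a dataset
#'
#' Holds the site index and a label-free [TabularDataset-class] restricted to
#' that site's columns; row IDs are identical (content and order) across all
#' partitions produced from one plan.
#'
#' @slot siteIndex 0-based site index.
#' @slot dataset the site's slice (no labels).
#' @export
setClass("SitePartition", representation(
  siteIndex = "integer",
  dataset   = "TabularDataset"
))

setValidity("SitePartition", function(object) {
  msgs <- character()
  if (length(object@siteIndex) != 1L || object@siteIndex < 0L)
    msgs <- c(msgs, "siteIndex must be a single non-negative integer")
  if (length(object@dataset@labels) != 0L)
    msgs <- c(msgs, "site partitions never carry labels")
  if (length(msgs)) msgs else TRUE
})

## ---- autoencoder / latent side ------------------------------------------

#' AutoencoderConfig: training configuration of a per-site autoencoder
#'
#' The middle entry of `hiddenDims` is the code layer; overcompleteness
#' (code width >= the site's post-embedding input width) is enforced when a
#' concrete site is attached at training time, since the input width depends
#' on the site's columns and embedding rule.
#'
#' @slot hiddenDims integer widths, odd length, middle one the code layer.
#' @slot initialLR initial SGD learning rate (default 0.01).
#' @slot lrDecay per-epoch multiplicative decay (default 0.99).
#' @slot weightDecay L2 coefficient applied to weights and embeddings
#'   (default 0.1), the guard against learning the identity map.
#' @slot epochs,batchSize training schedule.
#' @slot embeddingRule name of a registered embedding-width rule.
#' @export
setClass("AutoencoderConfig", representation(
  hiddenDims    = "integer",
  initialLR     = "numeric",
  lrDecay       = "numeric",
  weightDecay   = "numeric",
  epochs        = "integer",
  batchSize     = "integer",
  embeddingRule = "character"
))

setValidity("AutoencoderConfig", function(object) {
  msgs <- character()
  h <- object@hiddenDims
  if (length(h) < 1L || length(h) %% 2L == 0L)
    msgs <- c(msgs, "hiddenDims must have odd length (middle = code layer)")
  if (any(h < 1L)) msgs <- c(msgs, "all layer widths must be positive")
  if (object@initialLR <= 0) msgs <- c(msgs, "initialLR must be positive")
  if (object@lrDecay <= 0 || object@lrDecay > 1)
    msgs <- c(msgs, "lrDecay must be in (0, 1]")
  if (object@weightDecay < 0) msgs <- c(msgs, "weightDecay must be >= 0")
  if (object@epochs < 1L) msgs <- c(msgs, "epochs must be >= 1")
  if (object@batchSize < 1L) msgs <- c(msgs, "batchSize must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' AutoencoderModel: a trained per-site encoder/decoder pair
#'
#' @slot siteIndex site the model belongs to.
#' @slot config the [AutoencoderConfig-class] it was trained under.
#' @slot preproc fitted preprocessing: embedding widths, per-column
#'   imputation medians and standardization parameters (training rows only).
#' @slot params encoder/decoder weight matrices, biases and embedding tables.
#' @slot lossHistory mean training reconstruction loss per epoch.
#' @slot lrHistory learning rate used at each epoch.
#' @export
setClass("AutoencoderModel", representation(
  siteIndex   = "integer",
  config      = "AutoencoderConfig",
  preproc     = "list",
  params      = "list",
  lossHistory = "numeric",
  lrHistory   = "numeric"
))

setValidity("AutoencoderModel", function(object) {
  if (length(object@lossHistory) != length(object@lrHistory))
    "loss and learning-rate histories must have equal length (one per epoch)"
  else TRUE
})

#' LatentDataset: one site's transmitted latent code matrix
#'
#' @slot siteIndex originating site.
#' @slot rowIds row identifiers copied from the encoded partition.
#' @slot codes numeric matrix, `length(rowIds)` x code_dim, all finite.
#' @export
setClass("LatentDataset", representation(
  siteIndex = "integer",
  rowIds    = "integer",
  codes     = "matrix"
))

setValidity("LatentDataset", function(object) {
  msgs <- character()
  if (nrow(object@codes) != length(object@rowIds))
    msgs <- c(msgs, "codes must have one row per rowId")
  if (anyDuplicated(object@rowIds)) msgs <- c(msgs, "rowIds must be unique")
  if (length(object@codes) && !all(is.finite(object@codes)))
    msgs <- c(msgs, "latent codes must be finite")
  if (length(msgs)) msgs else TRUE
})

#' AggregatedLatent: relay output, the column-bound latent matrices
#'
#' @slot rowIds shared row identifiers.
#' @slot codes matrix of width sum(site code dims), sites in ascending
#'   siteIndex blocks.
#' @slot provenance data.frame mapping each column to (site_index, code_index).
#' @export
setClass("AggregatedLatent", representation(
  rowIds     = "integer",
  codes      = "matrix",
  provenance = "data.frame"
))

setValidity("AggregatedLatent", function(object) {
  msgs <- character()
  if (nrow(object@codes) != length(object@rowIds))
    msgs <- c(msgs, "codes must have one row per rowId")
  if (ncol(object@codes) != nrow(object@provenance))
    msgs <- c(msgs, "provenance must describe every column")
  if (!all(c("site_index", "code_index") %in% names(object@provenance)))
    msgs <- c(msgs, "provenance needs site_index and code_index columns")
  s <- object@provenance$site_index
  if (length(s) && any(diff(s) < 0))
    msgs <- c(msgs, "sites must appear in ascending siteIndex blocks")
  if (length(msgs)) msgs else TRUE
})

## ---- classifier side -----------------------------------------------------

#' ClassifierConfig: central tabular neural network settings
#'
#' @slot hiddenDims hidden layer widths (default `c(200, 100)`).
#' @slot lr Adam learning rate.
#' @slot epochs,batchSize training schedule.
#' @slot weightDecay L2 coefficient (default 0).
#' @slot embeddingRule embedding-width rule shared with the autoencoder.
#' @slot threshold decision threshold on the positive-class probability.
#' @export
setClass("ClassifierConfig", representation(
  hiddenDims    = "integer",
  lr            = "numeric",
  epochs        = "integer",
  batchSize     = "integer",
  weightDecay   = "numeric",
  embeddingRule = "character",
  threshold     = "numeric"
))

setValidity("ClassifierConfig", function(object) {
  msgs <- character()
  if (any(object@hiddenDims < 1L)) msgs <- c(msgs, "widths must be positive")
  if (object@threshold <= 0 || object@threshold >= 1)
    msgs <- c(msgs, "threshold must be strictly inside (0, 1)")
  if (object@lr <= 0) msgs <- c(msgs, "lr must be positive")
  if (object@epochs < 1L || object@batchSize < 1L)
    msgs <- c(msgs, "epochs and batchSize must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' ClassifierModel: trained binary classifier over tabular or latent input
#'
#' @slot config the [ClassifierConfig-class] used.
#' @slot inputType `"tabular"` (embeddings + standardized continuous) or
#'   `"matrix"` (all-continuous input such as latent codes; embeddings
#'   bypassed).
#' @slot preproc fitted preprocessing parameters.
#' @slot params weight matrices, biases, embedding tables.
#' @slot lossHistory mean training loss per epoch.
#' @export
setClass("ClassifierModel", representation(
  config      = "ClassifierConfig",
  inputType   = "character",
  preproc     = "list",
  params      = "list",
  lossHistory = "numeric"
))

#' EvalResult: accuracy and AUROC of one evaluated arm
#'
#' @slot accuracy,auroc metrics in `[0, 1]`.
#' @slot nEval number of evaluated rows.
#' @slot scores retained positive-class probabilities, for auditing.
#' @export
setClass("EvalResult", representation(
  accuracy = "numeric",
  auroc    = "numeric",
  nEval    = "integer",
  scores   = "numeric"
))

setValidity("EvalResult", function(object) {
  msgs <- character()
  if (object@accuracy < 0 || object@accuracy > 1)
    msgs <- c(msgs, "accuracy must be within [0, 1]")
  if (object@auroc < 0 || object@auroc > 1)
    msgs <- c(msgs, "auroc must be within [0, 1]")
  if (object@nEval <= 0L) msgs <- c(msgs, "nEval must be positive")
  if (length(msgs)) msgs else TRUE
})

## ---- experiment / reporting ---------------------------------------------

#' BenchmarkReport: the before/after-VFL metric grid
#'
#' One row per (arm, phase) with accuracy and AUROC, where arms are
#' `central` and `site_0 .. site_{k-1}` and phases `before` (raw features)
#' and `after` (latent features); signed relative percent differences per
#' arm; full [EvalResult-class]s and run metadata (plan, configs, seeds,
#' shared test row IDs).
#'
#' @slot grid data.frame: arm, phase, accuracy, auroc.
#' @slot differences data.frame: arm, accuracy_diff, auroc_diff (percent).
#' @slot evals named list of [EvalResult-class] (`"central.before"`, ...).
#' @slot metadata list: plan, configs, seed, test row IDs, timing.
#' @export
setClass("BenchmarkReport", representation(
  grid        = "data.frame",
  differences = "data.frame",
  evals       = "list",
  metadata    = "list"
))

#' PerturbationReport: how far latent codes sit from the raw features
#'
#' @slot featureSpaceChanged TRUE when latent width differs from the site's
#'   original feature count.
#' @slot identityFlag TRUE if any latent column is a (near-)exact linear copy
#'   of a standardized original column (|r| > 0.999).
#' @slot maxAbsCorrelation max |Pearson r| over all (latent, original) pairs.
#' @slot reconstructionR2 held-out ridge-probe R-squared per original
#'   continuous column (linear reconstruction attack).
#' @slot ksStatistics two-sample Kolmogorov-Smirnov statistic between each
#'   standardized original column and its best-correlated latent column.
#' @slot ridgePenalty the ridge penalty used by the probe.
#' @slot details per-column bookkeeping (best-matching latent column etc.).
#' @export
setClass("PerturbationReport", representation(
  featureSpaceChanged = "logical",
  identityFlag        = "logical",
  maxAbsCorrelation   = "numeric",
  reconstructionR2    = "numeric",
  ksStatistics        = "numeric",
  ridgePenalty        = "numeric",
  details             = "list"
))

## ---- synthetic data ------------------------------------------------------

#' SyntheticSpec: generative recipe for a mixed-type labeled cohort
#'
#' Labels are balanced by construction (class counts differ by at most 1).
#' Each continuous column is Normal with a per-class mean shift delta (class
#' 0 at -delta/2, class 1 at +delta/2) and common noise scale; each
#' categorical column draws from class-conditional level probabilities.
#'
#' @slot nRows number of rows.
#' @slot contDeltas named numeric vector: per-class mean shift per continuous
#'   column (0 = pure noise).
#' @slot noiseScale standard deviation of the continuous noise.
#' @slot catSpecs named list; per categorical column a list with `levels`
#'   (character), `p0`, `p1` (class-conditional level probabilities).
#' @slot balance positive-class proportion (default 0.5).
#' @slot missingRate fraction of continuous cells set missing (default 0).
#' @slot seed default generation seed (overridable in [generateTabular()]).
#' @slot preset preset name, or `""` for a hand-built spec.
#' @export
setClass("SyntheticSpec", representation(
  nRows       = "integer",
  contDeltas  = "numeric",
  noiseScale  = "numeric",
  catSpecs    = "list",
  balance     = "numeric",
  missingRate = "numeric",
  seed        = "integer",
  preset      = "character"
))

setValidity("SyntheticSpec", function(object) {
  msgs <- character()
  if (object@nRows < 1L) msgs <- c(msgs, "nRows must be positive")
  if (length(object@contDeltas) + length(object@catSpecs) == 0L)
    msgs <- c(msgs, "spec needs at least one feature column")
  if (length(object@contDeltas) && is.null(names(object@contDeltas)))
    msgs <- c(msgs, "contDeltas must be named by column")
  if (object@noiseScale <= 0) msgs <- c(msgs, "noiseScale must be positive")
  if (object@balance <= 0 || object@balance >= 1)
    msgs <- c(msgs, "balance must be inside (0, 1)")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msgs <- c(msgs, "missingRate must be in [0, 1)")
  for (nm in names(object@catSpecs)) {
    cs <- object@catSpecs[[nm]]
    ok <- is.list(cs) && length(cs$levels) >= 2L &&
      length(cs$p0) == length(cs$levels) &&
      length(cs$p1) == length(cs$levels) &&
      all(cs$p0 >= 0) && all(cs$p1 >= 0) &&
      abs(sum(cs$p0) - 1) < 1e-8 && abs(sum(cs$p1) - 1) < 1e-8
    if (!ok) msgs <- c(msgs, sprintf(
      "catSpecs[['%s']] needs levels plus normalized p0/p1", nm))
  }
  if (length(msgs)) msgs else TRUE
})
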