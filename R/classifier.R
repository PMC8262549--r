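#' Construct a ClassifierConfig
#'
#' The central tabular network: categorical embeddings (shared width rule
#' with the autoencoders), two rectified-linear hidden layers `[200, 100]`
#' by default, a single sigmoid output, trained with Adam. Latent inputs are
#' all-continuous and bypass the embeddings. The same configuration is used
#' for the central, per-site and latent arms of a benchmark, so comparisons
#' differ only in their input.
#'
#' @param hiddenDims hidden layer widths.
#' @param lr Adam learning rate.
#' @param epochs,batchSize training schedule.
#' @param weightDecay L2 coefficient (default 0).
#' @param embeddingRule registered embedding-width rule name.
#' @param threshold decision threshold on the positive-class probability.
#' @return a [ClassifierConfig-class].
#' @export
ClassifierConfig <- function(hiddenDims = c(200L, 100L), lr = 1e-3,
                             epochs = 20L, batchSize = 128L,
                             weightDecay = 0, embeddingRule = "default",
                             threshold = 0.5) {
  new("ClassifierConfig", hiddenDims = as.integer(hiddenDims), lr = lr,
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      weightDecay = weightDecay, embeddingRule = embeddingRule,
      threshold = threshold)
}

setMethod("show", "ClassifierConfig", function(object) {
  cat(sprintf(
    "ClassifierConfig: hidden [%s], Adam lr %g, %d epochs, batch %d, threshold %g\n",
    paste(object@hiddenDims, collapse = ", "), object@lr, object@epochs,
    object@batchSize, object@threshold))
})

.check_labels <- function(y, n) {
  y <- as.integer(y)
  if (length(y) != n) stop("labels must align one-to-one with feature rows")
  if (anyNA(y)) stop("labels contain NA")
  if (length(unique(y)) < 2L)
    stop("degenerate labels: both classes must be present")
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  y
}

#' @rdname trainClassifier
#' @export
setMethod("trainClassifier", "TabularDataset",
          function(x, labels, config = ClassifierConfig(), seed = 0L) {
  # the formal 'labels' shadows the accessor, so reach the slot directly
  if (missing(labels)) labels <- if (length(x@labels)) x@labels else NULL
  if (is.null(labels)) stop("no labels supplied and the dataset has none")
  y <- .check_labels(labels, nRows(x))
  pre <- .fit_preproc(schema(x), features(x), config@embeddingRule)
  inp <- .make_inputs(pre, features(x))
  fit <- .train_clf_core(pre, inp, y, config, seed)
  new("ClassifierModel", config = config, inputType = "tabular",
      preproc = pre, params = fit$params, lossHistory = fit$loss)
})

.train_clf_matrix <- function(mat, labels, config, seed) {
  y <- .check_labels(labels, nrow(mat))
  pre <- .fit_matrix_preproc(mat)
  inp <- .make_matrix_inputs(pre, mat)
  fit <- .train_clf_core(pre, inp, y, config, seed)
  new("ClassifierModel", config = config, inputType = "matrix",
      preproc = pre, params = fit$params, lossHistory = fit$loss)
}

#' @rdname trainClassifier
#' @export
setMethod("trainClassifier", "matrix",
          function(x, labels, config = ClassifierConfig(), seed = 0L)
  .train_clf_matrix(x, labels, config, seed))

#' @rdname trainClassifier
#' @export
setMethod("trainClassifier", "LatentDataset",
          function(x, labels, config = ClassifierConfig(), seed = 0L)
  .train_clf_matrix(latentCodes(x), labels, config, seed))

#' @rdname trainClassifier
#' @export
setMethod("trainClassifier", "AggregatedLatent",
          function(x, labels, config = ClassifierConfig(), seed = 0L)
  .train_clf_matrix(latentCodes(x), labels, config, seed))

#' @describeIn trainClassifier per-epoch mean training loss.
#' @param x a `ClassifierModel`.
#' @export
setMethod("lossHistory", "ClassifierModel", function(x) x@lossHistory)

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf(
    "ClassifierModel (%s input, width %d): hidden [%s], final loss %.4g\n",
    object@inputType, object@preproc$n_input,
    paste(object@config@hiddenDims, collapse = ", "),
    utils::tail(object@lossHistory, 1)))
})

.scores_input <- function(model, x) {
  if (model@inputType == "tabular") {
    if (!is(x, "TabularDataset") && !is(x, "SitePartition"))
      stop("model was trained on tabular input")
    if (is(x, "SitePartition")) x <- x@dataset
    if (!identical(sort(colnames(features(x))),
                   sort(c(model@preproc$cat_cols, model@preproc$cont_cols))))
      stop("feature columns do not match the model's training schema")
    .make_inputs(model@preproc, features(x))
  } else {
    mat <- if (is(x, "LatentDataset") || is(x, "AggregatedLatent"))
      latentCodes(x) else as.matrix(x)
    if (ncol(mat) != model@preproc$n_input)
      stop("input width does not match the model's training width")
    .make_matrix_inputs(model@preproc, mat)
  }
}

#' @rdname predictScores
#' @export
setMethod("predictScores", "ClassifierModel", function(model, x) {
  inp <- .scores_input(model, x)
  .clf_scores_core(model@preproc, model@params, inp)
})
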