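#' @include AllClasses.R
NULL

#' @export
setGeneric("schema", function(x) standardGeneric("schema"))

#' @export
setGeneric("rowIds", function(x) standardGeneric("rowIds"))

#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @export
setGeneric("nRows", function(x) standardGeneric("nRows"))

#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @export
setGeneric("featureKinds", function(x) standardGeneric("featureKinds"))

#' @export
setGeneric("cardinalities", function(x) standardGeneric("cardinalities"))

#' @export
setGeneric("targetName", function(x) standardGeneric("targetName"))

#' @export
setGeneric("siteIndex", function(x) standardGeneric("siteIndex"))

#' @export
setGeneric("latentCodes", function(x) standardGeneric("latentCodes"))

#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))

#' @export
setGeneric("lrHistory", function(x) standardGeneric("lrHistory"))

#' @export
setGeneric("codeDim", function(x) standardGeneric("codeDim"))

#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Encode a site partition into its latent representation
#'
#' @param model a trained [AutoencoderModel-class].
#' @param partition the [SitePartition-class] to encode (columns must match
#'   the model's training schema).
#' @return a [LatentDataset-class], rows aligned to the partition.
#' @export
setGeneric("encodeLatent", function(model, partition)
  standardGeneric("encodeLatent"))

#' Train the central tabular classifier
#'
#' Dispatches on the feature container: a [TabularDataset-class] goes through
#' categorical embeddings + standardized continuous inputs; a
#' [LatentDataset-class], [AggregatedLatent-class] or plain matrix is treated
#' as all-continuous input and bypasses embeddings.
#'
#' @param x feature container.
#' @param labels 0/1 integer vector aligned to the rows of `x` (defaults to
#'   the dataset's own labels for a labeled [TabularDataset-class]).
#' @param config a [ClassifierConfig-class].
#' @param seed integer seed; training is deterministic given it.
#' @return a [ClassifierModel-class].
#' @export
setGeneric("trainClassifier", function(x, labels, config = ClassifierConfig(),
                                       seed = 0L)
  standardGeneric("trainClassifier"))

#' Positive-class probability scores from a trained classifier
#'
#' @param model a [ClassifierModel-class].
#' @param x feature container of the same type the model was trained on.
#' @return numeric vector of probabilities, one per row of `x`.
#' @export
setGeneric("predictScores", function(model, x)
  standardGeneric("predictScores"))

#' @export
setGeneric("benchmarkGrid", function(x) standardGeneric("benchmarkGrid"))

#' @export
setGeneric("benchmarkDifferences", function(x)
  standardGeneric("benchmarkDifferences"))
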