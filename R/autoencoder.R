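#' Construct an AutoencoderConfig
#'
#' Defaults follow the protocol's training regime: 64-128-64 hidden layers
#' (code layer 128), plain SGD from an initial learning rate of 0.01 decayed
#' by 0.99 per epoch, and a weight decay of 0.1 to keep the overcomplete
#' network away from the identity map.
#'
#' @param hiddenDims odd-length integer vector; the middle entry is the code
#'   layer width m.
#' @param initialLR,lrDecay,weightDecay SGD hyperparameters.
#' @param epochs,batchSize training schedule.
#' @param embeddingRule registered embedding-width rule name.
#' @return an [AutoencoderConfig-class].
#' @export
AutoencoderConfig <- function(hiddenDims = c(64L, 128L, 64L),
                              initialLR = 0.01, lrDecay = 0.99,
                              weightDecay = 0.1, epochs = 50L,
                              batchSize = 64L, embeddingRule = "default") {
  new("AutoencoderConfig", hiddenDims = as.integer(hiddenDims),
      initialLR = initialLR, lrDecay = lrDecay, weightDecay = weightDecay,
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      embeddingRule = embeddingRule)
}

#' @describeIn AutoencoderConfig the code layer width m (middle hidden dim).
#' @param x an `AutoencoderConfig`.
#' @export
setMethod("codeDim", "AutoencoderConfig", function(x)
  x@hiddenDims[(length(x@hiddenDims) + 1L) %/% 2L])

setMethod("show", "AutoencoderConfig", function(object) {
  cat(sprintf(
    "AutoencoderConfig: layers [%s] (code %d), SGD lr %g x %g/epoch, wd %g, %d epochs, batch %d\n",
    paste(object@hiddenDims, collapse = "-"), codeDim(object),
    object@initialLR, object@lrDecay, object@weightDecay,
    object@epochs, object@batchSize))
})

#' Train a site's overcomplete autoencoder
#'
#' Fits categorical embeddings jointly with a fully connected
#' encoder/decoder by mini-batch SGD, minimizing the composite
#' reconstruction loss (squared error on standardized continuous columns +
#' softmax cross-entropy over each categorical column's original levels).
#' The learning rate at epoch t (1-based) is `initialLR * lrDecay^(t-1)`.
#' Overcompleteness is enforced: the code width m must be at least the
#' site's post-embedding input width n.
#'
#' Imputation statistics (continuous medians, standardization) are fitted on
#' the supplied rows, which should be training rows only; test rows are
#' later only encoded.
#'
#' @param partition a non-empty [SitePartition-class].
#' @param config an [AutoencoderConfig-class].
#' @param seed base seed; the effective seed is `seed + siteIndex`, so sites
#'   initialized from one base seed differ but runs reproduce exactly.
#' @return an [AutoencoderModel-class] with per-epoch loss and learning-rate
#'   histories.
#' @export
trainAutoencoder <- function(partition, config = AutoencoderConfig(),
                             seed = 0L) {
  stopifnot(is(partition, "SitePartition"))
  if (nRows(partition) == 0L) stop("partition has no rows")
  pre <- .fit_preproc(schema(partition), features(partition),
                      config@embeddingRule)
  m <- codeDim(config)
  if (m < pre$n_input)
    stop(sprintf(
      "overcompleteness violated: code width %d < post-embedding input width %d",
      m, pre$n_input))
  inp <- .make_inputs(pre, features(partition))
  fit <- .train_ae_core(pre, inp, config, seed + siteIndex(partition))
  new("AutoencoderModel", siteIndex = siteIndex(partition), config = config,
      preproc = pre, params = fit$params,
      lossHistory = fit$loss, lrHistory = fit$lr)
}

#' @describeIn trainAutoencoder per-epoch mean training loss.
#' @param x an `AutoencoderModel`.
#' @export
setMethod("lossHistory", "AutoencoderModel", function(x) x@lossHistory)

#' @describeIn trainAutoencoder learning rate used at each epoch.
#' @export
setMethod("lrHistory", "AutoencoderModel", function(x) x@lrHistory)

#' @describeIn trainAutoencoder the model's code width m.
#' @export
setMethod("codeDim", "AutoencoderModel", function(x) codeDim(x@config))

#' @describeIn trainAutoencoder originating site index.
#' @export
setMethod("siteIndex", "AutoencoderModel", function(x) x@siteIndex)

setMethod("show", "AutoencoderModel", function(object) {
  cat(sprintf(
    "AutoencoderModel[site %d]: input width %d -> code %d, %d epochs, final loss %.4g\n",
    object@siteIndex, object@preproc$n_input, codeDim(object),
    length(object@lossHistory), utils::tail(object@lossHistory, 1)))
})

.check_encode_schema <- function(model, partition) {
  pre <- model@preproc
  sch <- schema(partition)
  same <- identical(sort(c(pre$cat_cols, pre$cont_cols)),
                    sort(sch@featureNames)) &&
    all(sch@featureKinds[match(pre$cat_cols, sch@featureNames)] ==
          "categorical") &&
    all(sch@featureKinds[match(pre$cont_cols, sch@featureNames)] ==
          "continuous")
  if (!same)
    stop("encode error: partition columns do not match the model's training schema")
}

#' @rdname encodeLatent
#' @export
setMethod("encodeLatent", signature("AutoencoderModel", "SitePartition"),
          function(model, partition) {
  .check_encode_schema(model, partition)
  inp <- .make_inputs(model@preproc, features(partition))
  codes <- .ae_encode_core(model@preproc, model@params, inp)
  colnames(codes) <- sprintf("code_%03d", seq_len(ncol(codes)) - 1L)
  new("LatentDataset", siteIndex = model@siteIndex,
      rowIds = rowIds(partition), codes = codes)
})

#' Mean composite reconstruction loss of a model on a partition
#'
#' Mean over rows of the summed squared error on standardized continuous
#' columns plus the cross-entropy of each categorical reconstruction head
#' (cells that were missing in the input are excluded from the
#' cross-entropy).
#'
#' @param model a trained [AutoencoderModel-class].
#' @param partition a [SitePartition-class] with the model's columns.
#' @return a single nonnegative finite number.
#' @export
reconstructionLoss <- function(model, partition) {
  .check_encode_schema(model, partition)
  inp <- .make_inputs(model@preproc, features(partition))
  .ae_loss(model@preproc, model@params, inp)
}

## ---- LatentDataset accessors and I/O ------------------------------------

#' Construct a LatentDataset
#'
#' @param siteIndex originating 0-based site index.
#' @param rowIds integer row identifiers.
#' @param codes numeric matrix of latent codes, one row per id.
#' @return a [LatentDataset-class].
#' @export
LatentDataset <- function(siteIndex, rowIds, codes) {
  codes <- as.matrix(codes)
  if (is.null(colnames(codes)))
    colnames(codes) <- sprintf("code_%03d", seq_len(ncol(codes)) - 1L)
  new("LatentDataset", siteIndex = as.integer(siteIndex),
      rowIds = as.integer(rowIds), codes = codes)
}

#' @describeIn LatentDataset the code matrix.
#' @param x a `LatentDataset`.
#' @export
setMethod("latentCodes", "LatentDataset", function(x) x@codes)

#' @describeIn LatentDataset row identifiers.
#' @export
setMethod("rowIds", "LatentDataset", function(x) x@rowIds)

#' @describeIn LatentDataset originating site.
#' @export
setMethod("siteIndex", "LatentDataset", function(x) x@siteIndex)

#' @describeIn LatentDataset number of rows.
#' @export
setMethod("nRows", "LatentDataset", function(x) nrow(x@codes))

#' @describeIn LatentDataset code width.
#' @export
setMethod("codeDim", "LatentDataset", function(x) ncol(x@codes))

setMethod("show", "LatentDataset", function(object) {
  cat(sprintf("LatentDataset[site %d]: %d rows x %d codes\n",
              object@siteIndex, nrow(object@codes), ncol(object@codes)))
})

#' Latent matrix CSV round-trip (row_id first, then code_000, ...)
#'
#' @param latent a [LatentDataset-class].
#' @param path CSV file path.
#' @return `writeLatentCSV`: `path`, invisibly. `readLatentCSV`: a
#'   [LatentDataset-class].
#' @export
writeLatentCSV <- function(latent, path) {
  out <- data.frame(row_id = latent@rowIds, latent@codes,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLatentCSV
#' @param siteIndex site index to attach on read.
#' @export
readLatentCSV <- function(path, siteIndex = 0L) {
  raw <- utils::read.csv(path, check.names = FALSE)
  if (!"row_id" %in% colnames(raw))
    stop("latent CSV must have a 'row_id' first column")
  LatentDataset(siteIndex, raw$row_id,
                as.matrix(raw[, setdiff(colnames(raw), "row_id"),
                              drop = FALSE]))
}

#' Save / load a trained site model as a single archive
#'
#' @param model an [AutoencoderModel-class].
#' @param path archive path (RDS).
#' @return `saveAutoencoder`: `path` invisibly; `loadAutoencoder`: the model.
#' @export
saveAutoencoder <- function(model, path) {
  stopifnot(is(model, "AutoencoderModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveAutoencoder
#' @export
loadAutoencoder <- function(path) {
  model <- readRDS(path)
  if (!is(model, "AutoencoderModel"))
    stop("archive does not contain an AutoencoderModel")
  model
}
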