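#' Construct a TabularDataset
#'
#' @param schema a [TabularSchema-class].
#' @param features data.frame in schema column order; categorical columns as
#'   integer level codes (or factors/characters, which are converted against
#'   the schema's level sets), continuous columns numeric.
#' @param labels optional 0/1 integer vector (NA allowed before filtering);
#'   omit (`NULL`) for label-free datasets.
#' @param rowIds optional integer identifiers; default 0-based row order.
#' @return a [TabularDataset-class].
#' @export
TabularDataset <- function(schema, features, labels = NULL, rowIds = NULL) {
  features <- as.data.frame(features)[, schema@featureNames, drop = FALSE]
  for (j in seq_along(schema@featureNames)) {
    nm <- schema@featureNames[j]
    if (schema@featureKinds[j] == "categorical") {
      col <- features[[nm]]
      if (is.factor(col) || is.character(col)) {
        lv <- schema@levels[[nm]]
        code <- match(as.character(col), lv)
        bad <- !is.na(col) & is.na(code) & as.character(col) != ""
        if (any(bad))
          stop(sprintf("column '%s': value(s) outside declared levels: %s",
                       nm, paste(unique(col[bad])[1:min(3, sum(bad))],
                                 collapse = ", ")))
        features[[nm]] <- as.integer(code)
      } else {
        features[[nm]] <- as.integer(col)
      }
    } else {
      features[[nm]] <- as.numeric(features[[nm]])
    }
  }
  if (is.null(rowIds)) rowIds <- seq_len(nrow(features)) - 1L
  labels <- if (is.null(labels)) integer(0) else as.integer(labels)
  new("TabularDataset", schema = schema, rowIds = as.integer(rowIds),
      features = features, labels = labels)
}

#' @describeIn TabularDataset the dataset's schema.
#' @param x a `TabularDataset`.
#' @export
setMethod("schema", "TabularDataset", function(x) x@schema)

#' @describeIn TabularDataset row identifiers.
#' @export
setMethod("rowIds", "TabularDataset", function(x) x@rowIds)

#' @describeIn TabularDataset the feature data.frame.
#' @export
setMethod("features", "TabularDataset", function(x) x@features)

#' @describeIn TabularDataset number of rows.
#' @export
setMethod("nRows", "TabularDataset", function(x) nrow(x@features))

#' @describeIn TabularDataset binary labels (`NULL` when absent).
#' @param object a `TabularDataset` (for `labels`).
#' @export
setMethod("labels", "TabularDataset", function(object)
  if (length(object@labels)) object@labels else NULL)

setMethod("show", "TabularDataset", function(object) {
  k <- object@schema@featureKinds
  cat(sprintf("TabularDataset: %d rows x %d features (%d cat, %d cont), %s\n",
              nrow(object@features), length(k), sum(k == "categorical"),
              sum(k == "continuous"),
              if (length(object@labels)) {
                tab <- table(factor(object@labels, levels = c(0, 1)))
                sprintf("labels 0/1 = %d/%d%s", tab[[1]], tab[[2]],
                        if (anyNA(object@labels))
                          sprintf(" (+%d NA)", sum(is.na(object@labels)))
                        else "")
              } else "unlabeled"))
})

#' Subset a dataset by row position (internal but reused widely)
#' @noRd
.take_rows <- function(ds, idx) {
  new("TabularDataset", schema = ds@schema,
      rowIds = ds@rowIds[idx],
      features = ds@features[idx, , drop = FALSE],
      labels = if (length(ds@labels)) ds@labels[idx] else integer(0))
}

#' Read a delimited table against a declared schema
#'
#' Row IDs are assigned from file order (0-based). Empty cells and
#' unparseable continuous cells become missing; categorical cells are coded
#' against the schema's level sets, with unseen non-empty values an error.
#'
#' @param path CSV file (RFC-4180 dialect, header row required).
#' @param schema a [TabularSchema-class]; every declared column (features and
#'   target) must be present in the header unless `requireTarget = FALSE`.
#' @param requireTarget whether the target column must be present; when
#'   present, labels are attached (non-0/1 entries become `NA`).
#' @return a [TabularDataset-class].
#' @export
readTabularCSV <- function(path, schema, requireTarget = TRUE) {
  header <- utils::read.csv(path, nrows = 1, check.names = FALSE,
                            colClasses = "character")
  if (anyDuplicated(colnames(header)))
    stop("duplicate column name(s) in header: ",
         paste(unique(colnames(header)[duplicated(colnames(header))]),
               collapse = ", "))
  need <- schema@featureNames
  if (requireTarget) need <- c(need, schema@target)
  miss <- setdiff(need, colnames(header))
  if (length(miss))
    stop("file is missing declared column(s): ", paste(miss, collapse = ", "))
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = c("", "NA"))
  feats <- raw[, schema@featureNames, drop = FALSE]
  for (j in seq_along(schema@featureNames)) {
    nm <- schema@featureNames[j]
    if (schema@featureKinds[j] == "continuous")
      feats[[nm]] <- suppressWarnings(as.numeric(feats[[nm]]))
  }
  labels <- NULL
  if (schema@target %in% colnames(raw)) {
    lab <- suppressWarnings(as.numeric(raw[[schema@target]]))
    lab[!lab %in% c(0, 1)] <- NA
    labels <- as.integer(lab)
  }
  TabularDataset(schema, feats, labels = labels)
}

#' Write a dataset (and its labels) to CSV
#'
#' Categorical codes are written back as their level strings; a `row_id`
#' column and, when present, the target column are included.
#'
#' @param ds a [TabularDataset-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTabularCSV <- function(ds, path) {
  out <- ds@features
  for (nm in names(out))
    if (featureKinds(ds@schema)[[nm]] == "categorical")
      out[[nm]] <- ds@schema@levels[[nm]][out[[nm]]]
  out <- cbind(row_id = ds@rowIds, out)
  if (length(ds@labels)) out[[ds@schema@target]] <- ds@labels
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
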