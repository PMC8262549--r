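#' Construct a TabularSchema
#'
#' @param kinds named character vector mapping each feature column to
#'   `"categorical"` or `"continuous"`, in column order.
#' @param target name of the binary target column.
#' @param levels named list giving the level set (character vector) of each
#'   categorical column.
#' @return a [TabularSchema-class].
#' @examples
#' TabularSchema(
#'   kinds  = c(age = "continuous", job = "categorical"),
#'   target = "income",
#'   levels = list(job = c("clerical", "manual", "service"))
#' )
#' @export
TabularSchema <- function(kinds, target, levels = list()) {
  if (is.null(names(kinds)) || any(!nzchar(names(kinds))))
    stop("'kinds' must be a named vector of column kinds")
  new("TabularSchema",
      featureNames = names(kinds),
      featureKinds = unname(kinds),
      levels       = levels,
      target       = target)
}

#' @describeIn TabularSchema feature column names, in order.
#' @param x a `TabularSchema`.
#' @export
setMethod("featureNames", "TabularSchema", function(x) x@featureNames)

#' @describeIn TabularSchema column kinds, parallel to `featureNames`.
#' @export
setMethod("featureKinds", "TabularSchema", function(x)
  stats::setNames(x@featureKinds, x@featureNames))

#' @describeIn TabularSchema named cardinalities of the categorical columns.
#' @export
setMethod("cardinalities", "TabularSchema", function(x) {
  cat_cols <- x@featureNames[x@featureKinds == "categorical"]
  vapply(x@levels[cat_cols], length, integer(1))
})

#' @describeIn TabularSchema name of the target column.
#' @export
setMethod("targetName", "TabularSchema", function(x) x@target)

setMethod("show", "TabularSchema", function(object) {
  k <- featureKinds(object)
  cat(sprintf(
    "TabularSchema: %d features (%d categorical, %d continuous), target '%s'\n",
    length(k), sum(k == "categorical"), sum(k == "continuous"),
    object@target))
  card <- cardinalities(object)
  if (length(card))
    cat("  cardinalities:", paste(sprintf("%s=%d", names(card), card),
                                  collapse = ", "), "\n")
})

#' Restrict a schema to a subset of its feature columns
#'
#' Used when slicing a dataset vertically; the target name is retained so the
#' orchestrating caller can keep labels, but partitions themselves never do.
#'
#' @param schema a [TabularSchema-class].
#' @param columns character vector of feature columns to keep (schema order
#'   is preserved).
#' @return a [TabularSchema-class] over `columns`.
#' @export
subsetSchema <- function(schema, columns) {
  miss <- setdiff(columns, schema@featureNames)
  if (length(miss))
    stop("unknown feature column(s): ", paste(miss, collapse = ", "))
  keep <- schema@featureNames %in% columns
  kinds <- stats::setNames(schema@featureKinds[keep],
                           schema@featureNames[keep])
  TabularSchema(kinds, schema@target,
                levels = schema@levels[intersect(names(schema@levels),
                                                 names(kinds))])
}

#' Read / write a schema as YAML
#'
#' The on-disk form lists `columns` (name, kind, levels for categoricals) and
#' `target`, so that a dataset CSV plus its schema YAML fully describe a
#' cohort.
#'
#' @param path file path.
#' @return `readSchemaYAML` returns a [TabularSchema-class];
#'   `writeSchemaYAML` returns `path` invisibly.
#' @export
readSchemaYAML <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$columns) || is.null(y$target))
    stop("schema YAML must contain 'columns' and 'target'")
  kinds <- vapply(y$columns, function(col) col$kind, character(1))
  names(kinds) <- vapply(y$columns, function(col) col$name, character(1))
  levels <- list()
  for (col in y$columns)
    if (identical(col$kind, "categorical"))
      levels[[col$name]] <- as.character(unlist(col$levels))
  TabularSchema(kinds, y$target, levels)
}

#' @rdname readSchemaYAML
#' @param schema a [TabularSchema-class] to serialize.
#' @export
writeSchemaYAML <- function(schema, path) {
  cols <- lapply(seq_along(schema@featureNames), function(j) {
    nm <- schema@featureNames[j]
    col <- list(name = nm, kind = schema@featureKinds[j])
    if (col$kind == "categorical") col$levels <- as.list(schema@levels[[nm]])
    col
  })
  yaml::write_yaml(list(columns = cols, target = schema@target), path)
  invisible(path)
}
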