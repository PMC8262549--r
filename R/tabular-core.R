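#' Balance a labeled dataset by random undersampling of the majority class
#'
#' Every minority-class row is retained; majority rows are drawn uniformly
#' without replacement until both classes have exactly the minority count, so
#' the output has `2 * min(class counts)` rows and the prediction chance
#' level is 50%. Relative row order is preserved.
#'
#' @param ds a labeled [TabularDataset-class] (no `NA` labels).
#' @param seed integer seed for the majority draw.
#' @return a balanced [TabularDataset-class].
#' @export
balanceByUndersampling <- function(ds, seed = 0L) {
  y <- labels(ds)
  if (is.null(y)) stop("dataset has no labels")
  if (anyNA(y)) stop("labels contain NA; filter unlabeled rows first")
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  if (n0 == 0L || n1 == 0L)
    stop("degenerate labels: one class is empty, cannot balance")
  n_min <- min(n0, n1)
  minority <- if (n0 <= n1) 0L else 1L
  keep_min <- which(y == minority)
  maj_idx <- which(y != minority)
  keep_maj <- withr::with_seed(seed,
    sort(sample(maj_idx, n_min, replace = FALSE)))
  .take_rows(ds, sort(c(keep_min, keep_maj)))
}

#' Filter rows by nonmissing-feature count and label presence
#'
#' Keeps rows with strictly more than `minNonnull` nonmissing feature cells
#' ("more than" is a strict inequality: a row with exactly `minNonnull`
#' nonmissing cells is dropped). With `requireLabel = TRUE`, rows whose label
#' is missing are then dropped too.
#'
#' @param ds a [TabularDataset-class].
#' @param minNonnull threshold on the nonmissing feature count
#'   (`<= n_features`).
#' @param requireLabel drop rows with `NA` labels after the nonnull rule.
#' @return the filtered [TabularDataset-class], with an `exclusions`
#'   attribute: named integer vector `c(nonnull = ..., unlabeled = ...)` of
#'   rows dropped by each rule.
#' @export
filterRows <- function(ds, minNonnull = 0L, requireLabel = FALSE) {
  p <- length(ds@schema@featureNames)
  if (minNonnull > p)
    stop("minNonnull exceeds the number of feature columns")
  nonnull <- p - rowSums(is.na(ds@features))
  keep1 <- nonnull > minNonnull
  dropped_nonnull <- sum(!keep1)
  dropped_unlabeled <- 0L
  keep <- keep1
  if (requireLabel) {
    if (!length(ds@labels)) stop("requireLabel = TRUE on an unlabeled dataset")
    keep <- keep1 & !is.na(ds@labels)
    dropped_unlabeled <- sum(keep1) - sum(keep)
  }
  out <- .take_rows(ds, which(keep))
  attr(out, "exclusions") <- c(nonnull = as.integer(dropped_nonnull),
                               unlabeled = as.integer(dropped_unlabeled))
  out
}

#' Stratified train/test split
#'
#' Exact partition (disjoint, union = input), stratified by label: each class
#' contributes `round(class_n * testFraction)` rows to the test side, at
#' least one per side. Deterministic given the seed; applied before any site
#' sees data so that every benchmark arm shares the same held-out rows.
#'
#' @param ds a labeled [TabularDataset-class].
#' @param testFraction proportion in (0, 1).
#' @param seed integer seed.
#' @return list with elements `train` and `test` ([TabularDataset-class]s).
#' @export
splitTrainTest <- function(ds, testFraction = 0.2, seed = 0L) {
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must be strictly inside (0, 1)")
  y <- labels(ds)
  if (is.null(y)) stop("dataset has no labels")
  test_idx <- withr::with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(cl) {
      idx <- which(y == cl)
      if (length(idx) < 2L)
        stop(sprintf("class %d has fewer than 2 rows; cannot stratify", cl))
      n_test <- max(1L, min(length(idx) - 1L,
                            round(length(idx) * testFraction)))
      sample(idx, n_test)
    }))
  })
  test_idx <- sort(test_idx)
  list(train = .take_rows(ds, setdiff(seq_len(nRows(ds)), test_idx)),
       test  = .take_rows(ds, test_idx))
}

#' Construct a VerticalPlan
#'
#' @param assignments list of disjoint character vectors of feature column
#'   names, one per site in site order.
#' @return a [VerticalPlan-class].
#' @export
VerticalPlan <- function(assignments) {
  new("VerticalPlan", assignments = lapply(assignments, as.character))
}

setMethod("show", "VerticalPlan", function(object) {
  cat(sprintf("VerticalPlan: %d sites, feature dims [%s]\n",
              length(object@assignments),
              paste(lengths(object@assignments), collapse = ", ")))
})

#' Check a plan against a schema
#'
#' A valid plan's site assignments are non-empty, disjoint, and their union
#' is exactly the schema's feature columns.
#'
#' @param plan a [VerticalPlan-class].
#' @param schema a [TabularSchema-class].
#' @return `TRUE`, invisibly; otherwise an error.
#' @export
validatePlan <- function(plan, schema) {
  cols <- unlist(plan@assignments, use.names = FALSE)
  unknown <- setdiff(cols, schema@featureNames)
  if (length(unknown))
    stop("plan assigns nonexistent column(s): ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(schema@featureNames, cols)
  if (length(missing))
    stop("plan omits feature column(s): ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Vertically split a dataset into per-site partitions
#'
#' Partition i holds exactly the plan's i-th column set over all rows, with
#' no labels: only the orchestrating caller keeps the target. Row IDs are
#' identical in content and order across partitions.
#'
#' @param ds a [TabularDataset-class].
#' @param plan a [VerticalPlan-class], valid against `schema(ds)`.
#' @return list of [SitePartition-class], one per site (0-based indices).
#' @export
verticalSplit <- function(ds, plan) {
  validatePlan(plan, ds@schema)
  lapply(seq_along(plan@assignments), function(i) {
    cols <- plan@assignments[[i]]
    sub <- subsetSchema(ds@schema, cols)
    new("SitePartition",
        siteIndex = i - 1L,
        dataset = new("TabularDataset", schema = sub,
                      rowIds = ds@rowIds,
                      features = ds@features[, sub@featureNames,
                                             drop = FALSE],
                      labels = integer(0)))
  })
}

#' @describeIn SitePartition the 0-based site index.
#' @param x a `SitePartition`.
#' @export
setMethod("siteIndex", "SitePartition", function(x) x@siteIndex)

#' @describeIn SitePartition the site's label-free dataset slice.
#' @export
setMethod("features", "SitePartition", function(x) x@dataset@features)

#' @describeIn SitePartition the slice's schema.
#' @export
setMethod("schema", "SitePartition", function(x) x@dataset@schema)

#' @describeIn SitePartition shared row identifiers.
#' @export
setMethod("rowIds", "SitePartition", function(x) x@dataset@rowIds)

#' @describeIn SitePartition number of rows.
#' @export
setMethod("nRows", "SitePartition", function(x) nrow(x@dataset@features))

setMethod("show", "SitePartition", function(object) {
  cat(sprintf("SitePartition[site %d]: %d rows x %d columns (%s)\n",
              object@siteIndex, nRows(object),
              length(object@dataset@schema@featureNames),
              paste(object@dataset@schema@featureNames, collapse = ", ")))
})
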