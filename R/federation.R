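#' Relay alignment: restrict all sites to their shared rows
#'
#' The simulated third-party relay reorders every site's latent matrix to
#' the sorted intersection of row IDs, so that row i means the same
#' individual at every site. Rows absent from any site are dropped and
#' counted per site.
#'
#' @param latents list of [LatentDataset-class] (at least one).
#' @return list of aligned [LatentDataset-class]s (same order as supplied),
#'   with an attribute `dropped`: integer vector of rows dropped per site.
#' @export
alignLatents <- function(latents) {
  if (!length(latents)) stop("need at least one latent dataset")
  ids <- Reduce(intersect, lapply(latents, rowIds))
  if (!length(ids))
    stop("alignment error: no row IDs shared by all sites")
  ids <- sort(ids)
  out <- lapply(latents, function(l) {
    pos <- match(ids, l@rowIds)
    new("LatentDataset", siteIndex = l@siteIndex, rowIds = ids,
        codes = l@codes[pos, , drop = FALSE])
  })
  attr(out, "dropped") <- vapply(latents, function(l)
    length(l@rowIds) - length(ids), integer(1))
  out
}

#' Relay aggregation: column-bind aligned latent matrices
#'
#' Sites are concatenated in ascending `siteIndex` order; the provenance map
#' records, for every aggregate column, which site and code index it came
#' from, so that slicing the aggregate by provenance reproduces each input
#' matrix exactly.
#'
#' @param latents list of already aligned [LatentDataset-class]s (identical
#'   row IDs in identical order; call [alignLatents()] first otherwise).
#' @return an [AggregatedLatent-class].
#' @export
aggregateLatents <- function(latents) {
  if (!length(latents)) stop("need at least one latent dataset")
  sidx <- vapply(latents, siteIndex, integer(1))
  if (anyDuplicated(sidx)) stop("duplicate site index among inputs")
  ids <- rowIds(latents[[1L]])
  for (l in latents)
    if (!identical(rowIds(l), ids))
      stop("row IDs differ across sites; call alignLatents() first")
  ord <- order(sidx)
  latents <- latents[ord]
  sidx <- sidx[ord]
  mats <- lapply(latents, latentCodes)
  codes <- do.call(cbind, mats)
  prov <- data.frame(
    site_index = rep(sidx, vapply(mats, ncol, integer(1))),
    code_index = unlist(lapply(mats, function(m) seq_len(ncol(m)) - 1L)))
  colnames(codes) <- sprintf("site%d_code_%03d", prov$site_index,
                             prov$code_index)
  new("AggregatedLatent", rowIds = ids, codes = codes, provenance = prov)
}

#' @describeIn aggregateLatents aggregate code matrix.
#' @param x an `AggregatedLatent`.
#' @export
setMethod("latentCodes", "AggregatedLatent", function(x) x@codes)

#' @describeIn aggregateLatents shared row identifiers.
#' @export
setMethod("rowIds", "AggregatedLatent", function(x) x@rowIds)

#' @describeIn aggregateLatents number of rows.
#' @export
setMethod("nRows", "AggregatedLatent", function(x) nrow(x@codes))

#' @describeIn aggregateLatents column provenance map (site_index,
#'   code_index per aggregate column).
#' @export
setMethod("provenance", "AggregatedLatent", function(x) x@provenance)

setMethod("show", "AggregatedLatent", function(object) {
  cat(sprintf("AggregatedLatent: %d rows x %d codes from %d site(s)\n",
              nrow(object@codes), ncol(object@codes),
              length(unique(object@provenance$site_index))))
})

#' Slice one site's matrix back out of an aggregate
#'
#' @param aggregate an [AggregatedLatent-class].
#' @param site site index to extract.
#' @return a [LatentDataset-class] identical to the site's input.
#' @export
sliceAggregate <- function(aggregate, site) {
  keep <- aggregate@provenance$site_index == site
  if (!any(keep)) stop(sprintf("no columns from site %d", site))
  codes <- aggregate@codes[, keep, drop = FALSE]
  colnames(codes) <- sprintf("code_%03d",
                             aggregate@provenance$code_index[keep])
  new("LatentDataset", siteIndex = as.integer(site),
      rowIds = aggregate@rowIds, codes = codes)
}

#' Aggregate CSV + provenance JSON export
#'
#' @param aggregate an [AggregatedLatent-class].
#' @param path CSV output path.
#' @param provenancePath optional JSON path for the provenance map.
#' @return `path`, invisibly.
#' @export
writeAggregateCSV <- function(aggregate, path, provenancePath = NULL) {
  out <- data.frame(row_id = aggregate@rowIds, aggregate@codes,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(provenancePath))
    jsonlite::write_json(aggregate@provenance, provenancePath,
                         dataframe = "columns")
  invisible(path)
}
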