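#' Quantify how far latent codes are perturbed from the raw features
#'
#' Three transparent proxies for the qualitative claim that transmitted
#' codes differ from the original data in both feature space and
#' distribution (the metrics are defined by this package, not mandated by
#' any external protocol):
#' \itemize{
#'   \item \strong{correlation}: max |Pearson r| between any latent column
#'     and any standardized original column (categoricals enter as level
#'     codes); any |r| > 0.999 raises the identity-encoding flag;
#'   \item \strong{linear reconstruction}: a ridge probe fitted from latent
#'     to each original continuous column on half the rows (alternating, so
#'     the split is deterministic) and scored as held-out R-squared on the
#'     other half -- the strength of the obvious linear inversion attack;
#'   \item \strong{distribution divergence}: two-sample Kolmogorov-Smirnov
#'     statistic between each standardized original column and its
#'     best-correlated latent column.
#' }
#'
#' @param original the [SitePartition-class] that was encoded.
#' @param latent the site's [LatentDataset-class]; row IDs must match.
#' @param ridgePenalty ridge penalty of the reconstruction probe (reported,
#'   since attack strength depends on it).
#' @return a [PerturbationReport-class].
#' @export
assessPerturbation <- function(original, latent, ridgePenalty = 1) {
  if (!identical(rowIds(original), rowIds(latent)))
    stop("alignment error: original and latent row IDs differ")
  Z <- latentCodes(latent)
  feats <- features(original)
  sch <- schema(original)
  n <- nrow(Z)

  # standardized original columns (categoricals as numeric level codes)
  orig <- matrix(0, n, ncol(feats),
                 dimnames = list(NULL, colnames(feats)))
  for (j in seq_len(ncol(feats))) {
    x <- as.numeric(feats[[j]])
    med <- stats::median(x, na.rm = TRUE)
    if (!is.finite(med)) med <- 0
    x[is.na(x)] <- med
    sdv <- stats::sd(x)
    if (!is.finite(sdv) || sdv < 1e-12) sdv <- 1
    orig[, j] <- (x - mean(x)) / sdv
  }

  cors <- suppressWarnings(stats::cor(Z, orig))
  cors[!is.finite(cors)] <- 0
  max_abs <- if (length(cors)) max(abs(cors)) else 0
  best <- apply(abs(cors), 2L, which.max)

  ks <- vapply(seq_len(ncol(orig)), function(j)
    unname(suppressWarnings(
      stats::ks.test(orig[, j], Z[, best[j]])$statistic)),
    numeric(1))
  names(ks) <- colnames(orig)

  # held-out ridge probe, continuous columns only; the half-split alternates
  # along the row-ID order so the report is invariant to a common row
  # permutation of both inputs
  cont_cols <- featureNames(sch)[featureKinds(sch) == "continuous"]
  ord <- order(rowIds(latent))
  train_idx <- ord[seq(1L, n, by = 2L)]
  test_idx <- ord[seq(2L, n, by = 2L)]
  r2 <- stats::setNames(rep(NA_real_, length(cont_cols)), cont_cols)
  if (length(cont_cols) && length(train_idx) > 1L && length(test_idx) > 1L) {
    Ztr <- Z[train_idx, , drop = FALSE]
    Zte <- Z[test_idx, , drop = FALSE]
    mu <- colMeans(Ztr)
    Ztr <- sweep(Ztr, 2L, mu)
    Zte <- sweep(Zte, 2L, mu)
    G <- crossprod(Ztr) + diag(ridgePenalty, ncol(Z))
    for (nm in cont_cols) {
      y <- orig[, nm]
      ytr <- y[train_idx] - mean(y[train_idx])
      yte <- y[test_idx] - mean(y[train_idx])
      beta <- solve(G, crossprod(Ztr, ytr))
      resid <- yte - drop(Zte %*% beta)
      tot <- sum((yte - mean(yte))^2)
      if (tot > 0) r2[nm] <- 1 - sum(resid^2) / tot
    }
  }

  new("PerturbationReport",
      featureSpaceChanged = ncol(Z) != ncol(feats),
      identityFlag = max_abs > 0.999,
      maxAbsCorrelation = max_abs,
      reconstructionR2 = r2,
      ksStatistics = ks,
      ridgePenalty = ridgePenalty,
      details = list(best_latent_column = stats::setNames(
        colnames(Z)[best], colnames(orig))))
}

setMethod("show", "PerturbationReport", function(object) {
  cat(sprintf(
    "PerturbationReport: feature space changed: %s; identity flag: %s\n",
    object@featureSpaceChanged, object@identityFlag))
  cat(sprintf("  max |r|(latent, original) = %.4f\n",
              object@maxAbsCorrelation))
  if (length(object@reconstructionR2))
    cat(sprintf("  ridge-probe R^2 (lambda = %g): median %.3f, max %.3f\n",
                object@ridgePenalty,
                stats::median(object@reconstructionR2, na.rm = TRUE),
                max(object@reconstructionR2, na.rm = TRUE)))
  cat(sprintf("  KS divergence: median %.3f\n",
              stats::median(object@ksStatistics)))
})

#' Side-by-side column-distribution heatmaps (diagnostic)
#'
#' Writes two PNG files, one for the original slice and one for its latent
#' codes, each showing rows x columns with every column min-max scaled to
#' [0, 1] so per-feature prevalence patterns are comparable by eye.
#'
#' @param original a [SitePartition-class].
#' @param latent the matching [LatentDataset-class].
#' @param outDir output directory (created if needed).
#' @param maxRows rows displayed (head of the matrix).
#' @return character vector of the two file paths, invisibly.
#' @export
renderHeatmaps <- function(original, latent, outDir, maxRows = 200L) {
  if (!nRows(original) || !ncol(latentCodes(latent)))
    stop("nonempty matrices required")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  scale01 <- function(m) {
    apply(m, 2L, function(x) {
      x[is.na(x)] <- stats::median(x, na.rm = TRUE)
      if (anyNA(x)) x[is.na(x)] <- 0
      rng <- range(x)
      if (diff(rng) < 1e-12) rep(0.5, length(x))
      else (x - rng[1L]) / diff(rng)
    })
  }
  draw <- function(m, path, main) {
    m <- m[seq_len(min(nrow(m), maxRows)), , drop = FALSE]
    grDevices::png(path, width = 640, height = 480)
    on.exit(grDevices::dev.off())
    graphics::image(t(scale01(m)), main = main, xlab = "feature",
                    ylab = "row", axes = FALSE,
                    col = grDevices::hcl.colors(64, "viridis"))
  }
  feats <- features(original)
  num <- vapply(seq_len(ncol(feats)),
                function(j) as.numeric(feats[[j]]), numeric(nrow(feats)))
  num <- matrix(num, nrow = nrow(feats))
  p1 <- file.path(outDir, sprintf("site%d_original.png",
                                  siteIndex(original)))
  p2 <- file.path(outDir, sprintf("site%d_latent.png", siteIndex(latent)))
  draw(num, p1, sprintf("site %d: original features", siteIndex(original)))
  draw(latentCodes(latent), p2,
       sprintf("site %d: latent codes", siteIndex(latent)))
  invisible(c(p1, p2))
}
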