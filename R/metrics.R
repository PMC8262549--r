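#' Classification accuracy at a decision threshold
#'
#' Fraction of rows whose thresholded score equals the label. A score
#' exactly at the threshold is called positive (`>=` convention), which
#' matters for coarse score vectors.
#'
#' @param scores positive-class probabilities.
#' @param labels 0/1 vector of the same length.
#' @param threshold decision threshold (default 0.5).
#' @return a proportion in `[0, 1]`.
#' @export
accuracy <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (!length(scores)) stop("empty input")
  mean(as.integer(scores >= threshold) == as.integer(labels))
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' `P(score_pos > score_neg) + 0.5 * P(tie)` over all positive-negative
#' pairs, computed from midranks, so ties receive half credit and the value
#' is invariant under any strictly increasing transform of the scores.
#'
#' @param scores real-valued scores (higher = more positive).
#' @param labels 0/1 vector; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUROC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a classifier on held-out rows
#'
#' @param model a [ClassifierModel-class].
#' @param x feature container matching the model's input type.
#' @param labels 0/1 vector aligned to the rows of `x`.
#' @return an [EvalResult-class] (accuracy, AUROC, n, retained scores).
#' @export
evaluateClassifier <- function(model, x, labels) {
  scores <- predictScores(model, x)
  labels <- as.integer(labels)
  new("EvalResult",
      accuracy = accuracy(scores, labels, model@config@threshold),
      auroc = auroc(scores, labels),
      nEval = length(labels),
      scores = scores)
}

setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult: accuracy %.4f, AUROC %.4f over %d rows\n",
              object@accuracy, object@auroc, object@nEval))
})
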