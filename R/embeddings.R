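## Registry of embedding-width heuristics. A rule maps a categorical
## cardinality to a dense embedding width >= 1; continuous columns always
## pass through standardized at width 1.

.embedding_rules <- new.env(parent = emptyenv())

#' Register an embedding-width rule
#'
#' @param name rule identifier.
#' @param fn function(cardinality) returning an integer width >= 1.
#' @return `name`, invisibly.
#' @export
registerEmbeddingRule <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .embedding_rules)
  invisible(name)
}

.embedding_width <- function(rule, cardinality) {
  if (!exists(rule, envir = .embedding_rules, inherits = FALSE))
    stop(sprintf("unknown embedding rule '%s'", rule))
  w <- as.integer(get(rule, envir = .embedding_rules)(cardinality))
  if (is.na(w) || w < 1L)
    stop(sprintf("embedding rule '%s' returned an invalid width", rule))
  w
}

# default heuristic: half the cardinality, capped at 50
registerEmbeddingRule("default", function(cardinality)
  min(50L, as.integer(ceiling(cardinality / 2))))

#' Embedding widths and post-embedding input width for a schema
#'
#' Each categorical column gets an integer embedding width from the named
#' rule; continuous columns contribute width 1 (standardized pass-through).
#' The sum is the width `n` of the network input, the quantity the
#' overcompleteness constraint (code width m >= n) is checked against.
#'
#' @param schema a [TabularSchema-class] (typically one site's slice).
#' @param rule name of a registered rule (default `"default"`:
#'   `min(50, ceiling(cardinality / 2))`).
#' @return named integer vector of per-column input widths, with attribute
#'   `n_input` = their sum.
#' @examples
#' sch <- TabularSchema(
#'   kinds = c(a = "categorical", b = "categorical",
#'             x = "continuous", y = "continuous", z = "continuous"),
#'   target = "out",
#'   levels = list(a = paste0("L", 1:9), b = paste0("L", 1:16))
#' )
#' embeddingWidths(sch)   # a=5, b=8, x=y=z=1; n_input = 16
#' @export
embeddingWidths <- function(schema, rule = "default") {
  widths <- integer(length(schema@featureNames))
  names(widths) <- schema@featureNames
  for (j in seq_along(widths)) {
    nm <- schema@featureNames[j]
    widths[j] <- if (schema@featureKinds[j] == "categorical")
      .embedding_width(rule, length(schema@levels[[nm]]))
    else 1L
  }
  attr(widths, "n_input") <- sum(widths)
  widths
}
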