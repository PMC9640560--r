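#' Build a harmonised prediction matrix
#'
#' Assembles long-form raw predictions into a dense variants x tools
#' [PredictionMatrix-class]: assay `"raw"` keeps the original cell values
#' for provenance, assay `"call"` holds canonical calls from the label or
#' score harmonisation pathway (numeric-looking values for score-capable
#' tools go through [harmonizeScore()], everything else through
#' [harmonizeLabel()]). Missing cells become `UNKNOWN`.
#'
#' @param predictions Long-form predictions as returned by
#'   [readPredictionTable()].
#' @param registry Tool registry; only registry tools become columns. Pass a
#'   category subset (e.g. `subset(defaultToolRegistry(), category ==
#'   "SEQUENCE")`) to build a stage-specific matrix.
#' @param vocabulary Label vocabulary, see [defaultVocabulary()].
#' @param rules Numeric score rules, see [defaultScoreRules()].
#' @return A `PredictionMatrix` with one row per distinct variant (input
#'   order preserved) and one column per registry tool present in the data.
#' @examples
#' preds <- readPredictionTable(tpmtExample("seq_calls_candidates"))
#' pm <- buildPredictionMatrix(preds)
#' dim(pm)
#' @export
buildPredictionMatrix <- function(predictions,
                                  registry = defaultToolRegistry(),
                                  vocabulary = defaultVocabulary(),
                                  rules = defaultScoreRules()) {
  .checkRegistry(registry)
  keep <- predictions$tool %in% registry$name
  predictions <- predictions[keep, , drop = FALSE]
  variants <- unique(predictions$variant)
  tools <- if (nrow(predictions)) {
    registry$name[registry$name %in% unique(predictions$tool)]
  } else {
    registry$name
  }
  raw <- matrix(NA_character_, nrow = length(variants), ncol = length(tools),
                dimnames = list(variants, tools))
  if (nrow(predictions)) {
    raw[cbind(match(predictions$variant, variants),
              match(predictions$tool, tools))] <- predictions$raw
  }
  call <- raw
  for (tl in tools) {
    call[, tl] <- .harmonizeCell(tl, raw[, tl], vocabulary, rules)
  }
  pv <- parseSubstitution(variants)
  rs <- rep(NA_character_, length(variants))
  if ("rsid" %in% colnames(predictions)) {
    first <- predictions[!duplicated(predictions$variant), , drop = FALSE]
    rs[match(first$variant, variants)] <- first$rsid
  }
  rowDat <- S4Vectors::DataFrame(rsid = rs, refAA = refAA(pv),
                                 position = variantPosition(pv),
                                 altAA = altAA(pv), row.names = variants)
  colDat <- S4Vectors::DataFrame(
    registry[match(tools, registry$name), , drop = FALSE],
    row.names = tools)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(call = call, raw = raw),
    rowData = rowDat, colData = colDat)
  new("PredictionMatrix", se)
}

#' Assay accessors for PredictionMatrix
#'
#' `callMatrix()` returns the canonical-call assay, `rawMatrix()` the raw
#' provenance assay.
#'
#' @param x A [PredictionMatrix-class].
#' @return A character matrix, variants x tools.
#' @name PredictionMatrix-accessors
NULL

#' @rdname PredictionMatrix-accessors
#' @export
callMatrix <- function(x) SummarizedExperiment::assay(x, "call")

#' @rdname PredictionMatrix-accessors
#' @export
rawMatrix <- function(x) SummarizedExperiment::assay(x, "raw")

#' @describeIn buildPredictionMatrix Read and harmonise a table in one step.
#' @param path Path to a prediction table (see [readPredictionTable()]).
#' @param ... Passed on to [readPredictionTable()].
#' @export
readPredictionMatrix <- function(path, registry = defaultToolRegistry(),
                                 vocabulary = defaultVocabulary(),
                                 rules = defaultScoreRules(), ...) {
  buildPredictionMatrix(readPredictionTable(path, registry, ...),
                        registry, vocabulary, rules)
}

setMethod("show", "PredictionMatrix", function(object) {
  cat("PredictionMatrix:", nrow(object), "variants x", ncol(object),
      "tools\n")
  cat(" categories:",
      paste(names(table(SummarizedExperiment::colData(object)$category)),
            table(SummarizedExperiment::colData(object)$category),
            sep = "=", collapse = " "), "\n")
  calls <- callMatrix(object)
  cat(" calls:", paste(names(table(calls)), table(calls), sep = "=",
                       collapse = " "), "\n")
})
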