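#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## Canonical call vocabulary. Severity is totally ordered over the three
## informative values; UNKNOWN is outside the order and never counts toward
## a vote.
.CALL_LEVELS <- c("NEUTRAL", "DELETERIOUS", "STRONGLY_DELETERIOUS", "UNKNOWN")

#' Canonical call levels
#'
#' The harmonised call vocabulary used throughout the package. The first
#' three values form a severity order (`NEUTRAL < DELETERIOUS <
#' STRONGLY_DELETERIOUS`); `UNKNOWN` marks missing or unmappable raw output
#' and is excluded from every vote.
#'
#' @return Character vector of the four canonical call values.
#' @examples
#' canonicalCalls()
#' @export
canonicalCalls <- function() .CALL_LEVELS

#' Severity rank of canonical calls
#'
#' Maps canonical calls to integer severity: `NEUTRAL` = 1, `DELETERIOUS` =
#' 2, `STRONGLY_DELETERIOUS` = 3, `UNKNOWN` = `NA`.
#'
#' @param call Character vector of canonical calls.
#' @return Integer vector of the same length.
#' @examples
#' callSeverity(c("NEUTRAL", "STRONGLY_DELETERIOUS", "UNKNOWN"))
#' @export
callSeverity <- function(call) {
  sev <- match(call, .CALL_LEVELS[1:3])
  bad <- !is.na(call) & is.na(sev) & call != "UNKNOWN"
  if (any(bad)) {
    stop("not a canonical call: ",
         paste(unique(call[bad]), collapse = ", "))
  }
  sev
}

.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' TPMT sequence length
#'
#' Length of the human thiopurine S-methyltransferase protein (UniProt
#' P51580), used as the default upper bound on residue positions. All
#' positions in this package are 1-based on the full UniProt sequence; the
#' crystal structure 2H11 lacking residues 1-16 is handled as missing
#' structural predictions, never by renumbering.
#'
#' @return Integer, 245.
#' @export
tpmtLength <- function() 245L

#' Vectorised amino-acid substitution
#'
#' An S4 container for amino-acid substitutions in one-letter notation
#' ("W33G"): reference residue, 1-based position on the UniProt sequence,
#' alternative residue, and an optional dbSNP identifier. Reference and
#' alternative residues must differ and be standard amino acids.
#'
#' @slot rsid Character vector of dbSNP identifiers (`NA` when absent).
#' @slot refAA One-letter reference amino acids.
#' @slot position Integer residue positions (1-based).
#' @slot altAA One-letter alternative amino acids.
#' @aliases ProteinVariant
#' @seealso [parseSubstitution()]
#' @exportClass ProteinVariant
setClass("ProteinVariant",
         representation(rsid = "character", refAA = "character",
                        position = "integer", altAA = "character"))

setValidity("ProteinVariant", function(object) {
  n <- length(object@position)
  if (length(object@refAA) != n || length(object@altAA) != n ||
      length(object@rsid) != n)
    return("slots must have equal length")
  if (n == 0L) return(TRUE)
  if (!all(object@refAA %in% .AA1) || !all(object@altAA %in% .AA1))
    return("amino acids must be one-letter codes of the 20 standard residues")
  if (any(object@refAA == object@altAA))
    return("reference and alternative residues must differ")
  if (any(is.na(object@position)) || any(object@position < 1L))
    return("positions must be positive integers")
  TRUE
})

#' Prediction matrix of harmonised calls
#'
#' A `SummarizedExperiment` subclass holding a dense variants x tools grid.
#' Assay `"call"` carries canonical calls (see [canonicalCalls()]); assay
#' `"raw"` keeps the original cell value for provenance. `rowData` holds the
#' parsed variant fields, `colData` the tool registry entries.
#'
#' @aliases PredictionMatrix
#' @seealso [buildPredictionMatrix()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass PredictionMatrix
setClass("PredictionMatrix", contains = "SummarizedExperiment")

setValidity("PredictionMatrix", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("call", "raw") %in% an))
    return("assays 'call' and 'raw' are required")
  calls <- SummarizedExperiment::assay(object, "call")
  if (!all(calls %in% .CALL_LEVELS))
    return("assay 'call' contains non-canonical values")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("name", "category") %in% colnames(cd)))
    return("colData must carry 'name' and 'category'")
  if (!all(cd$category %in% c("SEQUENCE", "STRUCTURE")))
    return("tool categories must be SEQUENCE or STRUCTURE")
  TRUE
})

#' Screening configuration
#'
#' Thresholds and mode for the two-stage consensus screen: a variant must be
#' called deleterious by at least `kSeq` of the `nSeq` sequence-based tools
#' (stage 1) and by at least `kStruct` of the `nStruct` structure-based
#' tools (stage 2). In `"strict"` MuSiC mode the three MuSiC-family tools
#' contribute to the stage-2 vote only on a strong-destabilisation call;
#' in `"lenient"` mode any destabilising call counts. `knownDeleterious`
#' lists variants excluded from novelty by prior experimental evidence.
#'
#' @slot kSeq,nSeq Stage-1 vote threshold and panel size.
#' @slot kStruct,nStruct Stage-2 vote threshold and panel size.
#' @slot musicMode `"strict"` or `"lenient"`.
#' @slot knownDeleterious Character vector of variant labels.
#' @aliases ScreeningConfig
#' @seealso [screeningConfig()], [runScreening()]
#' @exportClass ScreeningConfig
setClass("ScreeningConfig",
         representation(kSeq = "integer", nSeq = "integer",
                        kStruct = "integer", nStruct = "integer",
                        musicMode = "character",
                        knownDeleterious = "character"))

setValidity("ScreeningConfig", function(object) {
  if (object@kSeq < 1L || object@kStruct < 1L)
    return("vote thresholds must be positive")
  if (object@nSeq < 1L || object@nStruct < 1L)
    return("panel sizes must be positive")
  if (!object@musicMode %in% c("strict", "lenient"))
    return("musicMode must be 'strict' or 'lenient'")
  TRUE
})
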