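#' Construct a screening configuration
#'
#' @param kSeq,nSeq Stage-1 vote threshold and expected sequence panel size
#'   (defaults 9 of 12).
#' @param kStruct,nStruct Stage-2 threshold and structure panel size
#'   (defaults 6 of 8).
#' @param musicMode `"strict"` (discovery: MuSiC tools count only on a
#'   strong-destabilisation call) or `"lenient"` (validation: any
#'   destabilising call counts).
#' @param knownDeleterious Variants with prior experimental evidence,
#'   excluded from the novel set (default `"Y240S"`).
#' @return A [ScreeningConfig-class].
#' @examples
#' screeningConfig(musicMode = "lenient")
#' @export
screeningConfig <- function(kSeq = 9L, nSeq = 12L, kStruct = 6L,
                            nStruct = 8L,
                            musicMode = c("strict", "lenient"),
                            knownDeleterious = "Y240S") {
  musicMode <- match.arg(musicMode)
  new("ScreeningConfig", kSeq = as.integer(kSeq), nSeq = as.integer(nSeq),
      kStruct = as.integer(kStruct), nStruct = as.integer(nStruct),
      musicMode = musicMode,
      knownDeleterious = as.character(knownDeleterious))
}

setMethod("show", "ScreeningConfig", function(object) {
  cat("ScreeningConfig: stage 1 >=", object@kSeq, "of", object@nSeq,
      "| stage 2 >=", object@kStruct, "of", object@nStruct,
      "| MuSiC mode:", object@musicMode, "\n")
  if (length(object@knownDeleterious)) {
    cat(" known deleterious:",
        paste(object@knownDeleterious, collapse = ", "), "\n")
  }
})

## Per-row contribution of each tool to a stage vote. UNKNOWN never counts;
## in strict mode, strong-capable tools contribute only at the strong tier.
.voteContributions <- function(calls, colDat, strict) {
  sev <- matrix(callSeverity(calls), nrow = nrow(calls),
                dimnames = dimnames(calls))
  thr <- rep(2L, ncol(calls))
  if (strict) thr[colDat$strongCallSupported] <- 3L
  contrib <- sweep(sev, 2L, thr, ">=")
  contrib[is.na(contrib)] <- FALSE
  contrib
}

.stageVote <- function(pm, config, category, k) {
  colDat <- SummarizedExperiment::colData(pm)
  if (!all(colDat$category == category)) {
    stop("matrix must contain only ", category, " tools for this stage")
  }
  calls <- callMatrix(pm)
  strict <- category == "STRUCTURE" && config@musicMode == "strict"
  contrib <- .voteContributions(calls, colDat, strict)
  vote <- unname(as.integer(rowSums(contrib)))
  evaluable <- unname(rowSums(calls != "UNKNOWN") > 0L)
  S4Vectors::DataFrame(variant = rownames(calls), vote = vote,
                       pass = evaluable & vote >= k, evaluable = evaluable,
                       row.names = rownames(calls))
}

#' Stage-1 sequence-tool vote
#'
#' Counts, per variant, the sequence-based tools calling the substitution
#' deleterious (at severity `DELETERIOUS` or stronger). `UNKNOWN` cells
#' count against the variant: the denominator stays at the configured panel
#' size. A variant with no informative sequence call is flagged
#' non-evaluable and cannot pass.
#'
#' @param pm A [PredictionMatrix-class] restricted to SEQUENCE tools.
#' @param config A [ScreeningConfig-class].
#' @return A `DataFrame` with columns `variant`, `vote`, `pass`,
#'   `evaluable`.
#' @export
stage1Vote <- function(pm, config = screeningConfig()) {
  .stageVote(pm, config, "SEQUENCE", config@kSeq)
}

#' Stage-2 structure-tool vote
#'
#' Counts, per variant, the structure-based tools calling the substitution
#' destabilising. In `"strict"` mode the MuSiC-family tools contribute only
#' on a strong-destabilisation call (the discovery rule); in `"lenient"`
#' mode any destabilising call counts (the validation rule). A variant whose
#' entire structural panel is `UNKNOWN` (e.g. a residue absent from the
#' crystal structure) is flagged non-evaluable and cannot pass.
#'
#' @inheritParams stage1Vote
#' @param pm A [PredictionMatrix-class] restricted to STRUCTURE tools.
#' @return A `DataFrame` with columns `variant`, `vote`, `pass`,
#'   `evaluable`.
#' @export
stage2Vote <- function(pm, config = screeningConfig()) {
  .stageVote(pm, config, "STRUCTURE", config@kStruct)
}

#' Run the two-stage consensus screen
#'
#' Applies the stage-1 sequence vote to every variant, the stage-2
#' structure vote to the stage-1 survivors covered by the structural panel,
#' and the novelty filter to the stage-2 passers. Variants present in the
#' structural matrix but absent from the sequence matrix are warned about
#' and treated as stage-1 failures.
#'
#' @param seqPm [PredictionMatrix-class] of SEQUENCE-tool calls.
#' @param structPm [PredictionMatrix-class] of STRUCTURE-tool calls,
#'   covering at least the stage-1 survivors.
#' @param config A [ScreeningConfig-class].
#' @return A `DataFrame`, ordered by residue position then alternative
#'   amino acid, with columns `variant`, `rsid`, `position`, `seqVote`,
#'   `stage1Pass`, `structVote`, `structEvaluable`, `stage2Pass`, `novel`.
#'   The configuration used is stored in `metadata()$config`.
#' @examples
#' seqPm <- readPredictionMatrix(tpmtExample("seq_calls_candidates"))
#' structPm <- readPredictionMatrix(tpmtExample("struct_calls_candidates"))
#' res <- runScreening(seqPm, structPm)
#' sum(res$stage2Pass); sum(res$novel)
#' @export
runScreening <- function(seqPm, structPm, config = screeningConfig()) {
  s1 <- stage1Vote(seqPm, config)
  s2 <- stage2Vote(structPm, config)
  orphans <- setdiff(s2$variant, s1$variant)
  if (length(orphans)) {
    warning("variant(s) in structural matrix but not in sequence matrix ",
            "(treated as stage-1 failures): ",
            paste(orphans, collapse = ", "), call. = FALSE)
  }
  variants <- s1$variant
  idx2 <- match(variants, s2$variant)
  structVote <- ifelse(is.na(idx2), NA_integer_, s2$vote[idx2])
  structEvaluable <- !is.na(idx2) & s2$evaluable[idx2]
  stage2Pass <- s1$pass & !is.na(idx2) & s2$pass[idx2]
  rowDat <- SummarizedExperiment::rowData(seqPm)
  pv <- parseSubstitution(variants)
  out <- S4Vectors::DataFrame(
    variant = variants,
    rsid = unname(rowDat[variants, "rsid"]),
    position = variantPosition(pv),
    seqVote = s1$vote,
    stage1Pass = s1$pass,
    structVote = structVote,
    structEvaluable = structEvaluable,
    stage2Pass = stage2Pass,
    novel = stage2Pass & !(variants %in% config@knownDeleterious),
    row.names = variants)
  out <- out[order(out$position, altAA(pv)), , drop = FALSE]
  S4Vectors::metadata(out)$config <- config
  out
}
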