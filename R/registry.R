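#' Default predictor registry
#'
#' The 20-tool panel behind the consensus screen: 12 sequence-based
#' predictors (labels: deleterious/neutral-family vocabularies) and 8
#' structure-based stability predictors. The three MuSiC-family tools
#' (PoPMuSiC, HoTMuSiC, SNPMuSiC) support a strong-destabilisation call
#' tier and a numeric score pathway (see [harmonizeScore()]); all other
#' panel tools are label-valued.
#'
#' @return A `data.frame` with columns `name`, `category` (`"SEQUENCE"` or
#'   `"STRUCTURE"`), `outputKind` (`"LABEL"` or `"SCORE"`), and
#'   `strongCallSupported`.
#' @examples
#' table(defaultToolRegistry()$category)
#' @export
defaultToolRegistry <- function() {
  seqTools <- c("PROVEAN", "PANTHER", "PolyPhen-2", "Mutation Assessor",
                "Meta-SNP", "PMut", "PredictSNP1", "SNAP2", "SuSPect",
                "SNPs&GO", "PhD-SNP", "SIFT")
  structTools <- c("CUPSAT", "DUET", "I-Mutant 3.0", "MUpro", "INPS-MD",
                   "PoPMuSiC", "HoTMuSiC", "SNPMuSiC")
  music <- c("PoPMuSiC", "HoTMuSiC", "SNPMuSiC")
  data.frame(
    name = c(seqTools, structTools),
    category = rep(c("SEQUENCE", "STRUCTURE"), c(length(seqTools),
                                                 length(structTools))),
    outputKind = ifelse(c(seqTools, structTools) %in% music,
                        "SCORE", "LABEL"),
    strongCallSupported = c(seqTools, structTools) %in% music,
    stringsAsFactors = FALSE)
}

.checkRegistry <- function(registry) {
  stopifnot(is.data.frame(registry),
            all(c("name", "category", "strongCallSupported") %in%
                  colnames(registry)),
            !anyDuplicated(registry$name),
            all(registry$category %in% c("SEQUENCE", "STRUCTURE")))
  registry
}
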