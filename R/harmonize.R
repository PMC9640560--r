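## Harmonisation: each tool's raw vocabulary or numeric score is mapped onto
## the canonical severity scale. Label matching is case-insensitive after
## whitespace normalisation; anything unmapped becomes UNKNOWN (with a
## warning), never an error, so a stray cell cannot abort a screen.

.normLabel <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Default harmonisation vocabulary
#'
#' Label sets mapping raw predictor vocabularies to canonical calls.
#' Damaging-family labels (including PolyPhen-2 "Possibly damaging" and
#' Mutation Assessor "Medium", which co-occur with consensus-deleterious
#' variants in the bundled tables) map to `DELETERIOUS`; only the MuSiC
#' "Strongly Decrease" tier maps to `STRONGLY_DELETERIOUS`. Single-letter
#' shorthand (`D`, `N`, `SD`) used by compact call tables is included.
#'
#' @return Named list with character vectors `deleterious`, `strong`,
#'   `neutral`.
#' @examples
#' defaultVocabulary()$strong
#' @export
defaultVocabulary <- function() {
  list(
    deleterious = c("deleterious", "disease", "effect", "probably damaging",
                    "possibly damaging", "high", "medium", "destabilising",
                    "destabilizing", "decrease", "damaging", "oncogenic",
                    "driver", "d"),
    strong = c("strongly decrease", "sd", "strongly_deleterious"),
    neutral = c("neutral", "probably benign", "benign", "low", "tolerated",
                "stabilising", "stabilizing", "increase", "n"))
}

#' Harmonise a raw predictor label
#'
#' Maps raw labels to canonical calls using a vocabulary of label sets.
#' Matching is case-insensitive after collapsing internal whitespace.
#' Unmapped labels yield `UNKNOWN` with a warning naming the tool.
#'
#' @param tool Tool name (used in warnings).
#' @param rawLabel Character vector of raw labels.
#' @param vocabulary A list as returned by [defaultVocabulary()].
#' @return Character vector of canonical calls.
#' @examples
#' harmonizeLabel("PROVEAN", "Deleterious")
#' harmonizeLabel("PoPMuSiC", "Strongly Decrease")
#' @export
harmonizeLabel <- function(tool, rawLabel, vocabulary = defaultVocabulary()) {
  lab <- .normLabel(rawLabel)
  out <- rep("UNKNOWN", length(lab))
  out[lab %in% .normLabel(vocabulary$deleterious)] <- "DELETERIOUS"
  out[lab %in% .normLabel(vocabulary$strong)] <- "STRONGLY_DELETERIOUS"
  out[lab %in% .normLabel(vocabulary$neutral)] <- "NEUTRAL"
  unk <- out == "UNKNOWN" & !is.na(rawLabel)
  if (any(unk)) {
    warning("unmapped label(s) for ", tool, ": ",
            paste(unique(rawLabel[unk]), collapse = ", "),
            " -> UNKNOWN", call. = FALSE)
  }
  out[is.na(rawLabel)] <- "UNKNOWN"
  out
}

#' Default numeric score rules
#'
#' Cutoffs for score-valued tools. PoPMuSiC predicts a destabilising
#' substitution at ddG > 0 kcal/mol and a strong destabilisation at >= 4;
#' HoTMuSiC at dTm < 0 degC and <= -10; SNPMuSiC at > 0 and >= 1. The
#' CScape family calls a variant oncogenic/driver (mapped to `DELETERIOUS`)
#' at a p-score strictly above 0.5. Strong cutoffs are inclusive; no
#' additional tolerance is applied, and every cutoff is overridable here.
#'
#' @return Named list of rules with fields `delCutoff`, `strongCutoff`
#'   (or `NA`) and `direction` (`"HIGHER_WORSE"` / `"LOWER_WORSE"`).
#' @export
defaultScoreRules <- function() {
  list(
    "PoPMuSiC" = list(direction = "HIGHER_WORSE", delCutoff = 0,
                      strongCutoff = 4),
    "HoTMuSiC" = list(direction = "LOWER_WORSE", delCutoff = 0,
                      strongCutoff = -10),
    "SNPMuSiC" = list(direction = "HIGHER_WORSE", delCutoff = 0,
                      strongCutoff = 1),
    "CScape" = list(direction = "HIGHER_WORSE", delCutoff = 0.5,
                    strongCutoff = NA_real_),
    "CScape-somatic" = list(direction = "HIGHER_WORSE", delCutoff = 0.5,
                            strongCutoff = NA_real_))
}

#' Harmonise a numeric predictor score
#'
#' Applies a tool's threshold rule to numeric scores. Deleterious calls use
#' a strict inequality against `delCutoff` (a score exactly at a CScape
#' cutoff of 0.5 is `NEUTRAL`); strong calls use an inclusive inequality
#' against `strongCutoff`, so every strong call also satisfies the
#' deleterious condition. Non-finite scores yield `UNKNOWN` with a warning.
#'
#' @param tool Tool name; must have a rule in `rules`.
#' @param score Numeric vector of raw scores.
#' @param rules Named list of rules, see [defaultScoreRules()].
#' @return Character vector of canonical calls.
#' @examples
#' harmonizeScore("HoTMuSiC", -12)    # STRONGLY_DELETERIOUS
#' harmonizeScore("SNPMuSiC", 0.4)    # DELETERIOUS
#' harmonizeScore("CScape", 0.5)      # NEUTRAL (boundary is exclusive)
#' @export
harmonizeScore <- function(tool, score, rules = defaultScoreRules()) {
  rule <- rules[[tool]]
  if (is.null(rule)) stop("no numeric rule registered for tool ", sQuote(tool))
  score <- suppressWarnings(as.numeric(score))
  out <- rep("NEUTRAL", length(score))
  if (rule$direction == "HIGHER_WORSE") {
    out[score > rule$delCutoff] <- "DELETERIOUS"
    if (is.finite(rule$strongCutoff))
      out[score >= rule$strongCutoff] <- "STRONGLY_DELETERIOUS"
  } else {
    out[score < rule$delCutoff] <- "DELETERIOUS"
    if (is.finite(rule$strongCutoff))
      out[score <= rule$strongCutoff] <- "STRONGLY_DELETERIOUS"
  }
  bad <- !is.finite(score)
  if (any(bad)) {
    warning("non-finite score(s) for ", tool, " -> UNKNOWN", call. = FALSE)
    out[bad] <- "UNKNOWN"
  }
  out
}

## One cell: numeric-looking raw values for score-capable tools go through
## the score pathway, everything else through the label pathway.
.harmonizeCell <- function(tool, raw, vocabulary, rules) {
  if (all(is.na(raw))) return(rep("UNKNOWN", length(raw)))
  num <- suppressWarnings(as.numeric(raw))
  if (!is.null(rules[[tool]]) && all(is.finite(num) | is.na(raw))) {
    out <- rep("UNKNOWN", length(raw))
    present <- !is.na(raw)
    out[present] <- harmonizeScore(tool, num[present], rules)
    return(out)
  }
  harmonizeLabel(tool, raw, vocabulary)
}
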