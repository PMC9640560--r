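#' Round half away from zero
#'
#' Decimal rounding with ties going up (76.475 -> 76.48), as used for all
#' reported percentages, rather than R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector.
#' @examples
#' roundHalfUp(c(0.125, 0.135), 2)
#' @export
roundHalfUp <- function(x, digits = 0) {
  mult <- 10^digits
  sign(x) * floor(abs(x) * mult + 0.5) / mult
}

.parseEvidence <- function(evidence) {
  lapply(strsplit(evidence, ";", fixed = TRUE), function(reports) {
    reports <- trimws(reports)
    parts <- strsplit(reports, ":", fixed = TRUE)
    bad <- lengths(parts) != 2L |
      !vapply(parts, `[`, "", 1L) %in% c("VD", "D")
    if (any(bad)) {
      stop("malformed evidence report(s): ",
           paste(reports[bad], collapse = ", "),
           " (expected 'VD:<study>' or 'D:<study>')")
    }
    data.frame(severity = vapply(parts, `[`, "", 1L),
               study = vapply(parts, `[`, "", 2L),
               stringsAsFactors = FALSE)
  })
}

#' Derive evidence-class flags for gold-standard variants
#'
#' Adds per-variant report counts and evidence-class flags to a
#' gold-standard table. `very_dangerous` is set when at least one study
#' reports the variant as very dangerous (VD). `extremely_deleterious`
#' marks variants established as very dangerous by multiple studies, or
#' very dangerous with corroborating additional reports; when the input
#' table carries an explicit `extremely_deleterious` column (as the bundled
#' table does, since study evidence beyond the tabulated reports can inform
#' membership) that curated flag is kept, otherwise the rule above is
#' applied to the tabulated reports.
#'
#' @param gold A `data.frame` from [readGoldStandard()].
#' @return The input with added columns `nVD`, `nD`, `very_dangerous`,
#'   `extremely_deleterious`.
#' @examples
#' gold <- classifyEvidence(readGoldStandard(tpmtExample("gold_standard")))
#' subset(gold, very_dangerous)$variant
#' @export
classifyEvidence <- function(gold) {
  reports <- .parseEvidence(gold$evidence)
  gold$nVD <- vapply(reports, function(r) sum(r$severity == "VD"), 0L)
  gold$nD <- vapply(reports, function(r) sum(r$severity == "D"), 0L)
  gold$very_dangerous <- gold$nVD >= 1L
  if (!"extremely_deleterious" %in% colnames(gold)) {
    gold$extremely_deleterious <-
      gold$nVD >= 2L | (gold$nVD >= 1L & gold$nVD + gold$nD >= 2L)
  }
  gold
}

#' Re-detection rate of gold-standard variants
#'
#' Benchmarks a screening run against experimentally characterised
#' variants: a gold-standard variant is re-detected when it passes both
#' stages of the screen. Variants without structural coverage (all
#' structure-tool cells unavailable) are excluded from the denominator.
#' Screening should be run in `"lenient"` MuSiC mode for validation.
#'
#' @param gold Gold-standard table with evidence flags (see
#'   [classifyEvidence()]; applied automatically if flags are absent).
#' @param screening Screening results from [runScreening()] on the
#'   gold-standard call matrices.
#' @param classes Evidence classes to report: any of `"very_dangerous"`,
#'   `"extremely_deleterious"`, `"all"`.
#' @return A `data.frame` with one row per class: `class`, `nTotal`,
#'   `nExcluded`, `nRedetected`, `percentage` (2 decimals, half-up;
#'   `NA` with a warning when a class is empty after exclusions).
#' @examples
#' gold <- readGoldStandard(tpmtExample("gold_standard"))
#' seqPm <- readPredictionMatrix(tpmtExample("seq_calls_gold"))
#' structPm <- readPredictionMatrix(tpmtExample("struct_calls_gold"))
#' res <- runScreening(seqPm, structPm, screeningConfig(musicMode = "lenient"))
#' redetectionRate(gold, res)
#' @export
redetectionRate <- function(gold, screening,
                            classes = c("very_dangerous",
                                        "extremely_deleterious", "all")) {
  if (!all(c("very_dangerous", "extremely_deleterious") %in%
             colnames(gold))) {
    gold <- classifyEvidence(gold)
  }
  gold <- gold[!duplicated(gold$variant), , drop = FALSE]
  idx <- match(gold$variant, screening$variant)
  if (anyNA(idx)) {
    warning("gold-standard variant(s) absent from screening results: ",
            paste(gold$variant[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  redetected <- !is.na(idx) & screening$stage1Pass[idx] &
    screening$stage2Pass[idx]
  excluded <- !gold$structural_coverage
  rows <- lapply(classes, function(cl) {
    sel <- switch(cl,
                  all = rep(TRUE, nrow(gold)),
                  very_dangerous = gold$very_dangerous,
                  extremely_deleterious = gold$extremely_deleterious,
                  stop("unknown evidence class ", sQuote(cl)))
    nTotal <- sum(sel)
    nExcluded <- sum(sel & excluded)
    denom <- nTotal - nExcluded
    nRedetected <- sum(sel & !excluded & redetected)
    pct <- if (denom > 0L) roundHalfUp(100 * nRedetected / denom, 2)
           else NA_real_
    if (denom == 0L) {
      warning("class ", sQuote(cl), " is empty after exclusions",
              call. = FALSE)
    }
    data.frame(class = cl, nTotal = nTotal, nExcluded = nExcluded,
               nRedetected = nRedetected, percentage = pct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Validate the screen against the bundled gold standard
#'
#' Convenience wrapper: reads the gold-standard call matrices and evidence
#' table, runs the screen in lenient MuSiC mode, and reports re-detection
#' rates per evidence class.
#'
#' @param goldPath,seqPath,structPath Paths to the evidence table and the
#'   sequence/structure call tables (defaults: the bundled tables).
#' @param config Screening configuration; defaults to lenient MuSiC mode.
#' @param classes Evidence classes, see [redetectionRate()].
#' @return A list with elements `screening` (the per-variant results) and
#'   `report` (the per-class re-detection table).
#' @examples
#' validateScreen()$report
#' @export
validateScreen <- function(goldPath = tpmtExample("gold_standard"),
                           seqPath = tpmtExample("seq_calls_gold"),
                           structPath = tpmtExample("struct_calls_gold"),
                           config = screeningConfig(musicMode = "lenient"),
                           classes = c("very_dangerous",
                                       "extremely_deleterious", "all")) {
  gold <- classifyEvidence(readGoldStandard(goldPath))
  seqPm <- readPredictionMatrix(seqPath)
  structPm <- readPredictionMatrix(structPath)
  screening <- runScreening(seqPm, structPm, config)
  list(screening = screening,
       report = redetectionRate(gold, screening, classes))
}
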