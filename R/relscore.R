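#' Amyloid-forming regions of TPMT
#'
#' The ten predicted amyloid-forming residue intervals of the TPMT sequence
#' used by the amyloid-proximity category.
#'
#' @return An [IRanges::IRanges] of inclusive residue intervals.
#' @examples
#' amyloidRegions()
#' @export
amyloidRegions <- function() {
  IRanges::IRanges(
    start = c(64, 86, 100, 127, 147, 154, 170, 178, 207, 231),
    end = c(69, 89, 101, 138, 149, 158, 175, 187, 217, 243))
}

#' Distance to the nearest residue interval
#'
#' Residue distance from a position to the nearest interval in a set:
#' 0 when the position lies inside any interval, otherwise the minimum
#' boundary distance in residues (a position one residue past an interval
#' end has distance 1).
#'
#' @param position Integer vector of residue positions.
#' @param regions An [IRanges::IRanges] (or anything coercible via
#'   `IRanges::IRanges()`) of inclusive intervals; must be non-empty.
#' @return Integer vector of distances.
#' @examples
#' nearestRegionDistance(c(150, 89, 33), amyloidRegions())
#' @export
nearestRegionDistance <- function(position, regions = amyloidRegions()) {
  regions <- methods::as(regions, "IRanges")
  if (length(regions) == 0L) stop("regions must be non-empty")
  st <- IRanges::start(regions)
  en <- IRanges::end(regions)
  if (any(en < st)) stop("invalid interval(s): end before start")
  vapply(as.integer(position), function(p) {
    min(pmax(st - p, p - en, 0L))
  }, integer(1))
}

#' Shift mutant binding energies to a wild-type baseline
#'
#' Converts absolute binding free energies (kJ/mol, e.g. MM-PBSA endpoint
#' estimates) into the raw values of the binding-energy category: the
#' difference `dG_mutant - dG_wildtype`, so that weaker binding (a larger
#' difference) scores as more deleterious, and the values are non-negative
#' whenever every mutant binds no better than the wild type — as the
#' normalise-by-maximum recipe requires.
#'
#' @param mutant Named numeric vector of mutant binding energies.
#' @param wildtype Wild-type reference binding energy (scalar).
#' @return Named numeric vector of energy differences (direction:
#'   higher = worse).
#' @examples
#' bindingEnergyScore(c(W33G = 15.81, L182P = -102.24), -138.77)
#' @export
bindingEnergyScore <- function(mutant, wildtype) {
  if (missing(wildtype) || length(wildtype) != 1L || !is.finite(wildtype)) {
    stop("a finite wild-type reference binding energy is required")
  }
  mutant - wildtype
}

#' Cumulative oncogenic score
#'
#' Sums the CScape and CScape-somatic coding p-scores per mutation (each in
#' \[0, 1\], values above 0.5 meaning oncogenic/driver), giving the raw
#' value of the oncogenic category.
#'
#' @param scores A `data.frame` with columns `variant`, `cscape_score`,
#'   `cscape_somatic_score` (as read from
#'   `tpmtExample("oncogenic_scores")`).
#' @return Named numeric vector of cumulative scores.
#' @examples
#' df <- readReport(tpmtExample("oncogenic_scores"))
#' cumulativeOncogenicScore(df)
#' @export
cumulativeOncogenicScore <- function(scores) {
  stats::setNames(as.numeric(scores$cscape_score) +
                    as.numeric(scores$cscape_somatic_score),
                  scores$variant)
}

#' Per-category relative deleteriousness scores
#'
#' Normalises each category's raw values to the worst mutation. For
#' `HIGHER_WORSE` categories the relative score is `100 * value /
#' max(value)` (the maximal mutation scores exactly 100; ties all score
#' 100). For `PROXIMITY` categories (distances, where closer is worse) the
#' normalised value is inverted: `100 - 100 * value / max(value)`. All
#' scores are clipped to \[0, 100\].
#'
#' @param features A `data.frame` with columns `mutation`, `category`,
#'   `value`, `direction` (`"HIGHER_WORSE"` or `"PROXIMITY"`), e.g. from
#'   `tpmtExample("relative_score_features")`. A category missing a value
#'   for any mutation is skipped entirely with a message.
#' @return Numeric matrix, mutations x categories, of relative scores.
#' @examples
#' feats <- readReport(tpmtExample("relative_score_features"))
#' round(relativeCategoryScores(feats), 2)
#' @export
relativeCategoryScores <- function(features) {
  stopifnot(all(c("mutation", "category", "value", "direction") %in%
                  colnames(features)))
  features$value <- as.numeric(features$value)
  muts <- unique(features$mutation)
  cats <- unique(features$category)
  keep <- vapply(cats, function(cat) {
    sub <- features[features$category == cat, , drop = FALSE]
    ok <- all(muts %in% sub$mutation) && !anyNA(sub$value)
    if (!ok) message("skipping category ", cat, ": incomplete values")
    ok
  }, logical(1))
  cats <- cats[keep]
  out <- matrix(NA_real_, length(muts), length(cats),
                dimnames = list(muts, cats))
  for (cat in cats) {
    sub <- features[features$category == cat, , drop = FALSE]
    val <- sub$value[match(muts, sub$mutation)]
    dir <- unique(sub$direction)
    if (length(dir) != 1L) {
      stop("category ", cat, " mixes directions")
    }
    if (dir == "HIGHER_WORSE") {
      if (any(val < 0)) {
        stop("negative values in HIGHER_WORSE category ", cat,
             "; re-baseline the raw values first ",
             "(see bindingEnergyScore())")
      }
      mx <- max(val)
      if (mx == 0) {
        warning("all values zero in category ", cat, call. = FALSE)
        rel <- rep(0, length(val))
      } else {
        rel <- 100 * val / mx
      }
    } else if (dir == "PROXIMITY") {
      if (any(val < 0)) stop("negative distance in category ", cat)
      mx <- max(val)
      rel <- if (mx == 0) rep(100, length(val))
             else 100 - 100 * val / mx
    } else {
      stop("unknown direction ", sQuote(dir), " in category ", cat)
    }
    out[, cat] <- pmin(100, pmax(0, rel))
  }
  out
}

#' Aggregate relative scores into a Total
#'
#' Sums each mutation's relative category scores and renormalises the sums
#' to the worst mutation, appending a `Total` column in \[0, 100\] (exactly
#' one mutation — or all tied maxima — scores 100).
#'
#' @param scores Matrix from [relativeCategoryScores()].
#' @return The matrix with an appended `Total` column.
#' @export
totalScore <- function(scores) {
  stopifnot(is.matrix(scores), ncol(scores) >= 1L)
  raw <- rowSums(scores)
  total <- if (max(raw) == 0) rep(0, length(raw)) else 100 * raw / max(raw)
  cbind(scores, Total = total)
}

#' Full relative-score matrix
#'
#' One-step wrapper: per-category relative scores plus the `Total`
#' aggregate, ordered by decreasing Total.
#'
#' @inheritParams relativeCategoryScores
#' @return Numeric matrix, mutations x (categories + Total).
#' @examples
#' feats <- readReport(tpmtExample("relative_score_features"))
#' round(relativeScoreMatrix(feats), 1)
#' @export
relativeScoreMatrix <- function(features) {
  m <- totalScore(relativeCategoryScores(features))
  m[order(-m[, "Total"]), , drop = FALSE]
}
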