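#' Functional-class percentage summary
#'
#' Converts per-class variant counts into percentages of the total,
#' rounded half-up. The class vocabulary is open: any class strings are
#' accepted (the bundled `snp_class_counts` table uses dbSNP-style classes:
#' intron, 3'UTR, 5'UTR, missense, synonymous, frameshift, nonsense,
#' other).
#'
#' @param counts Named numeric vector of non-negative counts, or a
#'   `data.frame` with columns `class` and `count`.
#' @param decimals Decimal places for the percentages (default 2).
#' @return Named numeric vector of percentages, in the input class order.
#' @examples
#' counts <- readReport(tpmtExample("snp_class_counts"))
#' classPercentages(counts)
#' @export
classPercentages <- function(counts, decimals = 2) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(as.numeric(counts$count), counts$class)
  }
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be non-negative numbers")
  }
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive")
  roundHalfUp(100 * counts / total, decimals)
}
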