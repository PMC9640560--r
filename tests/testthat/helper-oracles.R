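# Independent oracles and in-code fixture builders.

# Brute-force vote count: loop over tools, no vectorised severity algebra.
oracleVote <- function(calls, strongTools = character(), strict = FALSE) {
  vote <- 0L
  for (tl in names(calls)) {
    cl <- calls[[tl]]
    if (cl == "UNKNOWN") next
    needed <- if (strict && tl %in% strongTools) {
      cl == "STRONGLY_DELETERIOUS"
    } else {
      cl %in% c("DELETERIOUS", "STRONGLY_DELETERIOUS")
    }
    if (needed) vote <- vote + 1L
  }
  vote
}

# Exhaustive Poisson-binomial tail: enumerate all 2^n outcomes.
oracleTail <- function(p, k) {
  n <- length(p)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  probs <- apply(grid, 1L, function(x) prod(ifelse(x == 1, p, 1 - p)))
  sum(probs[rowSums(grid) >= k])
}

# Long-form prediction table from a call matrix of raw labels.
longForm <- function(mat) {
  data.frame(rsid = NA_character_,
             variant = rep(rownames(mat), ncol(mat)),
             tool = rep(colnames(mat), each = nrow(mat)),
             raw = as.vector(mat),
             missing = is.na(as.vector(mat)),
             stringsAsFactors = FALSE)
}

# Random raw-label matrix for one tool category; severity-coded labels so
# tests can upgrade cells deterministically.
severityLabel <- c("Neutral", "Decrease", "Strongly Decrease")

randomCallMatrix <- function(nVariants, category, pStrong = 0.2,
                             pDel = 0.4) {
  registry <- defaultToolRegistry()
  tools <- registry$name[registry$category == category]
  positions <- sample(setdiff(1:245, 1), nVariants)
  variants <- paste0("L", positions, "P")
  sev <- matrix(sample(1:3, nVariants * length(tools), replace = TRUE,
                       prob = c(1 - pDel - pStrong, pDel, pStrong)),
                nrow = nVariants,
                dimnames = list(variants, tools))
  raw <- matrix(severityLabel[sev], nrow = nVariants,
                dimnames = dimnames(sev))
  raw
}

matrixFromRaw <- function(raw, category) {
  registry <- defaultToolRegistry()
  sub <- registry[registry$category == category, , drop = FALSE]
  suppressMessages(buildPredictionMatrix(longForm(raw), sub))
}

candidateSeqMatrix <- function() {
  suppressMessages(readPredictionMatrix(tpmtExample("seq_calls_candidates")))
}

candidateStructMatrix <- function() {
  suppressMessages(
    readPredictionMatrix(tpmtExample("struct_calls_candidates")))
}

goldSeqMatrix <- function() {
  suppressMessages(readPredictionMatrix(tpmtExample("seq_calls_gold")))
}

goldStructMatrix <- function() {
  suppressMessages(readPredictionMatrix(tpmtExample("struct_calls_gold")))
}
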