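## Tabular IO. All tables are plain TSV (default) or CSV with a header row.
## Cells equal to a configurable NA token become missing predictions.
## Typographic minus signs in transcribed numbers are normalised at read
## time so that locale or copy-paste artefacts never corrupt scores.

.normText <- function(x) {
  x <- gsub("−", "-", x)   # unicode minus
  x <- gsub("×", "x", x)   # multiplication sign
  trimws(x)
}

.readDelim <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(), quote = "\"",
                          stringsAsFactors = FALSE)
  df[] <- lapply(df, .normText)
  df
}

#' Path to a bundled example table
#'
#' The package ships curated TPMT call tables and feature tables used by the
#' examples, tests and the validation workflow: `seq_calls_candidates` /
#' `struct_calls_candidates` (consensus-candidate predictor calls),
#' `seq_calls_gold` / `struct_calls_gold` / `gold_standard` (experimentally
#' characterised variants with study-level evidence), `oncogenic_scores`,
#' `binding_energy`, `conservation_components`, `relative_score_features`
#' and `snp_class_counts`. Feature entries not derivable from printed values
#' are flagged `provenance = "synthetic"` inside the files.
#'
#' @param name Basename of the table (without extension). With no argument,
#'   lists the available tables.
#' @return A file path, or a character vector of table names.
#' @examples
#' tpmtExample()
#' tpmtExample("snp_class_counts")
#' @export
tpmtExample <- function(name) {
  dir <- system.file("extdata", package = "tpmtscreen")
  if (missing(name)) {
    return(sub("\\.tsv$", "", list.files(dir, pattern = "\\.tsv$")))
  }
  path <- file.path(dir, paste0(name, ".tsv"))
  if (!file.exists(path)) {
    stop("no bundled table ", sQuote(name), "; see tpmtExample()")
  }
  path
}

#' Read a per-variant, per-tool prediction table
#'
#' Reads a delimited table of raw predictor output in either wide form (one
#' row per variant, one column per tool) or long form (columns `variant`,
#' `tool`, `raw`), auto-detected from the header. Cells equal to an NA token
#' become missing predictions. Wide-form columns that do not match a
#' registry tool are reported, skipped, and returned in the `"auxiliary"`
#' attribute (sub-predictor columns such as mCSM/SDM components travel
#' there).
#'
#' @param path Path to a TSV/CSV file.
#' @param registry Tool registry, see [defaultToolRegistry()].
#' @param naTokens Cell values treated as missing.
#' @param sep Field separator; defaults by file extension.
#' @return A long-form `data.frame` with columns `rsid`, `variant`, `tool`,
#'   `raw`, `missing`, one row per (variant, tool) pair.
#' @examples
#' head(readPredictionTable(tpmtExample("seq_calls_candidates")))
#' @export
readPredictionTable <- function(path, registry = defaultToolRegistry(),
                                naTokens = c("NA", "", "-"), sep = NULL) {
  .checkRegistry(registry)
  df <- .readDelim(path, sep)
  lowered <- tolower(colnames(df))
  long <- if (all(c("variant", "tool") %in% lowered) &&
              any(c("raw", "value") %in% lowered)) {
    colnames(df) <- lowered
    rawCol <- intersect(c("raw", "value"), lowered)[1L]
    data.frame(rsid = if ("rsid" %in% lowered) df$rsid
               else rep(NA_character_, nrow(df)),
               variant = df$variant, tool = df$tool, raw = df[[rawCol]],
               stringsAsFactors = FALSE)
  } else {
    varCol <- which(lowered %in% c("variant", "snp", "mutation"))[1L]
    if (is.na(varCol)) stop("no variant column found in ", path)
    rsCol <- which(lowered == "rsid")[1L]
    idCols <- c(varCol, if (!is.na(rsCol)) rsCol)
    toolCols <- setdiff(seq_along(df), idCols)
    known <- colnames(df)[toolCols] %in% registry$name
    if (any(!known)) {
      message("skipping non-registry column(s): ",
              paste(colnames(df)[toolCols][!known], collapse = ", "))
    }
    aux <- df[, c(varCol, toolCols[!known]), drop = FALSE]
    keep <- toolCols[known]
    out <- data.frame(
      rsid = if (!is.na(rsCol)) rep(df[[rsCol]], length(keep))
             else rep(NA_character_, nrow(df) * length(keep)),
      variant = rep(df[[varCol]], length(keep)),
      tool = rep(colnames(df)[keep], each = nrow(df)),
      raw = unlist(df[keep], use.names = FALSE),
      stringsAsFactors = FALSE)
    attr(out, "auxiliary") <- aux
    out
  }
  long$missing <- long$raw %in% naTokens
  long$raw[long$missing] <- NA_character_
  long$rsid[long$rsid %in% naTokens] <- NA_character_
  dup <- duplicated(long[c("variant", "tool")])
  if (any(dup)) {
    pairs <- unique(long[dup, c("variant", "tool"), drop = FALSE])
    conflicting <- vapply(seq_len(nrow(pairs)), function(i) {
      vals <- long$raw[long$variant == pairs$variant[i] &
                         long$tool == pairs$tool[i]]
      length(unique(vals)) > 1L
    }, logical(1))
    if (any(conflicting)) {
      stop("conflicting duplicate predictions for: ",
           paste(pairs$variant[conflicting], pairs$tool[conflicting],
                 sep = "/", collapse = ", "))
    }
    long <- long[!dup, , drop = FALSE]
  }
  rownames(long) <- NULL
  long
}

#' Read a gold-standard evidence table
#'
#' Reads a table of experimentally characterised variants with study-level
#' evidence. The `evidence` column encodes one `severity:study` pair per
#' report, separated by semicolons, with severities `VD` (very dangerous)
#' or `D` (dangerous), e.g. `"VD:77;D:84"`. Optional columns
#' `structural_coverage` and `extremely_deleterious` are parsed as
#' booleans.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator; defaults by file extension.
#' @return A `data.frame`, one row per variant, with `evidence` kept as the
#'   encoded string (see [classifyEvidence()] for flag derivation).
#' @examples
#' gold <- readGoldStandard(tpmtExample("gold_standard"))
#' head(gold)
#' @export
readGoldStandard <- function(path, sep = NULL) {
  df <- .readDelim(path, sep)
  need <- c("variant", "evidence")
  if (!all(need %in% colnames(df))) {
    stop("gold-standard table must have columns: ",
         paste(need, collapse = ", "))
  }
  if (any(df$evidence %in% c("", "NA"))) {
    stop("every gold-standard entry needs at least one evidence report")
  }
  for (col in c("structural_coverage", "extremely_deleterious")) {
    if (col %in% colnames(df)) df[[col]] <- toupper(df[[col]]) == "TRUE"
  }
  if (!"structural_coverage" %in% colnames(df)) {
    df$structural_coverage <- TRUE
  }
  df$rsid[df$rsid %in% c("NA", "")] <- NA_character_
  df
}

#' Write a result table with a machine-readable summary
#'
#' Writes any pipeline result (screening results, validation report,
#' relative score matrix, distribution summary) as a delimited table with a
#' deterministic column order, plus a JSON sidecar (`<path>.json`)
#' summarising the content.
#'
#' @param x A `data.frame`, `DataFrame`, or matrix result.
#' @param path Output file path.
#' @param format `"tsv"` or `"csv"`.
#' @param digits Optional number of decimals applied to numeric columns on
#'   output; `NA` (default) writes full precision. Percentages computed by
#'   the pipeline are already rounded to 2 decimals.
#' @return Invisibly, the path written.
#' @export
writeReport <- function(x, path, format = c("tsv", "csv"), digits = NA) {
  format <- match.arg(format)
  if (is.matrix(x)) {
    x <- data.frame(mutation = rownames(x), as.data.frame(x),
                    check.names = FALSE)
  }
  x <- as.data.frame(x)
  if (!is.na(digits)) {
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], round, digits = digits)
  }
  utils::write.table(x, path, sep = if (format == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE)
  summary <- list(columns = colnames(x), rows = nrow(x))
  numCols <- colnames(x)[vapply(x, is.numeric, logical(1))]
  if (length(numCols)) {
    summary$totals <- as.list(colSums(x[numCols], na.rm = TRUE))
  }
  jsonlite::write_json(summary, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read back a written report table
#'
#' Companion to [writeReport()]: reads a delimited result table with type
#' inference, so that `readReport(writeReport(x, p), p)` reproduces `x` for
#' the package's result types.
#'
#' @param path Path written by [writeReport()].
#' @param sep Field separator; defaults by file extension.
#' @return A `data.frame`.
#' @export
readReport <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
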