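#' Parse amino-acid substitutions
#'
#' Parses substitution strings of the form `<ref><position><alt>` (one-letter
#' amino-acid codes, decimal position, e.g. `"W33G"`) into a
#' [ProteinVariant-class] object. Positions are 1-based on the full UniProt
#' P51580 sequence.
#'
#' @param text Character vector of substitution strings.
#' @param rsid Optional character vector of dbSNP identifiers, recycled or
#'   matched to `text`.
#' @param maxPosition Upper bound on the residue position (defaults to the
#'   245-residue TPMT sequence length).
#' @return A `ProteinVariant` of the same length as `text`.
#' @examples
#' parseSubstitution(c("W33G", "L182P"))
#' @export
parseSubstitution <- function(text, rsid = NA_character_,
                              maxPosition = tpmtLength()) {
  text <- trimws(as.character(text))
  m <- regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", text)
  parts <- regmatches(text, m)
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    stop("malformed substitution string: ",
         paste(sQuote(text[bad]), collapse = ", "))
  }
  ref <- toupper(vapply(parts, `[`, "", 2L))
  pos <- as.integer(vapply(parts, `[`, "", 3L))
  alt <- toupper(vapply(parts, `[`, "", 4L))
  if (any(off <- !ref %in% .AA1 | !alt %in% .AA1)) {
    stop("not a standard amino acid in: ",
         paste(sQuote(text[off]), collapse = ", "))
  }
  if (any(same <- ref == alt)) {
    stop("reference equals alternative residue in: ",
         paste(sQuote(text[same]), collapse = ", "))
  }
  if (any(out <- pos < 1L | pos > maxPosition)) {
    stop("position outside [1, ", maxPosition, "] in: ",
         paste(sQuote(text[out]), collapse = ", "))
  }
  new("ProteinVariant", rsid = rep_len(as.character(rsid), length(text)),
      refAA = ref, position = pos, altAA = alt)
}

#' @describeIn parseSubstitution Render variants back to `"W33G"` notation.
#' @param x A `ProteinVariant`.
#' @export
variantLabel <- function(x) {
  stopifnot(is(x, "ProteinVariant"))
  paste0(x@refAA, x@position, x@altAA)
}

#' Accessors for ProteinVariant
#'
#' `refAA()`, `altAA()`, `variantPosition()` and `rsid()` extract the
#' corresponding fields.
#'
#' @param x A [ProteinVariant-class].
#' @return A vector of the field values.
#' @name ProteinVariant-accessors
#' @examples
#' v <- parseSubstitution("W33G", rsid = "rs72552741")
#' variantPosition(v)
NULL

#' @rdname ProteinVariant-accessors
#' @export
refAA <- function(x) x@refAA

#' @rdname ProteinVariant-accessors
#' @export
altAA <- function(x) x@altAA

#' @rdname ProteinVariant-accessors
#' @export
variantPosition <- function(x) x@position

#' @rdname ProteinVariant-accessors
#' @export
rsid <- function(x) x@rsid

#' @export
setMethod("length", "ProteinVariant", function(x) length(x@position))

#' @export
setMethod("as.character", "ProteinVariant", function(x) variantLabel(x))

#' @export
setMethod("[", "ProteinVariant", function(x, i, j, ..., drop = TRUE) {
  new("ProteinVariant", rsid = x@rsid[i], refAA = x@refAA[i],
      position = x@position[i], altAA = x@altAA[i])
})

setMethod("show", "ProteinVariant", function(object) {
  n <- length(object)
  cat("ProteinVariant of length", n, "\n")
  if (n > 0L) {
    shown <- utils::head(variantLabel(object), 10L)
    cat(" ", paste(shown, collapse = " "),
        if (n > 10L) "..." else "", "\n")
  }
})
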