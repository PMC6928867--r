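#' Cross two tissue genomic signatures
#'
#' Splits two gene signatures into the genes specific to each and the genes
#' they share: `aSpecific = a \ b`, `bSpecific = b \ a`,
#' `shared = a n b`. The three sets are pairwise disjoint and their union
#' equals the union of the inputs. This is the first step of the pipeline:
#' comparing a spinal-cord signature against a brain signature isolates the
#' genes that make the cord transcriptionally distinctive.
#'
#' @param a,b Character vectors of gene symbols (normalized on entry); both
#'   must be non-empty.
#' @param aName,bName Labels carried along in the result.
#' @return A list of class `"SignatureCross"` with elements `aSpecific`,
#'   `bSpecific`, `shared`, `aName`, `bName` (sets are sorted character
#'   vectors).
#' @examples
#' crossSignatures(c("G1", "G2", "G3"), c("G2"), "SC", "Brain")
#' @export
crossSignatures <- function(a, b, aName = "a", bName = "b") {
  if (length(a) == 0L || length(b) == 0L)
    stop("both signatures must be non-empty", call. = FALSE)
  a <- unique(normalizeSymbols(a))
  b <- unique(normalizeSymbols(b))
  structure(
    list(aSpecific = sort(setdiff(a, b)),
         bSpecific = sort(setdiff(b, a)),
         shared    = sort(intersect(a, b)),
         aName = aName, bName = bName),
    class = "SignatureCross")
}

#' @export
print.SignatureCross <- function(x, ...) {
  cat("SignatureCross:", x$aName, "vs", x$bName, "\n")
  cat(sprintf("  %s-specific: %d gene(s)\n", x$aName, length(x$aSpecific)))
  cat(sprintf("  %s-specific: %d gene(s)\n", x$bName, length(x$bSpecific)))
  cat(sprintf("  shared:      %d gene(s)\n", length(x$shared)))
  invisible(x)
}

#' Intersect a gene set with one library term
#'
#' Restricts a gene set to the members of one annotation term, e.g. keeping
#' only the homeobox-family genes of a tissue-specific signature.
#'
#' @param genes Character vector of gene symbols.
#' @param library A [GeneSetLibrary-class].
#' @param term Name of a set in `library`.
#' @return Sorted character vector `genes n library[[term]]`.
#' @examples
#' lib <- GeneSetLibrary(list(HOMEOBOX = c("HOXA5", "HOXB8")))
#' annotateMembership(c("HOXA5", "GFAP"), lib, "HOMEOBOX")
#' @export
annotateMembership <- function(genes, library, term) {
  stopifnot(is(library, "GeneSetLibrary"))
  if (!term %in% names(geneSets(library)))
    stop("unknown term: ", term, call. = FALSE)
  genes <- unique(normalizeSymbols(genes))
  sort(intersect(genes, geneSets(library)[[term]]))
}
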