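#' @describeIn GeneSetLibrary-class named list of member vectors
#' @export
setMethod("geneSets", "GeneSetLibrary", function(x) x@sets)

#' @describeIn GeneSetLibrary-class provenance string
#' @export
setMethod("sourceTag", "GeneSetLibrary", function(x) x@sourceTag)

#' @describeIn Interactome-class provenance string
#' @export
setMethod("sourceTag", "Interactome", function(x) x@sourceTag)

#' @describeIn Interactome-class cleaned edge table
#' @export
setMethod("edges", "Interactome", function(x) x@edges)

#' @describeIn RegulatoryNetwork-class typed edge table
#' @export
setMethod("edges", "RegulatoryNetwork", function(x) x@edges)

#' @describeIn RegulatoryNetwork-class node table with role tags
#' @export
setMethod("networkNodes", "RegulatoryNetwork", function(x) x@nodes)

#' @describeIn TFCatalog-class catalog member symbols
#' @export
setMethod("members", "TFCatalog", function(x) x@members)

#' @describeIn TFCatalog-class catalog size (the enrichment universe N)
#' @export
setMethod("totalCount", "TFCatalog", function(x) length(x@members))

#' @describeIn GOAnnotationCorpus-class all term ids
#' @export
setMethod("termIds", "GOAnnotationCorpus", function(x) names(x@terms))

#' @describeIn GOAnnotationCorpus-class annotated protein ids of one term
#' @export
setMethod("termProteins", "GOAnnotationCorpus", function(x, term) {
  if (!term %in% names(x@terms))
    stop("unknown term id: ", term, call. = FALSE)
  x@terms[[term]]
})

#' @describeIn GOAnnotationCorpus-class human-readable name of one term
#' @export
setMethod("termName", "GOAnnotationCorpus", function(x, term) {
  if (!term %in% names(x@termNames))
    stop("unknown term id: ", term, call. = FALSE)
  unname(x@termNames[[term]])
})

#' @describeIn GOAnnotationCorpus-class size of the protein universe
#' @export
setMethod("nProteins", "GOAnnotationCorpus", function(x) x@nProteins)

#' @describeIn ExpressionTable-class recorded expression unit (TPM/FPKM)
#' @export
setMethod("exprUnit", "ExpressionTable", function(x)
  S4Vectors::metadata(x)$unit)

#' @describeIn ExpressionTable-class the expression matrix
#' @export
setMethod("exprValues", "ExpressionTable", function(x)
  SummarizedExperiment::assay(x, "expr"))

setMethod("show", "GeneSetLibrary", function(object) {
  cat("GeneSetLibrary with", length(object@sets), "set(s)\n")
  cat("  source:", object@sourceTag, "\n")
  if (length(object@sets)) {
    sz <- vapply(object@sets, length, 0L)
    head_n <- utils::head(names(object@sets), 5L)
    cat("  sets:", paste0(head_n, " (", sz[head_n], ")", collapse = ", "),
        if (length(object@sets) > 5L) "..." else "", "\n")
  }
})

setMethod("show", "Interactome", function(object) {
  cat("Interactome with", nrow(object@edges), "cleaned edge(s),",
      length(unique(c(object@edges$a, object@edges$b))), "protein(s)\n")
  cat("  source:", object@sourceTag, "\n")
  if (length(object@filterLog))
    cat("  dropped at ingestion:",
        paste(names(object@filterLog), object@filterLog,
              sep = "=", collapse = ", "), "\n")
})

setMethod("show", "TFCatalog", function(object) {
  cat("TFCatalog with", length(object@members), "transcription factor(s)\n")
})

setMethod("show", "GOAnnotationCorpus", function(object) {
  cat("GOAnnotationCorpus:", length(object@terms), "term(s) over",
      object@nProteins, "protein(s)\n")
})

setMethod("show", "RegulatoryNetwork", function(object) {
  cat("RegulatoryNetwork:", nrow(object@nodes), "node(s),",
      nrow(object@edges), "edge(s)\n")
  if (nrow(object@edges)) {
    tb <- table(factor(object@edges$type, levels = .EDGE_TYPES))
    cat("  ", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
})
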