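#' @rdname GeneSetLibrary-class
#' @param x,object An object.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetLibrary-class
#' @export
setGeneric("sourceTag", function(x) standardGeneric("sourceTag"))

#' @rdname Interactome-class
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname TFCatalog-class
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname TFCatalog-class
#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))

#' @rdname GOAnnotationCorpus-class
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' @rdname GOAnnotationCorpus-class
#' @param term A term id.
#' @export
setGeneric("termProteins", function(x, term) standardGeneric("termProteins"))

#' @rdname GOAnnotationCorpus-class
#' @export
setGeneric("termName", function(x, term) standardGeneric("termName"))

#' @rdname GOAnnotationCorpus-class
#' @export
setGeneric("nProteins", function(x) standardGeneric("nProteins"))

#' @rdname RegulatoryNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname ExpressionTable-class
#' @export
setGeneric("exprUnit", function(x) standardGeneric("exprUnit"))

#' @rdname ExpressionTable-class
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
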