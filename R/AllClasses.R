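#' @import methods
#' @importFrom S4Vectors metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' GeneSetLibrary: named gene sets sharing one normalized symbol space
#'
#' Container for named sets of normalized gene symbols. Both tissue genomic
#' signatures (one set per tissue) and annotation libraries (one set per
#' protein family or term) use this shape, so crossing and enrichment code
#' operate on a single type.
#'
#' @slot sets Named list; each element a character vector of normalized gene
#'   symbols (see [normalizeSymbols()]). Set names are unique; sets may
#'   overlap.
#' @slot sourceTag Free-text provenance of the library (file path, database
#'   release, or "synthetic").
#'
#' @seealso [readGmt()], [writeGmt()], [crossSignatures()],
#'   [overrepresentation()]
#' @export
setClass("GeneSetLibrary",
  representation(sets = "list", sourceTag = "character"),
  prototype(sets = list(), sourceTag = NA_character_)
)

setValidity("GeneSetLibrary", function(object) {
  s <- object@sets
  if (length(s) == 0L) return(TRUE)
  if (is.null(names(s)) || anyNA(names(s)) || any(names(s) == ""))
    return("all gene sets must be named")
  if (anyDuplicated(names(s)))
    return("gene set names must be unique")
  for (nm in names(s)) {
    g <- s[[nm]]
    if (!is.character(g))
      return(sprintf("set '%s' is not a character vector", nm))
    if (anyDuplicated(g))
      return(sprintf("set '%s' contains duplicate members", nm))
    if (!identical(g, normalizeSymbols(g)))
      return(sprintf("set '%s' contains non-normalized symbols", nm))
  }
  TRUE
})

#' ExpressionTable: genes-by-columns expression values with group metadata
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' assay `"expr"` of non-negative expression values (TPM or FPKM; the unit is
#' recorded in `metadata(x)$unit`), gene symbols as rownames (normalized,
#' duplicate-free), and per-column `label`, `group` and `n_samples` in
#' `colData`. For median tables each column is a region and `n_samples` is
#' the number of donors behind the median; for per-sample matrices each
#' column is a sample and `group` tags its comparison arm.
#'
#' @seealso [ExpressionTable()], [readExpressionTsv()],
#'   [regionSpecificFilter()], [welchDe()]
#' @export
setClass("ExpressionTable", contains = "SummarizedExperiment")

setValidity("ExpressionTable", function(object) {
  if (!"expr" %in% SummarizedExperiment::assayNames(object))
    return("assay 'expr' is required")
  v <- SummarizedExperiment::assay(object, "expr")
  if (!is.numeric(v)) return("expression values must be numeric")
  if (any(!is.finite(v))) return("expression values must be finite")
  if (any(v < 0)) return("expression values must be non-negative")
  g <- rownames(object)
  if (is.null(g) || any(g == "")) return("gene rownames are required")
  if (anyDuplicated(g)) return("duplicate gene symbols after normalization")
  if (!identical(g, normalizeSymbols(g)))
    return("gene symbols must be normalized")
  cd <- SummarizedExperiment::colData(object)
  need <- c("label", "group", "n_samples")
  if (!all(need %in% colnames(cd)))
    return("colData must carry label, group and n_samples")
  u <- S4Vectors::metadata(object)$unit
  if (is.null(u) || !is.character(u) || length(u) != 1L)
    return("metadata(x)$unit must be a single string (e.g. 'TPM')")
  TRUE
})

#' Interactome: cleaned undirected protein-protein interaction edges
#'
#' Edge set of published, same-species physical interactions. Edges are
#' stored with endpoints in lexicographic order so the set is invariant to
#' the order partners appeared in the source file; self-edges are excluded.
#'
#' @slot edges data.frame with character columns `a`, `b` (normalized
#'   symbols, `a < b`), `publication`, `system`.
#' @slot sourceTag Provenance string.
#' @slot filterLog Named integer vector counting rows dropped at ingestion
#'   (non-human species, unpublished, self-edges).
#'
#' @seealso [readInteractome()], [firstShell()]
#' @export
setClass("Interactome",
  representation(edges = "data.frame", sourceTag = "character",
                 filterLog = "integer"),
  prototype(edges = data.frame(a = character(), b = character(),
                               publication = character(),
                               system = character(),
                               stringsAsFactors = FALSE),
            sourceTag = NA_character_, filterLog = integer())
)

setValidity("Interactome", function(object) {
  e <- object@edges
  need <- c("a", "b", "publication", "system")
  if (!all(need %in% colnames(e)))
    return("edges need columns a, b, publication, system")
  if (nrow(e) == 0L) return(TRUE)
  if (any(e$a == e$b)) return("self-edges are not allowed")
  if (any(e$a > e$b)) return("edges must be stored with a < b")
  if (anyDuplicated(e[, c("a", "b")]))
    return("duplicate edges are not allowed")
  TRUE
})

#' TFCatalog: the transcription-factor universe
#'
#' The set of human genes encoding sequence-specific DNA-binding
#' transcription regulators. Serves both as the filter in interactor
#' crossing and as the universe N of the module over-representation test.
#'
#' @slot members Character vector of normalized, duplicate-free symbols.
#'
#' @seealso [readTfCatalog()], [crossWithTfs()], [moduleEnrichment()]
#' @export
setClass("TFCatalog",
  representation(members = "character"),
  prototype(members = character())
)

setValidity("TFCatalog", function(object) {
  m <- object@members
  if (length(m) == 0L) return("catalog must be non-empty")
  if (anyDuplicated(m)) return("catalog members must be unique")
  if (!identical(m, normalizeSymbols(m)))
    return("catalog members must be normalized symbols")
  TRUE
})

#' GOAnnotationCorpus: term-to-protein annotation sets
#'
#' Gene Ontology annotations flattened to one protein set per term, the
#' substrate of the co-occurrence screen. Protein identity is by database
#' object id (GAF column 2), not symbol. `nProteins` is the size of the
#' corpus protein universe (every annotated protein is counted).
#'
#' @slot terms Named list, term id -> character vector of protein ids.
#' @slot termNames Named character vector, term id -> human-readable name.
#' @slot nProteins Integer scalar, size of the protein universe.
#'
#' @seealso [readGaf()], [cooccurringTerms()], [antagonismScreen()]
#' @export
setClass("GOAnnotationCorpus",
  representation(terms = "list", termNames = "character",
                 nProteins = "integer"),
  prototype(terms = list(), termNames = character(), nProteins = 0L)
)

setValidity("GOAnnotationCorpus", function(object) {
  t <- object@terms
  if (length(t) == 0L) return(TRUE)
  if (is.null(names(t)) || anyDuplicated(names(t)))
    return("term ids must be present and unique")
  if (any(vapply(t, length, 0L) == 0L))
    return("term annotation sets must be non-empty")
  if (!all(names(t) %in% names(object@termNames)))
    return("every term id needs an entry in termNames")
  n <- length(unique(unlist(t, use.names = FALSE)))
  if (object@nProteins < n)
    return("nProteins smaller than the number of annotated proteins")
  TRUE
})

#' RegulatoryNetwork: typed multigraph of regulatory evidence
#'
#' Union of three evidence layers over one node set: undirected physical
#' protein-protein interactions, directed curated transcriptional repression
#' (TF -> silenced target), and directed predicted TF binding (motif in the
#' target promoter). Each edge carries its evidence type and free-text
#' provenance; physical edges are stored order-normalized.
#'
#' @slot nodes data.frame with columns `node` (normalized symbol) and
#'   `role` (free tag such as hox, tf, pathway_member, receptor).
#' @slot edges data.frame with columns `source`, `target`,
#'   `type` (one of physical, repression, predicted_binding), `provenance`.
#'
#' @seealso [assembleNetwork()], [exportNetwork()]
#' @export
setClass("RegulatoryNetwork",
  representation(nodes = "data.frame", edges = "data.frame"),
  prototype(
    nodes = data.frame(node = character(), role = character(),
                       stringsAsFactors = FALSE),
    edges = data.frame(source = character(), target = character(),
                       type = character(), provenance = character(),
                       stringsAsFactors = FALSE))
)

.EDGE_TYPES <- c("physical", "repression", "predicted_binding")

setValidity("RegulatoryNetwork", function(object) {
  e <- object@edges
  n <- object@nodes
  if (!all(c("node", "role") %in% colnames(n)))
    return("nodes need columns node, role")
  if (anyDuplicated(n$node)) return("duplicate node declarations")
  if (!all(c("source", "target", "type", "provenance") %in% colnames(e)))
    return("edges need columns source, target, type, provenance")
  if (nrow(e) == 0L) return(TRUE)
  if (!all(e$type %in% .EDGE_TYPES))
    return(sprintf("edge types must be one of: %s",
                   paste(.EDGE_TYPES, collapse = ", ")))
  if (anyDuplicated(e[, c("source", "target", "type")]))
    return("duplicate (source, target, type) triples")
  ph <- e[e$type == "physical", , drop = FALSE]
  if (nrow(ph) && any(ph$source > ph$target))
    return("physical edges must be stored order-normalized (source < target)")
  if (!all(c(e$source, e$target) %in% n$node))
    return("every edge endpoint must be a declared node")
  TRUE
})
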