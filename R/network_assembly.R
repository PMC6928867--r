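## helper: canonicalize one evidence layer into the edge schema
.layerEdges <- function(df, type, undirected) {
  if (is.null(df) || nrow(df) == 0L)
    return(data.frame(source = character(), target = character(),
                      type = character(), provenance = character(),
                      stringsAsFactors = FALSE))
  if (!all(c("source", "target") %in% colnames(df)))
    stop(type, " layer needs columns source, target", call. = FALSE)
  src <- normalizeSymbols(df$source)
  tgt <- normalizeSymbols(df$target)
  prov <- if ("provenance" %in% colnames(df)) as.character(df$provenance)
          else rep("", nrow(df))
  if (undirected) {
    swap <- src > tgt
    tmp <- src[swap]; src[swap] <- tgt[swap]; tgt[swap] <- tmp
  }
  out <- data.frame(source = src, target = tgt, type = type,
                    provenance = prov, stringsAsFactors = FALSE)
  # duplicates of one triple merge with concatenated provenance
  key <- paste(out$source, out$target, out$type, sep = "\r")
  if (anyDuplicated(key)) {
    prov_merged <- vapply(split(out$provenance, key), function(p) {
      paste(unique(p[nzchar(p)]), collapse = ";")
    }, character(1))
    out <- out[!duplicated(key), , drop = FALSE]
    out$provenance <- unname(prov_merged[paste(out$source, out$target,
                                               out$type, sep = "\r")])
  }
  out
}

#' Assemble a typed regulatory network from evidence layers
#'
#' Unions three evidence layers into one [RegulatoryNetwork-class]:
#' `physical` (undirected protein-protein interactions, endpoints
#' order-normalized), `repression` (directed, curated transcriptional
#' silencing, TF -> target) and `predicted` (directed, motif-predicted TF
#' binding, TF -> target). Nodes are auto-declared from the edges; known
#' roles can be supplied via `roles`. Duplicate (source, target, type)
#' triples are merged with concatenated provenance, so assembling a
#' network's own layers returns an equal network.
#'
#' @param physical,repression,predicted data.frames with columns `source`,
#'   `target` and optionally `provenance`; any may be `NULL` or empty.
#' @param roles Optional named character vector, node -> role tag (e.g.
#'   `c(HOXA5 = "hox", AR = "receptor")`); undeclared nodes get
#'   `"unknown"`.
#' @return A [RegulatoryNetwork-class].
#' @examples
#' rep_edges <- data.frame(source = "AR",
#'                         target = c("SOX2", "SMAD3", "TGFBR2", "TGFB1"))
#' assembleNetwork(repression = rep_edges)
#' @export
assembleNetwork <- function(physical = NULL, repression = NULL,
                            predicted = NULL, roles = NULL) {
  e <- rbind(.layerEdges(physical, "physical", undirected = TRUE),
             .layerEdges(repression, "repression", undirected = FALSE),
             .layerEdges(predicted, "predicted_binding", undirected = FALSE))
  nodes <- sort(unique(c(e$source, e$target)))
  role <- rep("unknown", length(nodes))
  if (!is.null(roles)) {
    names(roles) <- normalizeSymbols(names(roles))
    hit <- nodes %in% names(roles)
    role[hit] <- unname(roles[nodes[hit]])
  }
  rownames(e) <- NULL
  new("RegulatoryNetwork",
      nodes = data.frame(node = nodes, role = role,
                         stringsAsFactors = FALSE),
      edges = e)
}

#' Export a regulatory network
#'
#' Writes GraphML (via igraph; edge attributes `type` and `provenance`,
#' vertex attribute `role`) or SIF (`source<TAB>type<TAB>target`, one edge
#' per line; roles and provenance are not representable in SIF). Importing
#' the written file with [importNetwork()] reproduces the typed edge set.
#'
#' @param net A [RegulatoryNetwork-class].
#' @param path Output path.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("graphml", "sif")) {
  stopifnot(is(net, "RegulatoryNetwork"))
  format <- match.arg(format)
  e <- edges(net)
  if (format == "sif") {
    writeLines(paste(e$source, e$type, e$target, sep = "\t"), path,
               useBytes = TRUE)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = e$source, to = e$target, type = e$type,
                   provenance = e$provenance, stringsAsFactors = FALSE),
    directed = TRUE, vertices = networkNodes(net))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Import a regulatory network written by exportNetwork
#'
#' @param path Path to a GraphML or SIF file.
#' @param format `"graphml"` or `"sif"`.
#' @return A [RegulatoryNetwork-class]. SIF files carry no role or
#'   provenance information; those fields come back as defaults.
#' @export
importNetwork <- function(path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    f <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(f, length, 0L) != 3L)
    if (length(bad))
      stop(sprintf("%s: line %d is not 'source<TAB>type<TAB>target'",
                   path, bad[1]), call. = FALSE)
    df <- data.frame(source = vapply(f, `[[`, "", 1L),
                     type = vapply(f, `[[`, "", 2L),
                     target = vapply(f, `[[`, "", 3L),
                     stringsAsFactors = FALSE)
    return(assembleNetwork(
      physical = df[df$type == "physical", c("source", "target")],
      repression = df[df$type == "repression", c("source", "target")],
      predicted = df[df$type == "predicted_binding",
                     c("source", "target")]))
  }
  g <- igraph::read_graph(path, format = "graphml")
  e <- igraph::as_data_frame(g, what = "edges")
  v <- igraph::as_data_frame(g, what = "vertices")
  lay <- function(tp) {
    d <- e[e$type == tp, , drop = FALSE]
    if (nrow(d) == 0L) return(NULL)
    data.frame(source = d$from, target = d$to,
               provenance = if ("provenance" %in% colnames(d))
                 d$provenance else "",
               stringsAsFactors = FALSE)
  }
  roles <- NULL
  if ("role" %in% colnames(v))
    roles <- stats::setNames(v$role, v$name)
  assembleNetwork(physical = lay("physical"),
                  repression = lay("repression"),
                  predicted = lay("predicted_binding"),
                  roles = roles)
}
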