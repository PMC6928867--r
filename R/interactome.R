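#' First-shell interactors of a query protein set
#'
#' For each query protein, returns every protein directly adjacent to it in
#' the cleaned interactome (its first interaction shell). Queries may appear
#' as partners of other queries (HOX proteins interact with each other). A
#' query absent from the network yields a warning and an empty partner set.
#'
#' @param queries Character vector of query protein symbols.
#' @param net An [Interactome-class].
#' @return A list of class `"PartnerTable"` with `rows` (data.frame
#'   `query`, `partner`, `is_tf`; `is_tf` is `NA` until [crossWithTfs()]),
#'   `partners` (sorted distinct partner union) and `queries`.
#' @examples
#' net <- Interactome(a = c("HOXB8", "HOXB8"), b = c("PBX1", "PBX3"))
#' firstShell("HOXB8", net)$partners
#' @export
firstShell <- function(queries, net) {
  stopifnot(is(net, "Interactome"))
  queries <- unique(normalizeSymbols(queries))
  e <- edges(net)
  known <- unique(c(e$a, e$b))
  absent <- setdiff(queries, known)
  if (length(absent))
    warning("query protein(s) absent from the network: ",
            paste(absent, collapse = ", "), call. = FALSE)
  rows <- lapply(queries, function(q) {
    p <- sort(unique(c(e$b[e$a == q], e$a[e$b == q])))
    if (length(p) == 0L) return(NULL)
    data.frame(query = q, partner = p, is_tf = NA, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(query = character(), partner = character(),
                       is_tf = logical(), stringsAsFactors = FALSE)
  structure(list(rows = rows, partners = sort(unique(rows$partner)),
                 queries = queries),
            class = "PartnerTable")
}

#' @export
print.PartnerTable <- function(x, ...) {
  cat("PartnerTable:", length(x$queries), "query protein(s),",
      nrow(x$rows), "row(s),", length(x$partners),
      "distinct partner(s)\n")
  if (any(!is.na(x$rows$is_tf)))
    cat("  distinct TF partners:",
        length(unique(x$rows$partner[x$rows$is_tf %in% TRUE])), "\n")
  invisible(x)
}

#' Cross interaction partners with a TF catalog
#'
#' Keeps only the partner rows whose partner is a catalogued transcription
#' factor. Distinct-TF counting is by partner symbol, not by (query,
#' partner) row: the same TF interacting with two query proteins counts
#' once. Applying the crossing twice changes nothing.
#'
#' @param partners A `"PartnerTable"` from [firstShell()].
#' @param catalog A [TFCatalog-class].
#' @return A `"PartnerTable"` restricted to TF rows, with `is_tf = TRUE`
#'   and `partners` the distinct TF partner union.
#' @export
crossWithTfs <- function(partners, catalog) {
  stopifnot(inherits(partners, "PartnerTable"), is(catalog, "TFCatalog"))
  rows <- partners$rows
  rows$is_tf <- rows$partner %in% members(catalog)
  rows <- rows[rows$is_tf, , drop = FALSE]
  rownames(rows) <- NULL
  structure(list(rows = rows, partners = sort(unique(rows$partner)),
                 queries = partners$queries),
            class = "PartnerTable")
}

#' Second-shell links from TFs into a gene module
#'
#' For a set of transcription factors (typically the TF partners found one
#' shell out from the query proteins), returns their interaction edges whose
#' other endpoint lies inside a gene module — e.g. the gliosis-associated
#' co-expression module. This is how SOX2 and SMAD1 are linked onward to
#' AR, GLIS3 and NFIB.
#'
#' @param tfs Character vector of TF symbols.
#' @param net An [Interactome-class].
#' @param module Character vector of module gene symbols.
#' @return data.frame with columns `tf`, `module_partner`, one row per
#'   edge found (zero rows when the module is empty or no edge lands in it).
#' @export
secondShellTfLinks <- function(tfs, net, module) {
  stopifnot(is(net, "Interactome"))
  tfs <- unique(normalizeSymbols(tfs))
  module <- if (length(module)) unique(normalizeSymbols(module))
            else character()
  out <- do.call(rbind, lapply(tfs, function(tf) {
    sh <- suppressWarnings(firstShell(tf, net))
    hit <- intersect(sh$partners, module)
    if (length(hit) == 0L) return(NULL)
    data.frame(tf = tf, module_partner = hit, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(tf = character(), module_partner = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
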