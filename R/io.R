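#' Normalize gene symbols
#'
#' Canonicalizes HGNC-style gene symbols: strips surrounding whitespace and
#' upper-cases. All ingestion paths apply this exactly once, so re-reading
#' written output changes nothing (normalization is idempotent). Gene
#' identity throughout the package is by normalized symbol; no identifier
#' mapping is performed.
#'
#' @param x Character vector of raw symbols.
#' @return Character vector of normalized symbols.
#' @examples
#' normalizeSymbols(c(" hoxa5 ", "Smad1"))
#' @export
normalizeSymbols <- function(x) {
  if (!is.character(x)) stop("symbols must be character", call. = FALSE)
  out <- toupper(trimws(x))
  if (any(out == "" | is.na(out)))
    stop("empty gene symbol after normalization", call. = FALSE)
  out
}

#' Construct a GeneSetLibrary
#'
#' @param sets Named list of character vectors of gene symbols; members are
#'   normalized and de-duplicated (first occurrence kept).
#' @param sourceTag Provenance string.
#' @return A [GeneSetLibrary-class] object.
#' @examples
#' GeneSetLibrary(list(SC = c("hoxa5", "HOXB8")), sourceTag = "example")
#' @export
GeneSetLibrary <- function(sets, sourceTag = "user") {
  sets <- lapply(sets, function(g) unique(normalizeSymbols(g)))
  new("GeneSetLibrary", sets = sets, sourceTag = sourceTag)
}

#' Construct an ExpressionTable
#'
#' @param values Numeric matrix, genes in rows (rownames required), columns
#'   labeled by region or sample.
#' @param unit Expression unit recorded with the data ("TPM" or "FPKM").
#' @param group Character vector of per-column group tags (defaults to the
#'   column labels themselves, as in a median table where each region is its
#'   own group).
#' @param nSamples Integer vector of per-column sample counts (the number of
#'   donors behind a median column, or 1 for an individual sample).
#' @return An [ExpressionTable-class] object.
#' @examples
#' m <- matrix(c(23.01, 0.08), 1, 2,
#'             dimnames = list("HOXA5", c("Spinal Cord", "Cerebellum")))
#' ExpressionTable(m, unit = "TPM", nSamples = c(159L, 241L))
#' @export
ExpressionTable <- function(values, unit, group = colnames(values),
                            nSamples = rep(1L, ncol(values))) {
  if (is.null(rownames(values)))
    stop("values must have gene rownames", call. = FALSE)
  if (is.null(colnames(values)))
    stop("values must have column labels", call. = FALSE)
  rownames(values) <- normalizeSymbols(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols after normalization: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  cd <- S4Vectors::DataFrame(label = colnames(values),
                             group = as.character(group),
                             n_samples = as.integer(nSamples))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values), colData = cd,
    metadata = list(unit = unit))
  new("ExpressionTable", se)
}

#' Construct a TFCatalog
#'
#' @param members Character vector of TF gene symbols (normalized and
#'   de-duplicated on construction).
#' @return A [TFCatalog-class] object; `totalCount()` is its size, the
#'   universe of the module over-representation test.
#' @examples
#' totalCount(TFCatalog(c("SOX2", "SMAD1", "AR")))
#' @export
TFCatalog <- function(members) {
  new("TFCatalog", members = unique(normalizeSymbols(members)))
}

## internal: order-normalize an edge table and drop duplicates
.normalizeEdges <- function(a, b, publication, system) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  df <- data.frame(a = a, b = b, publication = publication, system = system,
                   stringsAsFactors = FALSE)
  df[!duplicated(df[, c("a", "b")]), , drop = FALSE]
}

#' Construct an Interactome from raw edge endpoints
#'
#' Symbols are normalized, endpoints order-normalized (so the edge set does
#' not depend on partner order in the source), self-edges dropped, and
#' duplicate pairs collapsed to their first occurrence.
#'
#' @param a,b Character vectors of interacting partners.
#' @param publication,system Optional per-edge metadata.
#' @param sourceTag Provenance string.
#' @param filterLog Named integer vector of ingestion drop counts.
#' @return An [Interactome-class] object.
#' @examples
#' Interactome(a = c("SMAD1", "HOXA5"), b = c("HOXA5", "SOX2"))
#' @export
Interactome <- function(a, b, publication = rep("", length(a)),
                        system = rep("", length(a)),
                        sourceTag = "user", filterLog = integer()) {
  a <- normalizeSymbols(a); b <- normalizeSymbols(b)
  keep <- a != b
  filterLog <- c(filterLog, self_edges = sum(!keep))
  df <- .normalizeEdges(a[keep], b[keep], publication[keep], system[keep])
  new("Interactome", edges = df, sourceTag = sourceTag,
      filterLog = filterLog[filterLog > 0L | names(filterLog) != "self_edges"])
}

#' Read a GMT gene-set library
#'
#' One set per line: `name<TAB>description<TAB>member...`. Members are
#' normalized and de-duplicated; empty member fields are skipped.
#'
#' @param path Path to a GMT file.
#' @return A [GeneSetLibrary-class]; the file path becomes the `sourceTag`.
#' @seealso [writeGmt()]
#' @export
readGmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("%s: line %d: expected >= 3 tab-separated fields", path, i),
           call. = FALSE)
    nm <- trimws(f[[1]])
    if (nm %in% names(sets))
      stop(sprintf("%s: line %d: duplicate set name '%s'", path, i, nm),
           call. = FALSE)
    memb <- trimws(f[-(1:2)])
    memb <- memb[nzchar(memb)]
    if (length(memb) == 0L)
      stop(sprintf("%s: line %d: set '%s' has no members", path, i, nm),
           call. = FALSE)
    sets[[nm]] <- unique(normalizeSymbols(memb))
  }
  new("GeneSetLibrary", sets = sets, sourceTag = path)
}

#' Write a GeneSetLibrary to GMT
#'
#' Inverse of [readGmt()]: `readGmt(writeGmt(lib, f))` reproduces `lib`'s
#' sets exactly.
#'
#' @param lib A [GeneSetLibrary-class].
#' @param path Output path.
#' @param description Description field written in column 2 of every line.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(lib, path, description = "na") {
  stopifnot(is(lib, "GeneSetLibrary"))
  lines <- vapply(names(lib@sets), function(nm) {
    paste(c(nm, description, lib@sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of column labels and a first column of gene symbols,
#' followed by a numeric body. Values must be non-negative; offending cells
#' are reported with their coordinates. Gene symbols are normalized; a
#' duplicated gene row is an error.
#'
#' @param path Path to a tab-separated file.
#' @param unit Expression unit to record ("TPM" or "FPKM").
#' @param group,nSamples Optional per-column metadata, as in
#'   [ExpressionTable()].
#' @return An [ExpressionTable-class].
#' @seealso [writeExpressionTsv()]
#' @export
readExpressionTsv <- function(path, unit, group = NULL, nSamples = NULL) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", sep = "\t")
  if (ncol(df) < 2L)
    stop(path, ": expected a gene column plus >= 1 value column",
         call. = FALSE)
  genes <- df[[1]]
  body <- df[, -1, drop = FALSE]
  vals <- matrix(NA_real_, nrow(body), ncol(body),
                 dimnames = list(NULL, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("%s: non-numeric value '%s' at gene %s, column '%s'",
                   path, body[[j]][bad[1]], genes[bad[1]],
                   colnames(body)[j]), call. = FALSE)
    neg <- which(v < 0)
    if (length(neg))
      stop(sprintf("%s: negative value %s at gene %s, column '%s'",
                   path, v[neg[1]], genes[neg[1]], colnames(body)[j]),
           call. = FALSE)
    vals[, j] <- v
  }
  rownames(vals) <- genes
  if (is.null(group)) group <- colnames(vals)
  if (is.null(nSamples)) nSamples <- rep(1L, ncol(vals))
  ExpressionTable(vals, unit = unit, group = group, nSamples = nSamples)
}

#' Write an ExpressionTable to TSV
#'
#' @param x An [ExpressionTable-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeExpressionTsv <- function(x, path) {
  stopifnot(is(x, "ExpressionTable"))
  v <- exprValues(x)
  df <- data.frame(gene = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein-interaction edge list
#'
#' Reads a 6-column tab-separated dialect: `interactor_a`, `interactor_b`,
#' `taxid_a`, `taxid_b`, `publication_id`, `system`. Cleaning applies the
#' filters used when mining curated interaction databases: rows where either
#' taxid differs from `speciesTaxid` are dropped (interactions reported in
#' non-human species), rows with an empty publication id are dropped
#' (unpublished interactions), and self-edges are dropped. Drop counts are
#' kept in the object's `filterLog` and shown by `show()`. Wider exports
#' must be pre-projected, or read with `columnMap` naming which input
#' columns carry the six roles.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param speciesTaxid Taxon id to retain (default `"9606"`, human).
#' @param columnMap Optional named character vector mapping the six required
#'   roles to the file's column names.
#' @return An [Interactome-class].
#' @export
readInteractome <- function(path, speciesTaxid = "9606", columnMap = NULL) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", sep = "\t")
  need <- c("interactor_a", "interactor_b", "taxid_a", "taxid_b",
            "publication_id", "system")
  if (!is.null(columnMap)) {
    if (!all(need %in% names(columnMap)))
      stop("columnMap must name all of: ", paste(need, collapse = ", "),
           call. = FALSE)
    missing_src <- setdiff(unname(columnMap[need]), colnames(df))
    if (length(missing_src))
      stop(path, ": missing mapped column(s): ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    df <- stats::setNames(df[, unname(columnMap[need]), drop = FALSE], need)
  }
  missing_col <- setdiff(need, colnames(df))
  if (length(missing_col))
    stop(path, ": missing required column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  n0 <- nrow(df)
  sp <- df$taxid_a == speciesTaxid & df$taxid_b == speciesTaxid
  df <- df[sp, , drop = FALSE]
  n_species <- n0 - nrow(df)
  pub <- nzchar(trimws(df$publication_id))
  df <- df[pub, , drop = FALSE]
  n_unpub <- sum(!pub)
  a <- normalizeSymbols(df$interactor_a)
  b <- normalizeSymbols(df$interactor_b)
  keep <- a != b
  n_self <- sum(!keep)
  edges <- .normalizeEdges(a[keep], b[keep], df$publication_id[keep],
                           df$system[keep])
  new("Interactome", edges = edges, sourceTag = path,
      filterLog = c(non_species = n_species, unpublished = n_unpub,
                    self_edges = n_self))
}

#' Write an Interactome in the 6-column dialect
#'
#' @param net An [Interactome-class].
#' @param path Output path.
#' @param speciesTaxid Taxid written for both endpoints.
#' @return `path`, invisibly.
#' @export
writeInteractome <- function(net, path, speciesTaxid = "9606") {
  stopifnot(is(net, "Interactome"))
  e <- edges(net)
  pub <- ifelse(nzchar(e$publication), e$publication, "PMID:0")
  df <- data.frame(interactor_a = e$a, interactor_b = e$b,
                   taxid_a = speciesTaxid, taxid_b = speciesTaxid,
                   publication_id = pub, system = e$system,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcription-factor catalog from a plain list
#'
#' One symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to a text file.
#' @return A [TFCatalog-class].
#' @export
readTfCatalog <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop(path, ": empty TF catalog", call. = FALSE)
  TFCatalog(lines)
}

#' Write a TFCatalog as a plain list
#'
#' @param catalog A [TFCatalog-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTfCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "TFCatalog"))
  writeLines(members(catalog), path, useBytes = TRUE)
  invisible(path)
}
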