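#' Construct a GOAnnotationCorpus
#'
#' @param terms Named list, term id -> character vector of annotated
#'   protein ids (duplicates collapsed; empty sets rejected by validity).
#' @param termNames Named character vector, term id -> term name; ids
#'   missing here get their id as name.
#' @param nProteins Size of the corpus protein universe; defaults to the
#'   number of distinct annotated proteins.
#' @return A [GOAnnotationCorpus-class].
#' @export
GOAnnotationCorpus <- function(terms, termNames = NULL, nProteins = NULL) {
  terms <- lapply(terms, function(p) unique(as.character(p)))
  if (is.null(termNames)) termNames <- character()
  miss <- setdiff(names(terms), names(termNames))
  termNames <- c(termNames, stats::setNames(miss, miss))
  if (is.null(nProteins))
    nProteins <- length(unique(unlist(terms, use.names = FALSE)))
  new("GOAnnotationCorpus", terms = terms, termNames = termNames,
      nProteins = as.integer(nProteins))
}

#' Read a GAF 2.1 annotation subset into a corpus
#'
#' Parses a Gene Ontology Annotation File: `!`-prefixed comment lines are
#' skipped; column 2 (DB object id) identifies the protein, column 3 the
#' symbol, column 4 the qualifier, column 5 the GO id, column 7 the
#' evidence code. Rows whose qualifier contains `NOT` are dropped (they
#' state what a protein does *not* do). Evidence codes are kept by default;
#' pass `evidenceKeep` to restrict. Annotations are not propagated up the
#' ontology unless an OBO file is supplied via `obo` with
#' `propagate = TRUE` (is_a/part_of parents only).
#'
#' @param path Path to a GAF 2.1 file (uncompressed).
#' @param evidenceKeep Optional character vector of evidence codes to keep.
#' @param obo Optional path to an OBO ontology file.
#' @param propagate If `TRUE` (requires `obo`), each annotation is copied
#'   to all is_a/part_of ancestors of its term.
#' @param termNames Optional named character vector of term names; names
#'   found in the OBO file (when given) are used too.
#' @return A [GOAnnotationCorpus-class].
#' @export
readGaf <- function(path, evidenceKeep = NULL, obo = NULL,
                    propagate = FALSE, termNames = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0L) stop(path, ": no annotation rows", call. = FALSE)
  f <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(f, length, 0L) < 7L)
  if (length(short))
    stop(sprintf("%s: annotation row %d has < 7 columns", path, short[1]),
         call. = FALSE)
  obj <- vapply(f, `[[`, "", 2L)
  qual <- vapply(f, `[[`, "", 4L)
  go <- vapply(f, `[[`, "", 5L)
  ev <- vapply(f, `[[`, "", 7L)
  keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
  if (!is.null(evidenceKeep)) keep <- keep & ev %in% evidenceKeep
  obj <- obj[keep]; go <- go[keep]
  if (length(go) == 0L)
    stop(path, ": no annotations left after filtering", call. = FALSE)
  oboNames <- character(); parents <- list()
  if (!is.null(obo)) {
    ont <- .readOboIsA(obo)
    oboNames <- ont$names
    parents <- ont$parents
  }
  if (propagate) {
    if (is.null(obo))
      stop("propagate = TRUE requires an obo file", call. = FALSE)
    anc <- lapply(unique(go), .oboAncestors, parents = parents)
    names(anc) <- unique(go)
    extra_go <- unlist(anc[go], use.names = FALSE)
    extra_obj <- rep(obj, times = vapply(anc[go], length, 0L))
    go <- c(go, extra_go); obj <- c(obj, extra_obj)
  }
  terms <- lapply(split(obj, go), unique)
  GOAnnotationCorpus(terms,
                     termNames = c(termNames,
                                   oboNames[setdiff(names(oboNames),
                                                    names(termNames))]))
}

## internal: minimal OBO parser, [Term] stanzas, id/name/is_a and
## relationship: part_of only
.readOboIsA <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  ids <- character(); nms <- character(); parents <- list()
  cur <- NULL; in_term <- FALSE
  for (ln in lines) {
    if (ln == "[Term]") { in_term <- TRUE; cur <- NULL; next }
    if (startsWith(ln, "[")) { in_term <- FALSE; next }
    if (!in_term) next
    if (startsWith(ln, "id: ")) {
      cur <- sub("^id: ", "", ln)
      parents[[cur]] <- character()
    } else if (startsWith(ln, "name: ") && !is.null(cur)) {
      nms[cur] <- sub("^name: ", "", ln)
    } else if (startsWith(ln, "is_a: ") && !is.null(cur)) {
      parents[[cur]] <- c(parents[[cur]],
                          sub("^is_a: (\\S+).*", "\\1", ln))
    } else if (startsWith(ln, "relationship: part_of ") && !is.null(cur)) {
      parents[[cur]] <- c(parents[[cur]],
                          sub("^relationship: part_of (\\S+).*", "\\1", ln))
    }
  }
  list(names = nms, parents = parents)
}

.oboAncestors <- function(term, parents) {
  seen <- character(); frontier <- parents[[term]]
  while (length(frontier)) {
    frontier <- setdiff(unique(frontier), seen)
    seen <- c(seen, frontier)
    frontier <- unlist(parents[frontier], use.names = FALSE)
  }
  seen
}

#' Terms co-occurring with a queried GO term
#'
#' Lists every other term of the corpus sharing at least one annotated
#' protein with the query, with the statistics used to rank them:
#' percent-Jaccard similarity `S = 100 * c_ab / (c_a + c_b - c_ab)` and
#' probability ratio `PR = (c_ab / c_b) / (c_a / N)` (how much more likely
#' a term-b protein is to carry the query annotation than a random corpus
#' protein). Rows are sorted by similarity descending, ties by PR
#' descending then term id, and ranked 1..n.
#'
#' @param corpus A [GOAnnotationCorpus-class].
#' @param query A term id present in the corpus.
#' @return data.frame with columns `term_a`, `term_b`, `term_b_name`,
#'   `c_a`, `c_b`, `c_ab`, `similarity`, `prob_ratio`, `rank`.
#' @export
cooccurringTerms <- function(corpus, query) {
  stopifnot(is(corpus, "GOAnnotationCorpus"))
  if (!query %in% termIds(corpus))
    stop("unknown term id: ", query, call. = FALSE)
  qa <- termProteins(corpus, query)
  c_a <- length(qa)
  N <- nProteins(corpus)
  others <- setdiff(termIds(corpus), query)
  rows <- lapply(others, function(tb) {
    pb <- corpus@terms[[tb]]
    c_ab <- length(intersect(qa, pb))
    if (c_ab == 0L) return(NULL)
    c_b <- length(pb)
    data.frame(term_a = query, term_b = tb,
               term_b_name = termName(corpus, tb),
               c_a = c_a, c_b = c_b, c_ab = c_ab,
               similarity = 100 * c_ab / (c_a + c_b - c_ab),
               prob_ratio = (c_ab / c_b) / (c_a / N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(term_a = character(), term_b = character(),
                      term_b_name = character(), c_a = integer(),
                      c_b = integer(), c_ab = integer(),
                      similarity = numeric(), prob_ratio = numeric(),
                      rank = integer(), stringsAsFactors = FALSE)
    return(res)
  }
  res <- res[order(-res$similarity, -res$prob_ratio, res$term_b), ,
             drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Parse the regulation polarity of a GO term name
#'
#' Detects a leading "positive regulation of " or "negative regulation of "
#' (case-insensitive) and strips it, leaving the regulated concept.
#'
#' @param termName A term name.
#' @return List with `direction` (`"positive"`, `"negative"` or `"none"`)
#'   and `concept` (the residual name).
#' @examples
#' parsePolarity("Positive regulation of SMAD protein signal transduction")
#' @export
parsePolarity <- function(termName) {
  stopifnot(is.character(termName), length(termName) == 1L)
  m <- regexpr("^(positive|negative) regulation of ", termName,
               ignore.case = TRUE)
  if (m == -1L)
    return(list(direction = "none", concept = termName))
  prefix <- substr(termName, 1L, attr(m, "match.length"))
  dir <- tolower(sub(" .*", "", trimws(prefix)))
  list(direction = dir,
       concept = substring(termName, attr(m, "match.length") + 1L))
}

#' Screen two pathways' regulation terms for antagonistic overlap
#'
#' Takes the (positive, negative) regulation term pair of two pathways
#' (e.g. SMAD signalling and androgen-receptor signalling) and examines the
#' four cross-pathway term pairs for shared annotated proteins. An overlap
#' between opposite polarities (positive of one pathway with negative of
#' the other) is *antagonistic* evidence — activating one pathway
#' co-occurs with shutting the other down; same-polarity overlap is
#' *agonistic*. The verdict is `"antagonism-only"` when at least one
#' overlap is observed and all observed overlaps are antagonistic,
#' `"vacuous"` when no cross-pathway pair overlaps, and `"mixed"`
#' otherwise.
#'
#' For each overlapping pair the similarity and the rank of the partner
#' term in the queried term's full co-occurrence list are reported.
#'
#' @param corpus A [GOAnnotationCorpus-class].
#' @param pathwayA,pathwayB Character vectors `c(pos = id, neg = id)`; a
#'   term absent from the corpus is treated as annotating nothing (its
#'   pairs report "no overlap"), but a pathway with both terms absent is an
#'   error.
#' @return List of class `"AntagonismScreen"`: `pairs` (data.frame with
#'   `term_a`, `term_b`, `polarity_a`, `polarity_b`, `classification`,
#'   `overlap`, `c_ab`, `similarity`, `rank_b_in_a`, `n_cooccurring_a`)
#'   and `verdict`.
#' @export
antagonismScreen <- function(corpus, pathwayA, pathwayB) {
  stopifnot(is(corpus, "GOAnnotationCorpus"))
  for (pw in list(pathwayA, pathwayB)) {
    if (!all(c("pos", "neg") %in% names(pw)))
      stop("each pathway needs terms named 'pos' and 'neg'", call. = FALSE)
  }
  present <- function(id) id %in% termIds(corpus)
  if (!present(pathwayA["pos"]) && !present(pathwayA["neg"]))
    stop("both terms of pathway A are absent from the corpus",
         call. = FALSE)
  if (!present(pathwayB["pos"]) && !present(pathwayB["neg"]))
    stop("both terms of pathway B are absent from the corpus",
         call. = FALSE)
  grid <- expand.grid(pa = c("pos", "neg"), pb = c("pos", "neg"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pa <- grid$pa[i]; pb <- grid$pb[i]
    ta <- unname(pathwayA[pa]); tb <- unname(pathwayB[pb])
    cls <- if (pa == pb) "agonistic" else "antagonistic"
    out <- data.frame(term_a = ta, term_b = tb, polarity_a = pa,
                      polarity_b = pb, classification = cls,
                      overlap = FALSE, c_ab = 0L,
                      similarity = NA_real_, rank_b_in_a = NA_integer_,
                      n_cooccurring_a = NA_integer_,
                      stringsAsFactors = FALSE)
    if (!present(ta) || !present(tb)) return(out)
    co <- cooccurringTerms(corpus, ta)
    out$n_cooccurring_a <- nrow(co)
    hit <- co[co$term_b == tb, , drop = FALSE]
    if (nrow(hit)) {
      out$overlap <- TRUE
      out$c_ab <- hit$c_ab
      out$similarity <- hit$similarity
      out$rank_b_in_a <- hit$rank
    }
    out
  })
  pairs <- do.call(rbind, rows)
  observed <- pairs$classification[pairs$overlap]
  verdict <- if (length(observed) == 0L) "vacuous"
             else if (all(observed == "antagonistic")) "antagonism-only"
             else "mixed"
  structure(list(pairs = pairs, verdict = verdict),
            class = "AntagonismScreen")
}

#' @export
print.AntagonismScreen <- function(x, ...) {
  cat("AntagonismScreen verdict:", x$verdict, "\n")
  p <- x$pairs
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %s(%s) x %s(%s): %s\n", p$term_a[i], p$polarity_a[i],
                p$term_b[i], p$polarity_b[i],
                if (p$overlap[i])
                  sprintf("%s overlap, c_ab=%d, S=%.1f%%, rank %d/%d",
                          p$classification[i], p$c_ab[i], p$similarity[i],
                          p$rank_b_in_a[i], p$n_cooccurring_a[i])
                else "no overlap"))
  }
  invisible(x)
}
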