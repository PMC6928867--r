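#' Hypergeometric upper-tail probability
#'
#' Exact probability of drawing at least `k` marked items when `n` items are
#' drawn without replacement from a universe of `N` items of which `K` are
#' marked:
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} /
#'   \binom{N}{n}.}
#' This is the one-sided (over-representation) Fisher exact test used
#' throughout the package. Terms are computed in log space via `lgamma` so
#' the statistic is stable for universes of tens of thousands of genes, and
#' summed from the largest term for accuracy.
#'
#' @param N Universe size.
#' @param K Number of marked items in the universe.
#' @param n Draw size.
#' @param k Observed overlap; the tail starts here.
#' @return Probability in (0, 1]; `k = 0` returns exactly 1.
#' @examples
#' hypergeomTail(N = 1211, K = 12, n = 7, k = 2)  # ~0.0018
#' @export
hypergeomTail <- function(N, K, n, k) {
  if (length(N) != 1L || length(K) != 1L || length(n) != 1L || length(k) != 1L)
    stop("scalar arguments required", call. = FALSE)
  if (any(c(N, K, n, k) != floor(c(N, K, n, k))) || any(c(N, K, n, k) < 0))
    stop("arguments must be non-negative integers", call. = FALSE)
  if (K > N || n > N)
    stop("K and n must not exceed N", call. = FALSE)
  if (k > min(n, K))
    stop("k must not exceed min(n, K)", call. = FALSE)
  if (k == 0L) return(1)
  i <- k:min(n, K)
  lchoose_ <- function(a, b) lgamma(a + 1) - lgamma(b + 1) - lgamma(a - b + 1)
  lt <- lchoose_(K, i) + lchoose_(N - K, n - i) - lchoose_(N, n)
  m <- max(lt)
  p <- exp(m) * sum(exp(lt - m))
  min(p, 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate control: sort p ascending, set
#' `q_(i) = p_(i) * m / i`, enforce monotone non-decrease from the largest
#' rank down, cap at 1, and restore the input order. Delegates to
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
adjustBH <- function(p) {
  .checkP(p)
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni adjustment
#'
#' Family-wise error-rate control: `q_i = min(1, p_i * m)`.
#'
#' @inheritParams adjustBH
#' @return Adjusted p-values, same order as the input.
#' @export
adjustBonferroni <- function(p) {
  .checkP(p)
  stats::p.adjust(p, method = "bonferroni")
}

.checkP <- function(p) {
  if (!is.numeric(p) || length(p) == 0L)
    stop("p must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  invisible(p)
}

#' Over-representation analysis of a gene set against a library
#'
#' For each library term with at least one member inside the universe,
#' computes overlap counts with the query, the fold enrichment
#' `(k/n)/(K/N)`, the hypergeometric upper-tail p, and a multiplicity-
#' adjusted p across all emitted terms. This is the engine behind
#' protein-family enrichment of a tissue-specific signature and, with a TF
#' catalog as universe, the module-overlap statistic.
#'
#' @param query Character vector of gene symbols. Genes outside the universe
#'   are dropped with a warning.
#' @param library A [GeneSetLibrary-class] of term -> member sets.
#' @param universe Character vector of gene symbols forming the universe.
#' @param method `"BH"` or `"bonferroni"`.
#' @return data.frame with one row per emitted term, columns `term`, `k`,
#'   `n`, `K`, `N`, `fold`, `p_raw`, `p_adj`, `method`, sorted by `p_adj`,
#'   ties by `p_raw` then term name.
#' @examples
#' lib <- GeneSetLibrary(list(HOMEOBOX = c("G1", "G2", "G3", "G4")))
#' overrepresentation(c("G1", "G2"), lib, paste0("G", 1:100))
#' @export
overrepresentation <- function(query, library, universe,
                               method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(is(library, "GeneSetLibrary"))
  if (length(geneSets(library)) == 0L)
    stop("library is empty", call. = FALSE)
  universe <- unique(normalizeSymbols(universe))
  query <- unique(normalizeSymbols(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped: ",
            paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
    query <- intersect(query, universe)
  }
  if (length(query) == 0L)
    stop("no query genes remain inside the universe", call. = FALSE)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(geneSets(library)), function(term) {
    tset <- intersect(geneSets(library)[[term]], universe)
    K <- length(tset)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, tset))
    data.frame(term = term, k = k, n = n, K = K, N = N,
               fold = if (k == 0L) 0 else (k / n) / (K / N),
               p_raw = hypergeomTail(N, K, n, k),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    stop("no library term intersects the universe", call. = FALSE)
  res$p_adj <- if (method == "BH") adjustBH(res$p_raw)
               else adjustBonferroni(res$p_raw)
  res$method <- method
  res <- res[order(res$p_adj, res$p_raw, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Module over-representation of TF partners
#'
#' Quantifies whether the transcription-factor partners of a query protein
#' are over-represented in a co-expression module, against the full TF
#' catalog as universe: `N = totalCount(catalog)`, `K = |module TFs|`,
#' `n = |partners|`, `k = |partners n module|`; p from [hypergeomTail()],
#' fold enrichment `(k/n)/(K/N)`.
#'
#' @param partners Character vector of TF partner symbols. Symbols outside
#'   the catalog are dropped with a warning.
#' @param moduleTfs Character vector of module TF symbols (intersected with
#'   the catalog).
#' @param catalog A [TFCatalog-class], the universe.
#' @return One-row data.frame shaped like [overrepresentation()] output with
#'   `term = "module"`, plus an `overlap` column listing the shared symbols.
#' @examples
#' cat12 <- TFCatalog(paste0("TF", 1:1211))
#' moduleEnrichment(paste0("TF", 1:7), paste0("TF", c(1, 2, 100:109)), cat12)
#' @export
moduleEnrichment <- function(partners, moduleTfs, catalog) {
  stopifnot(is(catalog, "TFCatalog"))
  partners <- unique(normalizeSymbols(partners))
  moduleTfs <- unique(normalizeSymbols(moduleTfs))
  outside <- setdiff(partners, members(catalog))
  if (length(outside)) {
    warning(length(outside), " partner(s) outside the TF catalog dropped: ",
            paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
    partners <- intersect(partners, members(catalog))
  }
  if (length(partners) == 0L)
    stop("no partners remain inside the TF catalog", call. = FALSE)
  moduleTfs <- intersect(moduleTfs, members(catalog))
  N <- totalCount(catalog)
  K <- length(moduleTfs)
  n <- length(partners)
  ov <- intersect(partners, moduleTfs)
  k <- length(ov)
  data.frame(term = "module", k = k, n = n, K = K, N = N,
             fold = if (k == 0L) 0 else (k / n) / (K / N),
             p_raw = hypergeomTail(N, K, n, k),
             p_adj = hypergeomTail(N, K, n, k),
             method = "none",
             overlap = paste(sort(ov), collapse = ","),
             stringsAsFactors = FALSE)
}
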