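#' Simulation configuration for the synthetic-data generators
#'
#' One configuration object drives every generator, and identical
#' (config, seed) pairs produce identical outputs. The defaults are the
#' study conditions the pipeline was designed around: the ten
#' worked-example homeobox genes at their printed median TPM and fold
#' ratios, 10 samples per comparison arm, 19 sub-threshold distractor
#' genes, 85 first-shell interactors of which 14 are catalogued TFs, a TF
#' catalog of 1211 symbols, and a GO corpus where only the cross-polarity
#' term pairs of two pathways share annotated proteins (5 each).
#'
#' @param seed Integer seed; every generator sets it before drawing.
#' @param nDistractors Distractor genes added to the median table, with
#'   target-region TPM drawn uniformly below the filter threshold.
#' @param nSamplesPerGroup Samples per comparison arm (>= 2).
#' @param nNullGenes Unplanted (fold 1) genes in the per-sample matrix.
#' @param plantedGenes data.frame with columns `gene`, `target_tpm`,
#'   `fold_ratio`; defaults pair [hoxMedianTable()] medians with
#'   [bneFoldRatios()] ratios.
#' @param noiseSdLog Natural-log-scale standard deviation of per-sample
#'   values around the group mean (default 0.25, i.e. about 25% coefficient
#'   of variation, consistent with adjusted p-values of 1e-7..1e-5 at ten
#'   samples per arm for fold ratios of this size).
#' @param baseExpression Linear-scale mean of the reference arm and of null
#'   genes.
#' @param nNonTfPartners Planted first-shell partners absent from the TF
#'   catalog (default 71, so TF + non-TF partners total 85).
#' @param nBackgroundEdges Random interactome edges among background
#'   proteins touching no query.
#' @param nBackgroundProteins Size of the background protein pool those
#'   edges are drawn from (caps the number of distinct background edges).
#' @param tfCatalogSize Total TF catalog size including decoys (1211).
#' @param goTermSize Proteins annotated to each focal pathway term.
#' @param goPlantedOverlap Proteins shared by each cross-polarity focal
#'   pair (same-polarity pairs share none).
#' @param goBackgroundTerms Background GO terms drawn from the whole
#'   protein universe.
#' @param goNProteins Size of the corpus protein universe.
#' @return A list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(seed = 1L,
                             nDistractors = 19L,
                             nSamplesPerGroup = 10L,
                             nNullGenes = 20L,
                             plantedGenes = NULL,
                             noiseSdLog = 0.25,
                             baseExpression = 10,
                             nNonTfPartners = 71L,
                             nBackgroundEdges = 100L,
                             nBackgroundProteins = 40L,
                             tfCatalogSize = 1211L,
                             goTermSize = 20L,
                             goPlantedOverlap = 5L,
                             goBackgroundTerms = 40L,
                             goNProteins = 500L) {
  if (is.null(plantedGenes)) {
    med <- exprValues(hoxMedianTable())
    rat <- bneFoldRatios()
    plantedGenes <- data.frame(gene = rownames(med),
                               target_tpm = med[, "Spinal Cord"],
                               fold_ratio = rat$ratio[match(rownames(med),
                                                            rat$gene)],
                               stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "fold_ratio") %in% colnames(plantedGenes)),
            all(plantedGenes$fold_ratio > 0),
            nSamplesPerGroup >= 2L, noiseSdLog >= 0,
            nDistractors >= 0L, tfCatalogSize >= 1L,
            goPlantedOverlap <= goTermSize)
  if (anyDuplicated(normalizeSymbols(plantedGenes$gene)))
    stop("planted gene symbols collide after normalization", call. = FALSE)
  structure(list(seed = as.integer(seed), nDistractors = as.integer(nDistractors),
                 nSamplesPerGroup = as.integer(nSamplesPerGroup),
                 nNullGenes = as.integer(nNullGenes),
                 plantedGenes = plantedGenes, noiseSdLog = noiseSdLog,
                 baseExpression = baseExpression,
                 nNonTfPartners = as.integer(nNonTfPartners),
                 nBackgroundEdges = as.integer(nBackgroundEdges),
                 nBackgroundProteins = as.integer(nBackgroundProteins),
                 tfCatalogSize = as.integer(tfCatalogSize),
                 goTermSize = as.integer(goTermSize),
                 goPlantedOverlap = as.integer(goPlantedOverlap),
                 goBackgroundTerms = as.integer(goBackgroundTerms),
                 goNProteins = as.integer(goNProteins)),
            class = "SimulationConfig")
}

#' Generate a median-expression table with planted region specificity
#'
#' Embeds the worked-example median rows (or the configured planted genes
#' at their `target_tpm`) among `nDistractors` distractor genes whose
#' target-region value is drawn uniformly from [0, 4.9] and whose
#' off-target values are drawn below 1 — i.e. genes that fail the default
#' [regionSpecificFilter()] on the target side while resembling real
#' sub-threshold homeobox genes.
#'
#' @param cfg A [simulationConfig()].
#' @param embedTable If `TRUE` (default) the printed worked-example rows
#'   are embedded verbatim; otherwise planted rows are synthesized from
#'   `cfg$plantedGenes` with off-target values below 1.
#' @return An [ExpressionTable-class] in TPM.
#' @export
genMedianMatrix <- function(cfg, embedTable = TRUE) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  base <- if (embedTable) {
    exprValues(hoxMedianTable())
  } else {
    g <- cfg$plantedGenes
    m <- cbind(`Spinal Cord` = g$target_tpm,
               matrix(stats::runif(nrow(g) * 3, 0, 0.99), nrow(g), 3,
                      dimnames = list(NULL, c("Cerebellum", "Hippocampus",
                                              "Brain Cortex"))))
    rownames(m) <- normalizeSymbols(g$gene)
    m
  }
  if (any(grepl("^DHOX", rownames(base))))
    stop("planted symbols collide with distractor namespace", call. = FALSE)
  nd <- cfg$nDistractors
  if (nd > 0L) {
    d <- cbind(`Spinal Cord` = stats::runif(nd, 0, 4.9),
               matrix(stats::runif(nd * 3, 0, 0.99), nd, 3))
    colnames(d) <- colnames(base)
    rownames(d) <- sprintf("DHOX%02d", seq_len(nd))
    base <- rbind(base, d)
  }
  ExpressionTable(base, unit = "TPM",
                  nSamples = c(159L, 241L, 197L, 255L))
}

#' Generate a two-group per-sample expression matrix with planted folds
#'
#' Emulates the disease-free two-region comparison: `nSamplesPerGroup`
#' spinal-cord (SC) and brain-cortex (BC) samples, each gene log-normal
#' around its group mean with `noiseSdLog` on the natural-log scale.
#' Planted genes have SC/BC group-mean ratio exactly `fold_ratio`; null
#' genes have ratio 1 in both groups.
#'
#' @param cfg A [simulationConfig()].
#' @return An [ExpressionTable-class]; colData `group` is `"SC"` or
#'   `"BC"`.
#' @export
genSampleMatrix <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (cfg$nSamplesPerGroup < 2L)
    stop("need >= 2 samples per group", call. = FALSE)
  set.seed(cfg$seed)
  g <- cfg$plantedGenes
  genes <- c(normalizeSymbols(g$gene),
             if (cfg$nNullGenes > 0L)
               sprintf("NULLG%03d", seq_len(cfg$nNullGenes)))
  fold <- c(g$fold_ratio, rep(1, cfg$nNullGenes))
  n <- cfg$nSamplesPerGroup
  sd <- cfg$noiseSdLog
  # lognormal with mean exactly the group mean: meanlog = log(mu) - sd^2/2
  draw <- function(mu) {
    stats::rlnorm(n, meanlog = log(mu) - sd^2 / 2, sdlog = sd)
  }
  sc <- t(vapply(fold * cfg$baseExpression, draw, numeric(n)))
  bc <- t(vapply(rep(cfg$baseExpression, length(fold)), draw, numeric(n)))
  v <- cbind(sc, bc)
  dimnames(v) <- list(genes, c(sprintf("SC%02d", seq_len(n)),
                               sprintf("BC%02d", seq_len(n))))
  ExpressionTable(v, unit = "TPM",
                  group = rep(c("SC", "BC"), each = n),
                  nSamples = rep(1L, 2L * n))
}

#' Generate an interactome and TF catalog with planted TF partners
#'
#' Plants the worked-example HOX-TF pairs, distributes `nNonTfPartners`
#' non-TF partners over the query proteins (so the first shell of the ten
#' queries holds TF and non-TF partners alike), and adds
#' `nBackgroundEdges` random edges among background proteins touching no
#' query. The returned catalog holds every planted TF plus decoy TF
#' symbols (none adjacent to a query) up to `tfCatalogSize` members.
#'
#' @param cfg A [simulationConfig()].
#' @param plantedPairs data.frame `query`, `partner` of TF edges to plant;
#'   defaults to [hoxTfPartnerEdges()]. Use a zero-row frame for a
#'   TF-free interactome.
#' @return List with elements `net` ([Interactome-class]), `catalog`
#'   ([TFCatalog-class]) and `queries` (the planted query symbols).
#' @export
genInteractome <- function(cfg, plantedPairs = hoxTfPartnerEdges()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  queries <- unique(normalizeSymbols(
    c(hoxQueryGenes(),
      if (nrow(plantedPairs)) plantedPairs$query else character())))
  a <- character(); b <- character()
  if (nrow(plantedPairs)) {
    a <- normalizeSymbols(plantedPairs$query)
    b <- normalizeSymbols(plantedPairs$partner)
  }
  if (cfg$nNonTfPartners > 0L) {
    np <- sprintf("NTP%03d", seq_len(cfg$nNonTfPartners))
    a <- c(a, sample(queries, cfg$nNonTfPartners, replace = TRUE))
    b <- c(b, np)
  }
  if (cfg$nBackgroundEdges > 0L) {
    bg <- sprintf("BGP%04d", seq_len(cfg$nBackgroundProteins))
    cap <- choose(length(bg), 2)
    if (cfg$nBackgroundEdges > cap)
      stop("requested background edges exceed simple-graph capacity",
           call. = FALSE)
    pick <- sample(cap, cfg$nBackgroundEdges)
    idx <- utils::combn(length(bg), 2L)[, pick, drop = FALSE]
    a <- c(a, bg[idx[1L, ]]); b <- c(b, bg[idx[2L, ]])
  }
  net <- Interactome(a = a, b = b,
                     publication = rep("PMID:1", length(a)),
                     system = rep("synthetic", length(a)),
                     sourceTag = sprintf("synthetic(seed=%d)", cfg$seed))
  planted_tfs <- if (nrow(plantedPairs))
    unique(normalizeSymbols(plantedPairs$partner)) else character()
  extra <- unique(normalizeSymbols(gliosisModuleTfs()))
  n_decoy <- cfg$tfCatalogSize - length(union(planted_tfs, extra))
  if (n_decoy < 0L) stop("tfCatalogSize smaller than planted TFs",
                         call. = FALSE)
  catalog <- TFCatalog(c(planted_tfs, setdiff(extra, planted_tfs),
                         sprintf("DTF%04d", seq_len(n_decoy))))
  list(net = net, catalog = catalog, queries = queries)
}

#' Generate a GO annotation corpus with planted antagonistic overlap
#'
#' Builds four focal regulation terms over two pathways (SMAD signalling
#' and androgen-receptor signalling, named after their real GO
#' counterparts): the cross-polarity pairs (positive of one pathway with
#' negative of the other) share exactly `goPlantedOverlap` proteins, the
#' same-polarity cross-pathway pairs share none, and background terms draw
#' their proteins uniformly from the whole universe.
#'
#' @param cfg A [simulationConfig()].
#' @return List with `corpus` ([GOAnnotationCorpus-class]), `pathwayA` and
#'   `pathwayB` (named term-id pairs `c(pos=, neg=)` for
#'   [antagonismScreen()]).
#' @export
genGoCorpus <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (cfg$goPlantedOverlap > cfg$goTermSize)
    stop("planted overlap exceeds term size", call. = FALSE)
  set.seed(cfg$seed)
  ts <- cfg$goTermSize; ov <- cfg$goPlantedOverlap
  own <- ts - ov
  need <- 4L * own + 2L * ov
  if (cfg$goNProteins < need)
    stop("goNProteins too small for four disjoint focal terms",
         call. = FALSE)
  prot <- sprintf("P%05d", seq_len(cfg$goNProteins))
  pool <- sample(prot, need)   # focal proteins, mutually disjoint blocks
  take <- function(k) {
    if (k == 0L) return(character())
    out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out
  }
  ov1 <- take(ov)  # shared by posA and negB
  ov2 <- take(ov)  # shared by negA and posB
  terms <- list(
    "GO:0060391" = c(take(own), ov1),
    "GO:0060392" = c(take(own), ov2),
    "GO:2000825" = c(take(own), ov2),
    "GO:0060766" = c(take(own), ov1))
  for (i in seq_len(cfg$goBackgroundTerms)) {
    terms[[sprintf("GO:9%06d", i)]] <- sample(prot, ts)
  }
  nms <- c("GO:0060391" = "Positive regulation of SMAD protein signal transduction",
           "GO:0060392" = "Negative regulation of SMAD protein signal transduction",
           "GO:2000825" = "Positive regulation of androgen receptor activity",
           "GO:0060766" = "Negative regulation of androgen receptor signaling pathway")
  bg <- setdiff(names(terms), names(nms))
  nms <- c(nms, stats::setNames(paste("background process", seq_along(bg)), bg))
  list(corpus = GOAnnotationCorpus(terms, termNames = nms,
                                   nProteins = cfg$goNProteins),
       pathwayA = c(pos = "GO:0060391", neg = "GO:0060392"),
       pathwayB = c(pos = "GO:2000825", neg = "GO:0060766"))
}

#' Write a GOAnnotationCorpus as GAF 2.1
#'
#' One row per (protein, term) annotation, 17 tab-separated columns with a
#' `!gaf-version: 2.1` header; the protein id fills both the DB object id
#' and symbol columns. Term names are not part of GAF and must be carried
#' separately.
#'
#' @param corpus A [GOAnnotationCorpus-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGaf <- function(corpus, path) {
  stopifnot(is(corpus, "GOAnnotationCorpus"))
  rows <- unlist(lapply(termIds(corpus), function(tid) {
    vapply(corpus@terms[[tid]], function(p) {
      paste(c("SYNDB", p, p, "", tid, "GO_REF:0000000", "IEA", "", "P",
              "", "", "protein", "taxon:9606", "20190101", "SYNDB", "",
              ""), collapse = "\t")
    }, character(1))
  }), use.names = FALSE)
  writeLines(c("!gaf-version: 2.1", rows), path, useBytes = TRUE)
  invisible(path)
}
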