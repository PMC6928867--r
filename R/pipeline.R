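#' Run the full inference pipeline
#'
#' Executes the analysis end to end from one configuration: signature
#' crossing, annotation-library over-representation, candidate restriction
#' to one annotation term, region-specificity filtering of a median table,
#' Welch differential-expression confirmation on a per-sample table,
#' first-shell interactor extraction and TF crossing, module
#' over-representation and second-shell module links, the GO co-occurrence
#' antagonism screen, and typed-network assembly. Every stage writes its
#' output under `outDir` and is recorded (with an MD5 checksum) in a run
#' manifest, so a rerun with an identical configuration reproduces
#' identical hashes and individual stages can be re-executed against the
#' retained intermediates. A stage failure aborts with the stage name and
#' cause; outputs of completed stages are kept.
#'
#' @param config A list (or path to a JSON file) with elements:
#' \describe{
#'   \item{signaturesGmt, signatureA, signatureB}{GMT path and the two set
#'     names to cross (A is the target tissue).}
#'   \item{annotationGmt}{GMT of term -> gene annotation sets used for both
#'     the over-representation stage and candidate restriction.}
#'   \item{annotationTerm}{Term whose members define the candidate family
#'     (e.g. a homeobox-domain set).}
#'   \item{mediansTsv}{Median expression TSV (regions as columns).}
#'   \item{targetRegion, minTarget, maxOther}{Region filter settings
#'     (defaults 5 and 1).}
#'   \item{samplesTsv, sampleGroups}{Per-sample TSV and a two/three-column
#'     TSV `label, group[, specimen]` assigning columns to arms (and
#'     optionally technical replicates to one specimen).}
#'   \item{group1, group2}{The two arm tags to compare (default SC, BC).}
#'   \item{interactomeTsv, tfCatalog}{Interaction edge list and TF catalog
#'     paths.}
#'   \item{moduleFile}{Plain list of module gene symbols.}
#'   \item{gaf, pairA, pairB}{GAF path and the two `c(pos=, neg=)` term-id
#'     pairs for the antagonism screen.}
#'   \item{repressionTsv, predictedTsv}{Optional `source, target[,
#'     provenance]` TSVs for the repression and predicted-binding layers.}
#'   \item{outDir}{Output directory (created).}
#'   \item{seed}{Recorded in the manifest.}
#' }
#' @param stages Integer subset of 1:9 to execute (default all, in
#'   order). Later stages read the on-disk outputs of earlier ones, so a
#'   prefix must have run before a suffix is resumed.
#' @return The run manifest (a list), invisibly; also written as
#'   `manifest.json` under `outDir`.
#' @export
runPipeline <- function(config, stages = 1:9) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- config
  defaults <- list(minTarget = 5, maxOther = 1, targetRegion = "Spinal Cord",
                   group1 = "SC", group2 = "BC", alpha = 0.05, seed = NA)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  path_keys <- c("signaturesGmt", "annotationGmt", "mediansTsv",
                 "samplesTsv", "sampleGroups", "interactomeTsv",
                 "tfCatalog", "moduleFile", "gaf", "repressionTsv",
                 "predictedTsv")
  for (k in intersect(path_keys, names(cfg))) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop("pipeline: missing input file for '", k, "': ", cfg[[k]],
           call. = FALSE)
  }
  if (is.null(cfg$outDir)) stop("config$outDir is required", call. = FALSE)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outDir, f)
  manifest <- list(package = "cordhox",
                   version = as.character(utils::packageVersion("cordhox")),
                   seed = cfg$seed,
                   thresholds = list(minTarget = cfg$minTarget,
                                     maxOther = cfg$maxOther,
                                     alpha = cfg$alpha),
                   stages = list())
  record <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      outputs = files,
      md5 = as.list(unname(tools::md5sum(files))))
  }
  run_stage <- function(id, name, fn) {
    if (!id %in% stages) return(invisible(NULL))
    message(sprintf("[stage %d:%s] running", id, name))
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage %d (%s) failed: %s", id, name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  run_stage(1L, "cross-signatures", function() {
    sig <- readGmt(cfg$signaturesGmt)
    cross <- crossSignatures(geneSets(sig)[[cfg$signatureA]],
                             geneSets(sig)[[cfg$signatureB]],
                             cfg$signatureA, cfg$signatureB)
    jsonlite::write_json(cross[c("aSpecific", "bSpecific", "shared",
                                 "aName", "bName")],
                         out("cross.json"), auto_unbox = TRUE, pretty = TRUE)
    record("cross_signatures", out("cross.json"))
  })

  run_stage(2L, "enrichment", function() {
    cross <- jsonlite::read_json(out("cross.json"), simplifyVector = TRUE)
    lib <- readGmt(cfg$annotationGmt)
    universe <- unique(c(unlist(geneSets(lib), use.names = FALSE),
                         cross$aSpecific, cross$bSpecific, cross$shared))
    enr <- suppressWarnings(
      overrepresentation(cross$aSpecific, lib, universe, method = "BH"))
    utils::write.table(enr, out("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("enrichment", out("enrichment.tsv"))
  })

  run_stage(3L, "candidates", function() {
    cross <- jsonlite::read_json(out("cross.json"), simplifyVector = TRUE)
    lib <- readGmt(cfg$annotationGmt)
    cand <- annotateMembership(cross$aSpecific, lib, cfg$annotationTerm)
    writeLines(cand, out("candidates.txt"))
    record("candidates", out("candidates.txt"))
  })

  run_stage(4L, "region-filter", function() {
    med <- readExpressionTsv(cfg$mediansTsv, unit = "TPM")
    cand <- readLines(out("candidates.txt"))
    keep <- intersect(rownames(exprValues(med)), cand)
    if (length(keep)) med <- med[keep, ]
    genes <- regionSpecificFilter(med, cfg$targetRegion,
                                  minTarget = cfg$minTarget,
                                  maxOther = cfg$maxOther)
    writeLines(genes, out("region_genes.txt"))
    record("region_filter", out("region_genes.txt"))
  })

  run_stage(5L, "diffexp", function() {
    grp <- utils::read.delim(cfg$sampleGroups, header = TRUE,
                             colClasses = "character")
    samp <- readExpressionTsv(cfg$samplesTsv, unit = "TPM")
    labels <- SummarizedExperiment::colData(samp)$label
    groups <- grp$group[match(labels, grp$label)]
    if (anyNA(groups))
      stop("sampleGroups does not cover all sample columns")
    repmap <- if ("specimen" %in% colnames(grp))
      grp$specimen[match(labels, grp$label)] else NULL
    de <- welchDe(samp, cfg$group1, cfg$group2, groups = groups,
                  replicateMap = repmap, correction = "bonferroni")
    utils::write.table(de, out("diffexp.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("diffexp", out("diffexp.tsv"))
  })

  run_stage(6L, "tf-partners", function() {
    net <- readInteractome(cfg$interactomeTsv)
    catalog <- readTfCatalog(cfg$tfCatalog)
    queries <- readLines(out("region_genes.txt"))
    shell <- suppressWarnings(firstShell(queries, net))
    tfp <- crossWithTfs(shell, catalog)
    utils::write.table(tfp$rows, out("tf_partners.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("tf_partners", out("tf_partners.tsv"))
  })

  run_stage(7L, "module-enrichment", function() {
    net <- readInteractome(cfg$interactomeTsv)
    catalog <- readTfCatalog(cfg$tfCatalog)
    module <- normalizeSymbols(readLines(cfg$moduleFile))
    rows <- utils::read.delim(out("tf_partners.tsv"),
                              colClasses = "character")
    enr <- do.call(rbind, lapply(unique(rows$query),
      function(q) {
        p <- unique(rows$partner[rows$query == q])
        r <- suppressWarnings(
          moduleEnrichment(p, intersect(module, members(catalog)), catalog))
        cbind(query = q, r)
      }))
    utils::write.table(enr, out("module_enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    overlap_tfs <- unique(unlist(strsplit(enr$overlap[nzchar(enr$overlap)],
                                          ",")))
    links <- secondShellTfLinks(overlap_tfs, net, module)
    utils::write.table(links, out("second_shell.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("module_enrichment",
           c(out("module_enrichment.tsv"), out("second_shell.tsv")))
  })

  run_stage(8L, "antagonism", function() {
    corpus <- readGaf(cfg$gaf)
    scr <- antagonismScreen(corpus,
                            pathwayA = unlist(cfg$pairA),
                            pathwayB = unlist(cfg$pairB))
    jsonlite::write_json(list(verdict = scr$verdict, pairs = scr$pairs),
                         out("antagonism.json"), auto_unbox = TRUE,
                         pretty = TRUE, na = "null")
    record("antagonism", out("antagonism.json"))
  })

  run_stage(9L, "network", function() {
    rows <- utils::read.delim(out("tf_partners.tsv"),
                              colClasses = "character")
    physical <- data.frame(source = rows$query, target = rows$partner,
                           provenance = "first-shell PPI",
                           stringsAsFactors = FALSE)
    if (file.exists(out("second_shell.tsv"))) {
      ss <- utils::read.delim(out("second_shell.tsv"),
                              colClasses = "character")
      if (nrow(ss))
        physical <- rbind(physical,
                          data.frame(source = ss$tf,
                                     target = ss$module_partner,
                                     provenance = "second-shell PPI",
                                     stringsAsFactors = FALSE))
    }
    readLayer <- function(p) {
      if (is.null(p)) return(NULL)
      utils::read.delim(p, colClasses = "character")
    }
    net <- assembleNetwork(physical = physical,
                           repression = readLayer(cfg$repressionTsv),
                           predicted = readLayer(cfg$predictedTsv))
    exportNetwork(net, out("network.graphml"), "graphml")
    exportNetwork(net, out("network.sif"), "sif")
    record("network", c(out("network.graphml"), out("network.sif")))
  })

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(manifest)
}
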