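# Build a complete on-disk input set + config for runPipeline() in `dir`.
writePipelineInputs <- function(dir, seed = 101L) {
  cfg <- simulationConfig(seed = seed)
  med <- genMedianMatrix(cfg)
  hox29 <- rownames(exprValues(med))
  scOnly <- sprintf("SCONLY%d", 1:5)
  shared <- sprintf("SHARED%d", 1:3)
  brainOnly <- sprintf("BRAING%02d", 1:10)

  sig <- GeneSetLibrary(list(SC = c(hox29, scOnly, shared),
                             Brain = c(brainOnly, shared)))
  writeGmt(sig, file.path(dir, "signatures.gmt"))
  ann <- GeneSetLibrary(list(HOMEOBOX = hox29,
                             OTHERFAM = c(brainOnly, scOnly)))
  writeGmt(ann, file.path(dir, "annotation.gmt"))
  writeExpressionTsv(med, file.path(dir, "medians.tsv"))

  sm <- genSampleMatrix(cfg)
  writeExpressionTsv(sm, file.path(dir, "samples.tsv"))
  cd <- SummarizedExperiment::colData(sm)
  utils::write.table(data.frame(label = cd$label, group = cd$group),
                     file.path(dir, "sample_groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  gi <- genInteractome(cfg)
  writeInteractome(gi$net, file.path(dir, "interactome.tsv"))
  writeTfCatalog(gi$catalog, file.path(dir, "tf_catalog.txt"))
  writeLines(gliosisModuleTfs(), file.path(dir, "module.txt"))

  gg <- genGoCorpus(cfg)
  writeGaf(gg$corpus, file.path(dir, "goa.gaf"))

  ly <- hoxTgfbArLayers()
  utils::write.table(ly$repression, file.path(dir, "repression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ly$predicted, file.path(dir, "predicted.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  list(signaturesGmt = file.path(dir, "signatures.gmt"),
       signatureA = "SC", signatureB = "Brain",
       annotationGmt = file.path(dir, "annotation.gmt"),
       annotationTerm = "HOMEOBOX",
       mediansTsv = file.path(dir, "medians.tsv"),
       targetRegion = "Spinal Cord",
       samplesTsv = file.path(dir, "samples.tsv"),
       sampleGroups = file.path(dir, "sample_groups.tsv"),
       group1 = "SC", group2 = "BC",
       interactomeTsv = file.path(dir, "interactome.tsv"),
       tfCatalog = file.path(dir, "tf_catalog.txt"),
       moduleFile = file.path(dir, "module.txt"),
       gaf = file.path(dir, "goa.gaf"),
       pairA = list(pos = "GO:0060391", neg = "GO:0060392"),
       pairB = list(pos = "GO:2000825", neg = "GO:0060766"),
       repressionTsv = file.path(dir, "repression.tsv"),
       predictedTsv = file.path(dir, "predicted.tsv"),
       outDir = file.path(dir, "out"),
       seed = seed)
}
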