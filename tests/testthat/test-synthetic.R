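test_that("generators are pure functions of (config, seed)", {
  cfg <- simulationConfig(seed = 33)
  expect_identical(exprValues(genMedianMatrix(cfg)),
                   exprValues(genMedianMatrix(cfg)))
  expect_identical(exprValues(genSampleMatrix(cfg)),
                   exprValues(genSampleMatrix(cfg)))
  expect_identical(edges(genInteractome(cfg)$net),
                   edges(genInteractome(cfg)$net))
  expect_identical(genGoCorpus(cfg)$corpus@terms,
                   genGoCorpus(cfg)$corpus@terms)
  # a different seed changes the stochastic parts
  cfg2 <- simulationConfig(seed = 34)
  expect_false(identical(exprValues(genSampleMatrix(cfg)),
                         exprValues(genSampleMatrix(cfg2))))
  # written files are byte-identical under one seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeExpressionTsv(genMedianMatrix(cfg), f1)
  writeExpressionTsv(genMedianMatrix(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("median generator plants pass/fail structure around the filter", {
  cfg <- simulationConfig(seed = 35)
  med <- genMedianMatrix(cfg)
  v <- exprValues(med)
  expect_identical(nrow(v), 29L)  # 10 planted + 19 distractors
  d <- v[grepl("^DHOX", rownames(v)), ]
  expect_true(all(d[, "Spinal Cord"] < 5))
  expect_true(all(d[, -1] < 1))
  # zero planted genes: the filter returns nothing
  none <- genMedianMatrix(simulationConfig(seed = 36,
                                           plantedGenes = data.frame(
                                             gene = "OFFG1",
                                             target_tpm = 0.5,
                                             fold_ratio = 1)),
                          embedTable = FALSE)
  expect_length(regionSpecificFilter(none, "Spinal Cord"), 0)
})

test_that("sample generator hits planted fold ratios exactly at zero noise", {
  cfg <- simulationConfig(seed = 37, noiseSdLog = 0)
  sm <- genSampleMatrix(cfg)
  de <- welchDe(sm, "SC", "BC")
  planted <- bneFoldRatios()
  got <- de$ratio[match(planted$gene, de$gene)]
  expect_equal(got, planted$ratio, tolerance = 1e-12)
  expect_error(genSampleMatrix(simulationConfig(seed = 1,
                                                nSamplesPerGroup = 2L)),
               NA)
})

test_that("null genes are calibrated: raw p roughly uniform over seeds", {
  ps <- vapply(1:60, function(s) {
    cfg <- simulationConfig(seed = 700 + s, nNullGenes = 1L)
    sm <- genSampleMatrix(cfg)
    de <- welchDe(sm, "SC", "BC")
    de$p_raw[de$gene == "NULLG001"]
  }, numeric(1))
  expect_gt(median(ps), 0.25)
  expect_lt(median(ps), 0.75)
  expect_gt(min(ps), 0)
})

test_that("interactome generator plants recoverable TF structure", {
  cfg <- simulationConfig(seed = 38)
  gi <- genInteractome(cfg)
  expect_identical(totalCount(gi$catalog), 1211L)
  sh <- suppressWarnings(firstShell(gi$queries, gi$net))
  tf <- crossWithTfs(sh, gi$catalog)
  expect_setequal(tf$partners, unique(hoxTfPartnerEdges()$partner))
  # zero planted pairs: TF crossing comes back empty
  gi0 <- genInteractome(cfg, plantedPairs = hoxTfPartnerEdges()[0, ])
  sh0 <- suppressWarnings(firstShell(gi0$queries, gi0$net))
  expect_length(crossWithTfs(sh0, gi0$catalog)$partners, 0)
  # capacity guard
  expect_error(genInteractome(simulationConfig(seed = 1,
                                               nBackgroundEdges = 10000L)),
               "capacity")
})

test_that("GO generator plants exact overlap arithmetic", {
  cfg <- simulationConfig(seed = 39)
  gg <- genGoCorpus(cfg)
  a <- termProteins(gg$corpus, gg$pathwayA["pos"])
  b <- termProteins(gg$corpus, gg$pathwayB["neg"])
  expect_length(intersect(a, b), 5)
  expect_length(intersect(a, termProteins(gg$corpus, gg$pathwayB["pos"])), 0)
  co <- cooccurringTerms(gg$corpus, unname(gg$pathwayA["pos"]))
  hit <- co[co$term_b == gg$pathwayB["neg"], ]
  expect_equal(hit$similarity, 100 * 5 / (20 + 20 - 5))
  expect_error(genGoCorpus(simulationConfig(seed = 1, goTermSize = 4L,
                                            goPlantedOverlap = 5L)),
               "[Oo]verlap")
})

test_that("generated files re-ingest cleanly through the readers", {
  cfg <- simulationConfig(seed = 40)
  d <- withr::local_tempdir()
  writeExpressionTsv(genMedianMatrix(cfg), file.path(d, "med.tsv"))
  expect_no_warning(readExpressionTsv(file.path(d, "med.tsv"), "TPM"))
  gi <- genInteractome(cfg)
  writeInteractome(gi$net, file.path(d, "net.tsv"))
  expect_no_warning(back <- readInteractome(file.path(d, "net.tsv")))
  expect_identical(nrow(edges(back)), nrow(edges(gi$net)))
  writeTfCatalog(gi$catalog, file.path(d, "tf.txt"))
  expect_no_warning(readTfCatalog(file.path(d, "tf.txt")))
  gg <- genGoCorpus(cfg)
  writeGaf(gg$corpus, file.path(d, "goa.gaf"))
  expect_no_warning(readGaf(file.path(d, "goa.gaf")))
})
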