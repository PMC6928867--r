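test_that("co-occurrence statistics follow their definitions", {
  corpus <- GOAnnotationCorpus(
    list("GO:1" = sprintf("P%d", 1:5),
         "GO:2" = c("P1", "P2", "P3", "P9"),
         "GO:3" = sprintf("P%d", 1:5)),
    nProteins = 100L)
  co <- cooccurringTerms(corpus, "GO:1")
  # identical annotation set ranks first with similarity 100
  expect_identical(co$term_b[1], "GO:3")
  expect_equal(co$similarity[1], 100)
  r2 <- co[co$term_b == "GO:2", ]
  expect_equal(r2$similarity, 100 * 3 / 6)            # c_ab=3, union 6
  expect_equal(r2$prob_ratio, (3 / 4) / (5 / 100))    # = 15
  expect_identical(co$rank, 1:2)
  expect_error(cooccurringTerms(corpus, "GO:9"), "unknown term")
})

test_that("similarity is symmetric and 100 iff sets coincide", {
  set.seed(410)
  pool <- sprintf("P%03d", 1:60)
  terms <- lapply(1:8, function(i) sample(pool, sample(3:20, 1)))
  names(terms) <- sprintf("GO:%d", 1:8)
  corpus <- GOAnnotationCorpus(terms, nProteins = 60L)
  for (a in names(terms)) {
    ca <- cooccurringTerms(corpus, a)
    for (j in seq_len(nrow(ca))) {
      b <- ca$term_b[j]
      cb <- cooccurringTerms(corpus, b)
      expect_equal(ca$similarity[j], cb$similarity[cb$term_b == a])
      expect_identical(ca$similarity[j] == 100,
                       setequal(terms[[a]], terms[[b]]))
    }
  }
})

test_that("ranks are gapless and shift by one when the top term is removed", {
  set.seed(411)
  pool <- sprintf("P%03d", 1:40)
  terms <- lapply(1:10, function(i) sample(pool, 10))
  names(terms) <- sprintf("GO:%d", 1:10)
  corpus <- GOAnnotationCorpus(terms, nProteins = 40L)
  co <- cooccurringTerms(corpus, "GO:1")
  expect_identical(co$rank, seq_len(nrow(co)))
  top <- co$term_b[1]
  corpus2 <- GOAnnotationCorpus(terms[setdiff(names(terms), top)],
                                nProteins = 40L)
  co2 <- cooccurringTerms(corpus2, "GO:1")
  expect_identical(co2$term_b, co$term_b[-1])
  expect_identical(co2$rank, co$rank[-1] - 1L)
})

test_that("polarity parsing strips regulation prefixes case-insensitively", {
  p <- parsePolarity("Positive regulation of SMAD protein signal transduction")
  expect_identical(p$direction, "positive")
  expect_identical(p$concept, "SMAD protein signal transduction")
  expect_identical(parsePolarity("NEGATIVE REGULATION OF X")$direction,
                   "negative")
  expect_identical(parsePolarity("NEGATIVE REGULATION OF X")$concept, "X")
  n <- parsePolarity("signal transduction")
  expect_identical(n$direction, "none")
  expect_identical(n$concept, "signal transduction")
})

test_that("antagonism screen recovers planted cross-polarity structure", {
  gg <- genGoCorpus(simulationConfig(seed = 21))
  scr <- antagonismScreen(gg$corpus, gg$pathwayA, gg$pathwayB)
  expect_identical(scr$verdict, "antagonism-only")
  hit <- scr$pairs[scr$pairs$overlap, ]
  expect_true(all(hit$classification == "antagonistic"))
  expect_identical(nrow(hit), 2L)  # pos-A/neg-B and neg-A/pos-B
  # planted similarity: 100 * ov / (c_a + c_b - ov) with 20-protein terms
  expect_equal(hit$similarity, rep(100 * 5 / 35, 2))
  expect_true(all(hit$rank_b_in_a >= 1))
})

test_that("screen reports vacuous and mixed structures faithfully", {
  none <- genGoCorpus(simulationConfig(seed = 22, goPlantedOverlap = 0L))
  expect_identical(antagonismScreen(none$corpus, none$pathwayA,
                                    none$pathwayB)$verdict, "vacuous")
  # an agonistic overlap flips the verdict to mixed
  terms <- list(pa = c("P1", "P2", "P3"), na = c("P4", "P5"),
                pb = c("P1", "P6"), nb = c("P7", "P2"))
  corpus <- GOAnnotationCorpus(terms, nProteins = 10L)
  scr <- antagonismScreen(corpus, c(pos = "pa", neg = "na"),
                          c(pos = "pb", neg = "nb"))
  expect_identical(scr$verdict, "mixed")
  # pathway with both terms absent errors; one absent term is tolerated
  expect_error(antagonismScreen(corpus, c(pos = "zz", neg = "zz2"),
                                c(pos = "pb", neg = "nb")), "absent")
  part <- antagonismScreen(corpus, c(pos = "pa", neg = "zz"),
                           c(pos = "pb", neg = "nb"))
  expect_true(all(!part$pairs$overlap[part$pairs$polarity_a == "neg"]))
})

test_that("GAF round-trip preserves term annotation sets", {
  gg <- genGoCorpus(simulationConfig(seed = 23))
  f <- withr::local_tempfile(fileext = ".gaf")
  writeGaf(gg$corpus, f)
  back <- readGaf(f)
  expect_setequal(termIds(back), termIds(gg$corpus))
  for (tid in termIds(gg$corpus))
    expect_setequal(termProteins(back, tid), termProteins(gg$corpus, tid))
})

test_that("GAF reader drops NOT qualifiers and honors evidence filters", {
  f <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c(
    "!gaf-version: 2.1",
    paste(c("DB", "P1", "P1", "", "GO:1", "REF", "IDA", "", "P",
            rep("", 8)), collapse = "\t"),
    paste(c("DB", "P2", "P2", "NOT", "GO:1", "REF", "IDA", "", "P",
            rep("", 8)), collapse = "\t"),
    paste(c("DB", "P3", "P3", "NOT|contributes_to", "GO:1", "REF", "IEA",
            "", "P", rep("", 8)), collapse = "\t"),
    paste(c("DB", "P4", "P4", "", "GO:1", "REF", "IEA", "", "P",
            rep("", 8)), collapse = "\t")), f)
  corpus <- readGaf(f)
  expect_setequal(termProteins(corpus, "GO:1"), c("P1", "P4"))
  ida <- readGaf(f, evidenceKeep = "IDA")
  expect_setequal(termProteins(ida, "GO:1"), "P1")
})

test_that("OBO propagation copies annotations to is_a ancestors", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", "[Term]", "id: GO:ROOT",
               "name: root process", "", "[Term]", "id: GO:MID",
               "name: mid process", "is_a: GO:ROOT ! root", "",
               "[Term]", "id: GO:LEAF", "name: leaf process",
               "is_a: GO:MID ! mid"), obo)
  gaf <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1",
               paste(c("DB", "P1", "P1", "", "GO:LEAF", "REF", "IDA", "",
                       "P", rep("", 8)), collapse = "\t")), gaf)
  flat <- readGaf(gaf)
  expect_identical(termIds(flat), "GO:LEAF")
  prop <- readGaf(gaf, obo = obo, propagate = TRUE)
  expect_setequal(termIds(prop), c("GO:LEAF", "GO:MID", "GO:ROOT"))
  expect_identical(termProteins(prop, "GO:ROOT"), "P1")
  expect_identical(termName(prop, "GO:MID"), "mid process")
  expect_error(readGaf(gaf, propagate = TRUE), "requires an obo")
})
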