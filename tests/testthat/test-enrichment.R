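test_that("hypergeometric tail matches enumeration and choose-sum oracles", {
  # tiny universe: every draw enumerated
  expect_equal(hypergeomTail(10, 5, 4, 2), enumTail(10, 5, 4, 2))
  expect_equal(hypergeomTail(10, 5, 4, 2), 155 / 210, tolerance = 1e-14)
  set.seed(403)
  for (i in 1:20) {
    N <- sample(4:12, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeomTail(N, K, n, k), enumTail(N, K, n, k),
                 tolerance = 1e-12)
  }
  # larger: exact binomial-coefficient arithmetic
  for (i in 1:50) {
    N <- sample(13:30, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeomTail(N, K, n, k), chooseSumTail(N, K, n, k),
                 tolerance = 1e-12)
  }
})

test_that("hypergeometric tail agrees with stats::phyper at scale", {
  for (case in list(c(1211, 12, 7, 2), c(20000, 150, 869, 30),
                    c(1211, 12, 14, 2))) {
    expect_equal(hypergeomTail(case[1], case[2], case[3], case[4]),
                 phyper(case[4] - 1, case[2], case[1] - case[2], case[3],
                        lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("hypergeometric tail handles edge cases and rejects bad bounds", {
  expect_identical(hypergeomTail(100, 10, 5, 0), 1)
  expect_equal(hypergeomTail(10, 10, 3, 3), 1)     # all marked
  expect_error(hypergeomTail(10, 11, 3, 1), "exceed N")
  expect_error(hypergeomTail(10, 5, 3, 4), "min\\(n, K\\)")
  expect_error(hypergeomTail(10, 5, 3, -1), "non-negative")
})

test_that("BH adjustment follows the step-up rule and its invariances", {
  expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustBH(0.07), 0.07)
  expect_equal(adjustBH(rep(0.2, 5)), rep(0.2, 5))
  set.seed(404)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1), min = 1e-6)
    q <- adjustBH(p)
    expect_true(all(q >= p))            # never below raw
    expect_true(all(q <= 1))
    perm <- sample(seq_along(p))
    expect_equal(adjustBH(p[perm]), q[perm])  # permutation-equivariant
  }
  expect_error(adjustBH(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(adjustBH(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("Bonferroni multiplies by m and caps at 1", {
  expect_equal(adjustBonferroni(rep(0.01, 10)), rep(0.1, 10))
  expect_equal(adjustBonferroni(c(0.2, rep(0.5, 9))),
               c(1, rep(1, 9)))
  expect_equal(adjustBonferroni(0.3), 0.3)
})

test_that("over-representation rows carry exact counts, fold and p", {
  lib <- GeneSetLibrary(list(HOMEOBOX = c("G1", "G2", "G3", "G4"),
                             EMPTYISH = c("X1", "X2")))
  universe <- sprintf("G%d", 1:96)  # X1, X2 outside -> term dropped
  universe <- c(universe, "X9", "X8", "X7", "X6")
  res <- overrepresentation(c("G1", "G2"), lib, universe)
  expect_identical(nrow(res), 1L)
  expect_identical(res$term, "HOMEOBOX")
  expect_identical(c(res$k, res$n, res$K, res$N), c(2L, 2L, 4L, 100L))
  expect_equal(res$p_raw, 6 / 4950, tolerance = 1e-12)
  expect_equal(res$p_adj, res$p_raw)  # single emitted term
  expect_equal(res$fold, (2 / 2) / (4 / 100))
})

test_that("over-representation drops outside genes with a warning", {
  lib <- GeneSetLibrary(list(S = c("G1", "G2")))
  expect_warning(res <- overrepresentation(c("G1", "NOTHERE"), lib,
                                           sprintf("G%d", 1:10)),
                 "outside the universe")
  expect_identical(res$n, 1L)
  expect_error(suppressWarnings(
    overrepresentation("NOTHERE", lib, sprintf("G%d", 1:10))),
    "no query genes")
})

test_that("disjoint terms get k = 0, fold 0, p 1", {
  lib <- GeneSetLibrary(list(S = c("G9", "G10")))
  res <- overrepresentation(c("G1", "G2"), lib, sprintf("G%d", 1:10))
  expect_identical(res$k, 0L)
  expect_identical(res$fold, 0)
  expect_identical(res$p_raw, 1)
})

test_that("fold is scale-free and zero iff the overlap is zero", {
  lib <- GeneSetLibrary(list(S = sprintf("G%d", 1:4)))
  u1 <- sprintf("G%d", 1:100)
  r1 <- overrepresentation(c("G1", "G2"), lib, u1)
  # double N and K: same fold
  lib2 <- GeneSetLibrary(list(S = c(sprintf("G%d", 1:4),
                                    sprintf("H%d", 1:4))))
  u2 <- c(u1, sprintf("H%d", 1:100))
  r2 <- overrepresentation(c("G1", "G2"), lib2, u2)
  expect_equal(r1$fold, r2$fold)
})

test_that("module enrichment reproduces the worked TF-partner example", {
  gi <- genInteractome(simulationConfig(seed = 11))
  tab <- hoxTfPartnerEdges()
  partners7 <- tab$partner[tab$query == "HOXA5"]
  expect_length(partners7, 7)
  row <- moduleEnrichment(partners7, gliosisModuleTfs(), gi$catalog)
  expect_identical(c(row$k, row$n, row$K, row$N), c(2L, 7L, 12L, 1211L))
  expect_identical(row$overlap, "SMAD1,SOX2")
  expect_equal(row$p_raw, 0.0018401722, tolerance = 1e-6)
  expect_equal(row$fold, (2 / 7) / (12 / 1211), tolerance = 1e-12)

  # disjoint module: p = 1
  d <- moduleEnrichment("DDIT3", sprintf("DTF%04d", 1:12), gi$catalog)
  expect_identical(d$p_raw, 1)
  # partners = module: verified against enumeration at small N
  cat30 <- TFCatalog(sprintf("T%02d", 1:30))
  full <- moduleEnrichment(sprintf("T%02d", 1:5), sprintf("T%02d", 1:5),
                           cat30)
  expect_equal(full$p_raw, enumTail(30, 5, 5, 5), tolerance = 1e-12)
})
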