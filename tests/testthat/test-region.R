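test_that("region filter keeps all worked-example genes at defaults", {
  got <- regionSpecificFilter(hoxMedianTable(), "Spinal Cord")
  expect_identical(got, hoxQueryGenes())
})

test_that("region filter excludes threshold violations on either side", {
  v <- rbind(LOWTGT  = c(4.9, 0.1, 0.1),
             HIGHOFF = c(10.0, 2.0, 0.1),
             PASS    = c(5.0, 0.99, 0.0))
  colnames(v) <- c("Spinal Cord", "Brain Cortex", "Cerebellum")
  x <- ExpressionTable(v, unit = "TPM")
  expect_identical(regionSpecificFilter(x, "Spinal Cord"), "PASS")
  expect_error(regionSpecificFilter(x, "Thalamus"), "target column")
  expect_error(regionSpecificFilter(x, "Spinal Cord", minTarget = 1,
                                    maxOther = 2), "minTarget > maxOther")
})

test_that("region filter is monotone in both thresholds", {
  set.seed(405)
  v <- matrix(runif(40 * 4, 0, 10), 40, 4,
              dimnames = list(sprintf("G%02d", 1:40),
                              c("Spinal Cord", "A", "B", "C")))
  x <- ExpressionTable(v, unit = "TPM")
  base <- regionSpecificFilter(x, "Spinal Cord", minTarget = 4,
                               maxOther = 3)
  expect_true(all(regionSpecificFilter(x, "Spinal Cord", 6, 3) %in% base))
  expect_true(all(regionSpecificFilter(x, "Spinal Cord", 4, 1) %in% base))
})

test_that("filter recovers exactly the planted genes among distractors", {
  med <- genMedianMatrix(simulationConfig(seed = 19, nDistractors = 19L))
  expect_identical(regionSpecificFilter(med, "Spinal Cord"),
                   hoxQueryGenes())
})

test_that("low-expression check classifies cells and summarizes", {
  v <- rbind(G1 = c(0.1, 0.1), G2 = c(0.1, 5.0))
  colnames(v) <- c("astro", "oligo")
  x <- ExpressionTable(v, unit = "FPKM")
  chk <- lowExpressionCheck(x, threshold = 0.1)
  expect_identical(unname(chk$flags[1, ]), c("at", "at"))
  expect_identical(chk$flags["G2", "oligo"], "above")
  expect_equal(chk$summary, 0.75)  # 3 of 4 cells at detection level

  m2 <- rbind(G = c(0.1, 0.1)); colnames(m2) <- c("astro", "oligo")
  all_at <- lowExpressionCheck(ExpressionTable(m2, unit = "FPKM"), 0.1)
  expect_equal(all_at$summary, 1)
})

test_that("Welch test reproduces the closed-form example", {
  m <- rbind(GENE = c(10, 12, 14, 1, 2, 3))
  colnames(m) <- sprintf("s%d", 1:6)
  de <- welchDe(m, "g1", "g2", groups = rep(c("g1", "g2"), each = 3))
  expect_equal(de$t_stat, 7.745967, tolerance = 1e-6)
  expect_equal(de$df, 2.941176, tolerance = 1e-6)
  expect_equal(de$ratio, 6)
  # against the independent base implementation
  tt <- t.test(m[1, 1:3], m[1, 4:6])
  expect_equal(de$t_stat, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(de$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(de$p_raw, tt$p.value, tolerance = 1e-12)
})

test_that("Welch test is antisymmetric and handles degenerate groups", {
  set.seed(406)
  m <- matrix(rlnorm(5 * 8), 5, 8,
              dimnames = list(sprintf("G%d", 1:5), sprintf("s%d", 1:8)))
  grp <- rep(c("A", "B"), each = 4)
  ab <- welchDe(m, "A", "B", groups = grp)
  ba <- welchDe(m, "B", "A", groups = grp)
  expect_equal(ab$t_stat, -ba$t_stat)
  expect_equal(ab$ratio, 1 / ba$ratio)
  expect_equal(ab$p_raw, ba$p_raw)

  # identical groups: t = 0, p = 1, ratio = 1
  ident <- matrix(rep(c(3, 4, 5), 2), 1, 6, byrow = TRUE,
                  dimnames = list("G", sprintf("s%d", 1:6)))
  de <- welchDe(ident, "A", "B", groups = rep(c("A", "B"), each = 3))
  expect_equal(de$t_stat, 0)
  expect_equal(de$p_raw, 1)
  expect_equal(de$ratio, 1)

  # constant equal groups: p = 1 by convention
  const <- matrix(2, 1, 6, dimnames = list("G", sprintf("s%d", 1:6)))
  dc <- welchDe(const, "A", "B", groups = rep(c("A", "B"), each = 3))
  expect_equal(dc$p_raw, 1)

  expect_error(welchDe(m[, 1:5], "A", "B", groups = grp[1:5]),
               ">= 2 samples")
})

test_that("replicate map collapses technical replicates before testing", {
  m <- matrix(c(10, 10, 14, 12, 1, 2, 3, 4), 1, 8,
              dimnames = list("G", sprintf("s%d", 1:8)))
  grp <- rep(c("SC", "BC"), each = 4)
  # columns 1 and 2 are replicates of one specimen
  rmap <- c("sp1", "sp1", "sp2", "sp3", NA, NA, NA, NA)
  de <- welchDe(m, "SC", "BC", groups = grp, replicateMap = rmap)
  ref <- welchDe(rbind(G = c(10, 14, 12, 1, 2, 3, 4)), "SC", "BC",
                 groups = c("SC", "SC", "SC", "BC", "BC", "BC", "BC"))
  expect_equal(de$t_stat, ref$t_stat)
  expect_equal(de$p_raw, ref$p_raw)
  # a map mixing arms inside one specimen is rejected
  expect_error(welchDe(m, "SC", "BC", groups = grp,
                       replicateMap = c("x", NA, NA, NA, "x", NA, NA, NA)),
               "different arms")
})

test_that("Bonferroni correction spans all genes tested", {
  set.seed(407)
  m <- matrix(rlnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("G%d", 1:20), sprintf("s%d", 1:6)))
  de <- welchDe(m, "A", "B", groups = rep(c("A", "B"), each = 3))
  expect_equal(de$p_adj, pmin(1, de$p_raw * 20))
})
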