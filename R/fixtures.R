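#' Region median-TPM worked-example table
#'
#' The ten homeobox genes reported as spinal-cord-overexpressed, with their
#' median TPM across four CNS regions (spinal cord n = 159, cerebellum
#' n = 241, hippocampus n = 197, brain cortex n = 255 donors). All ten pass
#' [regionSpecificFilter()] at the default 5/1 TPM thresholds: the smallest
#' on-target median is 5.37 and the largest off-target median is 0.54.
#'
#' @return An [ExpressionTable-class], 10 genes x 4 regions, unit TPM.
#' @examples
#' regionSpecificFilter(hoxMedianTable(), "Spinal Cord")
#' @export
hoxMedianTable <- function() {
  v <- matrix(c(
    8.14,  0,    0,    0,
    29.14, 0.03, 0,    0.01,
    23.01, 0.08, 0.01, 0.02,
    20.31, 0.54, 0.19, 0.10,
    6.16,  0.17, 0.05, 0.04,
    8.52,  0,    0,    0,
    5.37,  0,    0,    0,
    15.82, 0,    0.05, 0.02,
    17.91, 0,    0,    0,
    5.41,  0,    0,    0.01), ncol = 4, byrow = TRUE,
    dimnames = list(c("HOXA2", "HOXA4", "HOXA5", "HOXB2", "HOXB3",
                      "HOXB5", "HOXB6", "HOXB7", "HOXB8", "HOXD8"),
                    c("Spinal Cord", "Cerebellum", "Hippocampus",
                      "Brain Cortex")))
  ExpressionTable(v, unit = "TPM", nSamples = c(159L, 241L, 197L, 255L))
}

#' The ten spinal-cord-overexpressed homeobox genes
#'
#' @return Character vector of the ten query gene symbols, the row set of
#'   [hoxMedianTable()].
#' @export
hoxQueryGenes <- function() rownames(exprValues(hoxMedianTable()))

#' Worked-example HOX-TF interaction pairs
#'
#' The reported physical interactions between spinal-cord-overexpressed HOX
#' proteins and transcription factors: 15 pairs covering 14 distinct TFs
#' (PBX1 partners both HOXB7 and HOXB8).
#'
#' @return data.frame with columns `query`, `partner`.
#' @export
hoxTfPartnerEdges <- function() {
  data.frame(
    query = c(rep("HOXA5", 7), rep("HOXB5", 3), rep("HOXB6", 2),
              "HOXB7", rep("HOXB8", 2)),
    partner = c("DDIT3", "FOXA2", "FOXO1", "SMAD1", "SOX2", "TWIST1",
                "ZNF707", "HOXC4", "HRAS", "NKX2-1", "ALX4", "TCF21",
                "PBX1", "PBX1", "PBX3"),
    stringsAsFactors = FALSE)
}

#' Worked-example two-group fold ratios
#'
#' Spinal cord vs. brain cortex expression fold ratios of the ten homeobox
#' genes in the disease-free two-group comparison (10 vs. 10 samples),
#' with the Bonferroni-adjusted p-values reported alongside. Used as the
#' default planted effect sizes of [genSampleMatrix()].
#'
#' @return data.frame with columns `gene`, `ratio`, `p_adj_reported`.
#' @export
bneFoldRatios <- function() {
  data.frame(
    gene = c("HOXA2", "HOXA4", "HOXA5", "HOXB2", "HOXB3", "HOXB5",
             "HOXB6", "HOXB7", "HOXB8", "HOXD8"),
    ratio = c(15.49, 58.62, 234.90, 41.46, 2.58, 52.41, 1.74, 102.29,
              407.52, 13.42),
    p_adj_reported = c(4.57e-7, 2.62e-6, 9.03e-6, 1.14e-7, 0.01, 0.002,
                       0.06, 2.47e-6, 0.009, 0.001),
    stringsAsFactors = FALSE)
}

#' Gliosis-module transcription factors (partly synthetic)
#'
#' The gliosis-associated co-expression module contains 12 transcription
#' factors. Five are named in the source evidence (SMAD1, SOX2, AR, GLIS3,
#' NFIB); the remaining seven live in a supplementary sheet that is not
#' reproduced here and are stood in by synthetic placeholder symbols. The
#' overlap statistics of [moduleEnrichment()] depend only on the module
#' *size* and the named overlap, so the placeholders do not affect the
#' worked example.
#'
#' @return Character vector of 12 TF symbols (7 of them `MODTF1`..`MODTF7`
#'   synthetic placeholders).
#' @export
gliosisModuleTfs <- function() {
  c("SMAD1", "SOX2", "AR", "GLIS3", "NFIB", paste0("MODTF", 1:7))
}

#' Worked-example regulatory-network evidence layers
#'
#' The three evidence layers of the HOXA5 / TGF-beta / androgen-receptor
#' network over ten molecules: curated transcriptional repression by AR of
#' SOX2, SMAD3, TGFBR2 and TGFB1; predicted HOXA5 binding at the promoters
#' of SMAD1, SMAD3, TGFB1 and TGFBR2; and physical interactions read from
#' the editable fixture file `hoxa5_tgfb_ar_physical_edges.tsv` shipped under
#' `extdata` (the grey-edge list is curated, not exhaustively enumerated in
#' text, so it ships as data rather than code).
#'
#' @return List with data.frames `physical`, `repression`, `predicted` and
#'   a named `roles` vector, ready for [assembleNetwork()].
#' @export
hoxTgfbArLayers <- function() {
  phys_path <- system.file("extdata", "hoxa5_tgfb_ar_physical_edges.tsv",
                           package = "cordhox", mustWork = TRUE)
  physical <- utils::read.delim(phys_path, header = TRUE,
                                colClasses = "character")
  list(
    physical = physical,
    repression = data.frame(
      source = "AR",
      target = c("SOX2", "SMAD3", "TGFBR2", "TGFB1"),
      provenance = "curated promoter analysis",
      stringsAsFactors = FALSE),
    predicted = data.frame(
      source = "HOXA5",
      target = c("SMAD1", "SMAD3", "TGFB1", "TGFBR2"),
      provenance = "predicted binding motif",
      stringsAsFactors = FALSE),
    roles = c(HOXA5 = "hox", SOX2 = "tf", SMAD1 = "tf", SMAD2 = "pathway_member",
              SMAD3 = "pathway_member", SMAD4 = "pathway_member",
              TGFBR1 = "receptor", TGFBR2 = "receptor",
              TGFB1 = "pathway_member", AR = "receptor"))
}
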