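#' Region-specific expression filter
#'
#' Retains genes substantially expressed in one target region and at most
#' very poorly expressed everywhere else: `value(target) >= minTarget` and
#' `value(c) < maxOther` for every other column. Applied to a median-TPM
#' table of CNS regions with the defaults (5 TPM on target, 1 TPM off
#' target) this isolates the spinal-cord-overexpressed homeobox genes.
#'
#' @param x An [ExpressionTable-class] of median values, one column per
#'   region.
#' @param targetLabel Column label of the target region.
#' @param minTarget Minimum target-region expression (default 5).
#' @param maxOther Strict upper bound for every other region (default 1);
#'   must be below `minTarget`.
#' @return Character vector of passing gene symbols, in input row order.
#' @examples
#' m <- matrix(c(23.01, 0.4, 0.08, 0.3), 2, 2,
#'             dimnames = list(c("HOXA5", "BG1"), c("Spinal Cord", "Cortex")))
#' regionSpecificFilter(ExpressionTable(m, "TPM"), "Spinal Cord")
#' @export
regionSpecificFilter <- function(x, targetLabel, minTarget = 5,
                                 maxOther = 1) {
  stopifnot(is(x, "ExpressionTable"))
  if (!(minTarget > maxOther && maxOther >= 0))
    stop("need minTarget > maxOther >= 0", call. = FALSE)
  v <- exprValues(x)
  if (!targetLabel %in% colnames(v))
    stop("target column not found: ", targetLabel, call. = FALSE)
  if (ncol(v) < 2L)
    stop("need at least one non-target column", call. = FALSE)
  other <- v[, setdiff(colnames(v), targetLabel), drop = FALSE]
  pass <- v[, targetLabel] >= minTarget &
    apply(other, 1L, function(r) all(r < maxOther))
  rownames(v)[pass]
}

#' Flag expression values against a detection threshold
#'
#' Classifies every cell of an expression table as `below` (under the
#' threshold), `at` (between the threshold and `atTolerance * threshold`,
#' i.e. equal to or only slightly above detection), or `above`. Used to
#' check that region-filtered genes are essentially undetected in cultured
#' brain cell types (FPKM tables with a 0.1 detection floor).
#'
#' @param x An [ExpressionTable-class].
#' @param threshold Detection threshold in the table's unit (default 0.1).
#' @param atTolerance Multiple of the threshold still counted as "at"
#'   detection level (default 1.5).
#' @return List with `flags` (character matrix, same shape as the values)
#'   and `summary` (fraction of cells not above `atTolerance * threshold`).
#' @export
lowExpressionCheck <- function(x, threshold = 0.1, atTolerance = 1.5) {
  stopifnot(is(x, "ExpressionTable"), threshold > 0, atTolerance >= 1)
  v <- exprValues(x)
  if (length(v) == 0L) stop("empty expression table", call. = FALSE)
  flags <- matrix("above", nrow(v), ncol(v), dimnames = dimnames(v))
  flags[v <= threshold * atTolerance] <- "at"
  flags[v < threshold] <- "below"
  list(flags = flags, summary = mean(flags != "above"))
}

#' Welch two-group differential expression
#'
#' Per-gene unequal-variance two-sided t-test between two sample groups,
#' with Bonferroni correction across all genes tested:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)`, degrees of freedom by
#' Welch-Satterthwaite, expression ratio on the linear scale
#' (`mean(group1) / mean(group2)`). When both groups have zero variance and
#' equal means, p is 1 by convention. Columns sharing a replicate-map entry
#' are averaged into one biological specimen before testing.
#'
#' @param x An [ExpressionTable-class] of per-sample values whose colData
#'   `group` tags each column, or a plain numeric matrix (then `groups` is
#'   required).
#' @param group1,group2 The two group tags to compare (ratio and t are
#'   group1 relative to group2).
#' @param groups Optional explicit per-column group vector overriding
#'   colData.
#' @param replicateMap Optional character vector, parallel to the columns,
#'   naming the biological specimen behind each column; technical replicate
#'   columns share a name and are collapsed by their mean. `NA` entries are
#'   kept as independent columns.
#' @param correction `"bonferroni"` (default) or `"BH"`.
#' @return data.frame with columns `gene`, `ratio`, `t_stat`, `df`,
#'   `p_raw`, `p_adj`, in input gene order. `ratio` is `NaN`-flagged when
#'   the group-2 mean is zero.
#' @examples
#' m <- rbind(GENE = c(10, 12, 14, 1, 2, 3))
#' colnames(m) <- paste0("s", 1:6)
#' welchDe(m, "SC", "BC", groups = rep(c("SC", "BC"), each = 3))
#' @export
welchDe <- function(x, group1, group2, groups = NULL, replicateMap = NULL,
                    correction = c("bonferroni", "BH")) {
  correction <- match.arg(correction)
  if (is(x, "ExpressionTable")) {
    v <- exprValues(x)
    if (is.null(groups))
      groups <- SummarizedExperiment::colData(x)$group
  } else if (is.matrix(x) && is.numeric(x)) {
    v <- x
    if (is.null(groups))
      stop("groups must be supplied with a plain matrix", call. = FALSE)
  } else stop("x must be an ExpressionTable or numeric matrix",
              call. = FALSE)
  groups <- as.character(groups)
  if (length(groups) != ncol(v))
    stop("groups length must match the number of columns", call. = FALSE)
  if (!is.null(replicateMap)) {
    if (length(replicateMap) != ncol(v))
      stop("replicateMap length must match the number of columns",
           call. = FALSE)
    key <- ifelse(is.na(replicateMap),
                  paste0(".col", seq_len(ncol(v))), replicateMap)
    split_idx <- split(seq_len(ncol(v)), key)
    grp_of <- vapply(split_idx, function(ix) {
      g <- unique(groups[ix])
      if (length(g) != 1L)
        stop("replicate map groups columns from different arms",
             call. = FALSE)
      g
    }, character(1))
    rn <- rownames(v)
    v <- vapply(split_idx, function(ix) rowMeans(v[, ix, drop = FALSE]),
                numeric(nrow(v)))
    if (is.null(dim(v)))
      v <- matrix(v, nrow = 1L, dimnames = list(rn, names(split_idx)))
    groups <- grp_of
  }
  i1 <- which(groups == group1)
  i2 <- which(groups == group2)
  if (length(i1) < 2L || length(i2) < 2L)
    stop("each group needs >= 2 samples (after replicate collapsing)",
         call. = FALSE)
  x1 <- v[, i1, drop = FALSE]; x2 <- v[, i2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  s1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  s2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- s1 / n1 + s2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  degen <- se2 == 0 & m1 == m2
  t_stat[degen] <- 0; df[degen] <- NA_real_; p[degen] <- 1
  sep <- se2 == 0 & m1 != m2  # perfectly separated, zero-variance groups
  df[sep] <- NA_real_; p[sep] <- .Machine$double.xmin
  res <- data.frame(gene = rownames(v), ratio = m1 / m2, t_stat = t_stat,
                    df = df, p_raw = p,
                    p_adj = if (correction == "bonferroni")
                      adjustBonferroni(p) else adjustBH(p),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
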