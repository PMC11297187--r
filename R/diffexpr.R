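#' @importFrom stats pt
NULL

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: a pseudo-reference is formed as the
#' per-gene geometric mean over genes with all-positive counts, and each
#' sample's factor is the median of its count/reference ratios over those
#' genes.
#'
#' @param counts integer matrix (genes x samples) or a
#'   [SummarizedExperiment::SummarizedExperiment] with a `counts` assay.
#' @return numeric vector of size factors, one per sample.
#' @export
medianRatioSizeFactors <- function(counts) {
  m <- .count_matrix(counts)
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep))
    stop("no gene has positive counts in every sample")
  lm <- log(m[keep, , drop = FALSE])
  ref <- rowMeans(lm)  # log geometric mean
  apply(lm, 2, function(x) exp(stats::median(x - ref)))
}

.count_matrix <- function(counts) {
  if (is(counts, "SummarizedExperiment"))
    SummarizedExperiment::assay(counts, "counts")
  else as.matrix(counts)
}

.count_condition <- function(counts, condition) {
  if (!is.null(condition)) return(as.character(condition))
  if (is(counts, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(counts)
    if ("condition" %in% colnames(cd)) return(as.character(cd$condition))
  }
  stop("condition labels required (colData$condition or `condition`)")
}

#' Two-condition differential expression test
#'
#' A lightweight differential expression stage: counts are normalized by
#' [medianRatioSizeFactors()], transformed to `log2(normalized + 1)` and
#' compared between the two conditions with per-gene Welch t-tests;
#' p-values are BH-corrected across genes. The log2 fold change is the
#' difference of condition means on the transformed scale (treatment minus
#' control, `control` being the condition literally named "control" if
#' present, else the first level). This stage makes no negative-binomial
#' modelling claims - its contract is recovery of strongly planted
#' signals; an externally computed table ([readDETable()]) is accepted as
#' a drop-in replacement.
#'
#' @param counts matrix or SummarizedExperiment (genes x samples).
#' @param condition optional character vector of condition labels (two
#'   levels, >= 2 replicates each).
#' @param alpha BH significance level (default 0.05).
#' @param lfc_min additionally require `|log2_fold_change| > lfc_min` for
#'   `is_de` (default 0).
#' @return [S4Vectors::DataFrame] with `gene_id`, `log2_fold_change`,
#'   `p`, `p_adj`, `is_de`.
#' @export
deTest <- function(counts, condition = NULL, alpha = 0.05, lfc_min = 0) {
  m <- .count_matrix(counts)
  cond <- .count_condition(counts, condition)
  lev <- unique(cond)
  if (length(lev) != 2) stop("exactly two conditions required")
  if ("control" %in% lev) lev <- c("control", setdiff(lev, "control"))
  g1 <- cond == lev[1]  # control
  g2 <- cond == lev[2]  # treatment
  if (sum(g1) < 2 || sum(g2) < 2)
    stop("need >= 2 replicates per condition")
  sf <- medianRatioSizeFactors(m)
  x <- log2(sweep(m, 2, sf, "/") + 1)
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  v1 <- apply(x[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, g2, drop = FALSE], 1, stats::var)
  n1 <- sum(g1); n2 <- sum(g2)
  se2 <- v1 / n1 + v2 / n2
  lfc <- m2 - m1
  p <- rep(1, nrow(m))
  nz <- se2 > 0
  tt <- lfc[nz] / sqrt(se2[nz])
  df <- se2[nz]^2 / ((v1[nz] / n1)^2 / (n1 - 1) + (v2[nz] / n2)^2 / (n2 - 1))
  p[nz] <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  # zero variance in both groups: identical means -> p = 1, else p -> 0
  p[!nz & lfc != 0] <- 0
  p_adj <- p.adjust(p, method = "BH")
  DataFrame(gene_id = rownames(m) %||% as.character(seq_len(nrow(m))),
            log2_fold_change = unname(lfc), p = unname(p),
            p_adj = unname(p_adj),
            is_de = unname(p_adj < alpha & abs(lfc) > lfc_min))
}

#' Read an externally computed differential expression table
#'
#' Accepts a TSV with columns `gene_id`, a log2 fold change column
#' (`log2_fold_change` or `log2FoldChange` or `lfc`) and an adjusted
#' p-value column (`p_adj` or `padj`), e.g. exported from a
#' negative-binomial DE analysis, and normalizes it to the [deTest()]
#' output shape.
#'
#' @param path path to the TSV.
#' @param alpha significance level defining `is_de` (default 0.05).
#' @return [S4Vectors::DataFrame] with `gene_id`, `log2_fold_change`,
#'   `p_adj`, `is_de` (and `p` if present in the file).
#' @export
readDETable <- function(path, alpha = 0.05) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  lfc_col <- intersect(c("log2_fold_change", "log2FoldChange", "lfc"),
                       colnames(tab))[1]
  padj_col <- intersect(c("p_adj", "padj"), colnames(tab))[1]
  if (is.na(lfc_col) || is.na(padj_col) || !"gene_id" %in% colnames(tab))
    stop("DE table needs gene_id, a log2 fold change and an adjusted p column")
  DataFrame(gene_id = tab$gene_id,
            log2_fold_change = tab[[lfc_col]],
            p = if ("p" %in% colnames(tab)) tab$p else NA_real_,
            p_adj = tab[[padj_col]],
            is_de = tab[[padj_col]] < alpha)
}
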