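# Gene alignment, normalization, per-gene summaries, cluster pseudobulks.

#' Align genes between a reference and an ST dataset
#'
#' Returns the genes shared by both datasets, ordered as in the ST dataset
#' so that column indexing is reproducible.
#'
#' @param ref reference [ExpressionMatrix-class] (cells).
#' @param st spatial [ExpressionMatrix-class] (spots).
#' @return data.frame with columns `gene`, `refIndex`, `stIndex`.
#' @examples
#' ref <- ExpressionMatrix(matrix(1, 2, 3, dimnames = list(NULL, c("A","B","C"))))
#' st  <- ExpressionMatrix(matrix(1, 2, 3, dimnames = list(NULL, c("B","C","D"))),
#'                         axisRole = "spots")
#' alignGenes(ref, st)$gene
#' @export
alignGenes <- function(ref, st) {
  stopifnot(is(ref, "ExpressionMatrix"), is(st, "ExpressionMatrix"))
  shared <- intersect(geneIds(st), geneIds(ref))
  if (length(shared) == 0L)
    stop(sprintf(
      "no shared genes between reference (%d genes) and ST (%d genes)",
      length(geneIds(ref)), length(geneIds(st))))
  data.frame(
    gene = shared,
    refIndex = match(shared, geneIds(ref)),
    stIndex = match(shared, geneIds(st)),
    stringsAsFactors = FALSE
  )
}

#' Normalize an expression matrix
#'
#' `total_count_log1p` scales every sample to the median pre-scaling sample
#' sum and applies `log1p`; `none` passes values through unchanged.  The
#' same strategy should be applied to reference and ST so both live on the
#' same scale.
#'
#' @param x an [ExpressionMatrix-class] of raw nonnegative values.
#' @param strategy `"total_count_log1p"` (default) or `"none"`.
#' @return A normalized `ExpressionMatrix` with identical ids.
#' @export
normalizeExpression <- function(x, strategy = c("total_count_log1p", "none")) {
  strategy <- match.arg(strategy)
  stopifnot(is(x, "ExpressionMatrix"))
  if (strategy == "none") return(x)
  v <- exprValues(x)
  if (any(v < 0)) stop("normalization expects nonnegative raw values")
  tot <- rowSums(v)
  if (any(tot == 0))
    warning(sprintf("%d sample(s) with zero total left as zeros",
                    sum(tot == 0)))
  target <- median(tot[tot > 0])
  if (!length(target) || is.na(target)) target <- 0
  scl <- ifelse(tot > 0, target / tot, 0)
  ExpressionMatrix(log1p(v * scl), sampleIds(x), geneIds(x), axisRole(x))
}

#' Per-gene sparsity of a count matrix
#'
#' Fraction of exact zeros in each gene column, computed on the raw count
#' matrix (one of the three uncertainty features).
#'
#' @param counts an [ExpressionMatrix-class] of raw counts.
#' @return Named numeric vector in `[0, 1]`, one entry per gene.
#' @export
geneSparsity <- function(counts) {
  stopifnot(is(counts, "ExpressionMatrix"))
  v <- exprValues(counts)
  setNames(colMeans(v == 0), geneIds(counts))
}

#' Coerce cluster labels to a canonical named factor
#'
#' @param labels factor/character/numeric labels, optionally named by sample
#'   id; unnamed labels are matched positionally.
#' @param x the [ExpressionMatrix-class] the labels refer to.
#' @return Factor of length `nrow(x)`, named by `sampleIds(x)`, levels
#'   sorted lexicographically.
#' @export
clusterLabels <- function(labels, x) {
  stopifnot(is(x, "ExpressionMatrix"))
  ids <- sampleIds(x)
  if (!is.null(names(labels))) {
    if (!all(ids %in% names(labels)))
      stop("cluster labels do not cover all samples")
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop(sprintf("got %d labels for %d samples", length(labels), length(ids)))
  }
  f <- factor(as.character(labels), levels = sort(unique(as.character(labels))))
  if (anyNA(f)) stop("NA cluster labels")
  names(f) <- ids
  f
}

#' Aggregate a reference into cluster pseudobulks
#'
#' Sums the expression of all member cells per cluster; used by
#' cluster-mode translation models.  Row order is the lexicographic sort of
#' cluster names.
#'
#' @param ref reference [ExpressionMatrix-class].
#' @param labels cluster labels (see [clusterLabels()]).
#' @return `ExpressionMatrix` with one row per cluster (axisRole kept
#'   `"cells"`: pseudobulks stand in for cells).
#' @export
aggregateByCluster <- function(ref, labels) {
  stopifnot(is(ref, "ExpressionMatrix"))
  f <- clusterLabels(labels, ref)
  v <- exprValues(ref)
  agg <- rowsum(v, group = f, reorder = TRUE)
  ExpressionMatrix(agg, sampleIds = rownames(agg), geneIds = geneIds(ref),
                   axisRole = "cells")
}
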