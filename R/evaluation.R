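# Evaluation machinery: gene k-fold CV, CSS aggregation, uncertainty
# curves, spatially constrained Ward clustering, concordance indices, and
# SHVG precision-recall.

#' Assign genes to cross-validation folds
#'
#' Seeded shuffle followed by contiguous chunking; fold sizes differ by at
#' most one, and merging all test folds covers every gene exactly once.
#'
#' @param genes character vector of gene ids.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return data.frame with columns `gene` and `fold` (1..k).
#' @export
kfoldSplit <- function(genes, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > length(genes)) stop("k exceeds the number of genes")
  set.seed(as.integer(seed))
  perm <- sample(genes)
  fold <- rep(seq_len(k), each = ceiling(length(genes) / k))[seq_along(genes)]
  out <- data.frame(gene = perm, fold = sort(fold), stringsAsFactors = FALSE)
  out[match(genes, out$gene), , drop = FALSE]
}

#' Summarize imputation accuracy by cosine similarity
#'
#' Gene-level CSS is the column-wise cosine between predicted and observed
#' expression; cell (spot) level is the row-wise transposed view.  The
#' median is the headline aggregate.
#'
#' @param pred,obs spots x genes matrices or [ExpressionMatrix-class]
#'   objects of identical shape.
#' @param level `"gene"` (default) or `"cell"`.
#' @return List with `scores` (named per-unit cosine) and `median`.
#' @export
cssSummary <- function(pred, obs, level = c("gene", "cell")) {
  level <- match.arg(level)
  P <- .coerceSpotMatrix(pred)
  Y <- .coerceSpotMatrix(obs)
  if (!all(dim(P) == dim(Y))) stop("pred and obs must have identical shapes")
  scores <- if (level == "gene") setNames(.colCosine(P, Y), colnames(P))
            else setNames(.colCosine(t(P), t(Y)), rownames(P))
  list(scores = scores, median = median(scores))
}

#' Median CSS below successive uncertainty quantiles
#'
#' For each grid point `t`, the median CSS over genes whose uncertainty
#' quantile is at most `t`; the final point (t = 1) is the global median.
#' Empty bins are kept with `NA` median and flagged by `nGenes = 0`.
#'
#' @param css named per-gene CSS.
#' @param uncertainty data.frame from [predictUncertainty()].
#' @param grid quantile grid (default 0.1..1 by 0.1).
#' @return data.frame with columns `quantile`, `medianCss`, `nGenes`.
#' @export
cssByUncertaintyQuantile <- function(css, uncertainty,
                                     grid = seq(0.1, 1, by = 0.1)) {
  if (is.null(names(css))) names(css) <- uncertainty$gene
  common <- intersect(names(css), uncertainty$gene)
  if (!length(common)) stop("no genes shared between css and uncertainty")
  q <- setNames(uncertainty$quantile, uncertainty$gene)[common]
  css <- css[common]
  data.frame(
    quantile = grid,
    medianCss = vapply(grid, function(t) {
      sel <- css[q <= t + 1e-12]
      if (length(sel)) median(sel) else NA_real_
    }, numeric(1)),
    nGenes = vapply(grid, function(t) sum(q <= t + 1e-12), integer(1))
  )
}

#' Spatially constrained agglomerative (Ward) clustering
#'
#' Bottom-up Ward agglomeration in which merges are restricted to pairs of
#' clusters connected in the spatial graph, so clusters are spatially
#' contiguous.  If the graph is disconnected and fewer clusters than
#' components are requested, the remaining merges ignore connectivity
#' (per-component clustering followed by a global merge).  Deterministic:
#' ties resolve to the lexicographically smallest cluster-index pair.
#'
#' @param expr spots x genes [ExpressionMatrix-class] or matrix.
#' @param graph [SpatialGraph-class] over the spots.
#' @param nClusters target number of clusters (`2 <= nClusters <= Ns`).
#' @param scale z-score each gene before clustering (default TRUE).
#' @return Integer factor of cluster labels, one per spot.
#' @export
spatialAgglomerativeClustering <- function(expr, graph, nClusters,
                                           scale = TRUE) {
  X <- .coerceSpotMatrix(expr)
  n <- nrow(X)
  nClusters <- as.integer(nClusters)
  if (nClusters > n) stop("nClusters exceeds the number of spots")
  if (nClusters < 1L) stop("nClusters must be >= 1")
  if (nrow(graph@weights) != n) stop("graph does not match the spots")
  if (scale) {
    sds <- apply(X, 2L, sd)
    sds[sds == 0] <- 1
    X <- sweep(sweep(X, 2L, colMeans(X)), 2L, sds, "/")
  }
  # active cluster bookkeeping: centroids, sizes, adjacency sets
  cent <- X
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  Wd <- as.matrix(graph@weights) > 0
  adj <- Wd | t(Wd)
  diag(adj) <- FALSE
  member <- as.list(seq_len(n))
  nActive <- n
  while (nActive > nClusters) {
    act <- which(active)
    # Ward distance between connected active pairs
    best <- c(NA_integer_, NA_integer_); bestD <- Inf
    connectedOnly <- TRUE
    repeat {
      for (ii in seq_along(act)) {
        a <- act[ii]
        nbrs <- if (connectedOnly) act[adj[a, act]] else act
        nbrs <- nbrs[nbrs > a]
        if (!length(nbrs)) next
        dc <- colSums((t(cent[nbrs, , drop = FALSE]) - cent[a, ])^2)
        wfac <- (size[a] * size[nbrs]) / (size[a] + size[nbrs])
        dW <- wfac * dc
        m <- which.min(dW)
        if (dW[m] < bestD - 1e-15) {
          bestD <- dW[m]; best <- c(a, nbrs[m])
        }
      }
      if (is.finite(bestD) || !connectedOnly) break
      connectedOnly <- FALSE  # disconnected graph: allow global merges
    }
    a <- best[1]; b <- best[2]
    cent[a, ] <- (size[a] * cent[a, ] + size[b] * cent[b, ]) /
      (size[a] + size[b])
    size[a] <- size[a] + size[b]
    member[[a]] <- c(member[[a]], member[[b]])
    adj[a, ] <- adj[a, ] | adj[b, ]
    adj[, a] <- adj[, a] | adj[, b]
    adj[a, a] <- FALSE
    active[b] <- FALSE
    nActive <- nActive - 1L
  }
  lab <- integer(n)
  for (ci in seq_along(which(active))) {
    lab[member[[which(active)[ci]]]] <- ci
  }
  factor(lab)
}

# entropy (nats) of a label vector and MI of a contingency table
.entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

.mutualInfo <- function(tab) {
  n <- sum(tab)
  pij <- tab / n
  pi <- rowSums(tab) / n
  pj <- colSums(tab) / n
  nz <- pij > 0
  sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
}

# expected mutual information under the hypergeometric null (for AMI)
.expectedMI <- function(a, b, n) {
  emi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      lo <- max(1L, a[i] + b[j] - n)
      hi <- min(a[i], b[j])
      if (hi < lo) next
      for (nij in lo:hi) {
        term <- (nij / n) * log(n * nij / (a[i] * b[j]))
        lp <- lgamma(a[i] + 1) + lgamma(b[j] + 1) +
          lgamma(n - a[i] + 1) + lgamma(n - b[j] + 1) -
          lgamma(n + 1) - lgamma(nij + 1) - lgamma(a[i] - nij + 1) -
          lgamma(b[j] - nij + 1) - lgamma(n - a[i] - b[j] + nij + 1)
        emi <- emi + term * exp(lp)
      }
    }
  }
  emi
}

#' Concordance between two spot labelings
#'
#' Computes the adjusted Rand score (ARS), adjusted mutual information
#' (AMIS), homogeneity (HOMO, of `reference` within `labels`) and
#' normalized mutual information (NMI, arithmetic normalization), plus
#' their arithmetic mean.  All four are invariant to label renaming.
#'
#' @param labels candidate labeling (e.g. clusters of imputed expression).
#' @param reference reference labeling (clusters of observed expression,
#'   or annotated cell types).
#' @return List with `ars`, `amis`, `homo`, `nmi`, `meanScore`.
#' @export
clusteringConcordance <- function(labels, reference) {
  if (length(labels) != length(reference))
    stop("labelings must have the same length")
  tab <- table(reference, labels)
  n <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  # adjusted Rand index
  sumIj <- sum(choose(tab, 2))
  sumA <- sum(choose(a, 2)); sumB <- sum(choose(b, 2))
  expIdx <- sumA * sumB / choose(n, 2)
  maxIdx <- (sumA + sumB) / 2
  ars <- if (maxIdx == expIdx) 1 else (sumIj - expIdx) / (maxIdx - expIdx)
  # information-theoretic scores
  mi <- .mutualInfo(tab)
  hu <- .entropy(a); hv <- .entropy(b)
  nmi <- if (hu + hv == 0) 1 else mi / ((hu + hv) / 2)
  emi <- .expectedMI(as.numeric(a), as.numeric(b), n)
  denom <- (hu + hv) / 2 - emi
  amis <- if (abs(denom) < 1e-15) 1 else (mi - emi) / denom
  homo <- if (hu == 0) 1 else 1 - (hu - mi) / hu  # 1 - H(ref | labels)/H(ref)
  out <- list(ars = as.numeric(ars), amis = as.numeric(amis),
              homo = as.numeric(homo), nmi = as.numeric(nmi))
  out$meanScore <- mean(unlist(out))
  out
}

#' Precision-recall curve for SHVG detection
#'
#' Treats the significance calls on observed expression as ground truth
#' and ranks genes by a score derived from imputed expression (e.g. the
#' Moran z statistic), sweeping all thresholds.  AUPRC uses step
#' integration `sum((R_k - R_{k-1}) * P_k)`.
#'
#' @param truthSignificant logical per gene (must contain both classes).
#' @param score numeric ranking per gene, higher = more likely positive.
#' @return List with `curve` (data.frame `threshold`, `precision`,
#'   `recall`) and `auprc`.
#' @export
shvgPrc <- function(truthSignificant, score) {
  truth <- as.logical(truthSignificant)
  if (length(truth) != length(score)) stop("length mismatch")
  if (!any(truth) || all(truth))
    stop("truth must contain at least one positive and one negative gene")
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]; score <- score[ord]
  tp <- cumsum(truth)
  fp <- cumsum(!truth)
  # merge ties: keep the last point of each distinct score
  last <- !duplicated(score, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]; thr <- score[last]
  precision <- tp / (tp + fp)
  recall <- tp / sum(truth)
  dr <- diff(c(0, recall))
  auprc <- sum(dr * precision)
  list(curve = data.frame(threshold = thr, precision = precision,
                          recall = recall),
       auprc = auprc)
}
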