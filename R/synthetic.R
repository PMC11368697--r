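# Seeded synthetic paired SC-reference / ST generator with known
# ground-truth mapping, cluster structure, dropout sparsity, and per-gene
# spatial autocorrelation on a regular grid.

#' Simulate a paired single-cell reference and ST dataset
#'
#' Generates (i) a clustered reference with log-normal cluster-specific
#' gene programs and Bernoulli dropout, (ii) a nonnegative ground-truth
#' cell-to-spot mapping `W` whose spots are soft mixtures (up to 3
#' clusters) of spatially blocked cluster bumps on a regular grid, and
#' (iii) ST expression `st = W %*% ref + noise`, clipped at zero.  Genes in
#' the spatial mask receive strongly cluster-differential programs, so
#' their spot profiles follow the spatial cluster blocks and carry high
#' Moran's I; non-spatial genes have cluster-flat means and near-zero
#' autocorrelation.  `smoothSigma` is the width (grid units) of the
#' cluster bumps and thus controls how smooth the spatial patterns are.
#' Because ST is an exact linear image of the returned reference, the data
#' are reachable by the full-mode model class and noiseless recovery is
#' well-posed.
#'
#' @param nCells,nSpots,nGenes,nClusters dataset dimensions (defaults 200
#'   cells, 100 spots, 100 genes, 5 clusters).
#' @param grid integer `c(rows, cols)` spot layout; `rows * cols` must
#'   equal `nSpots`.
#' @param noiseSd SD of additive Gaussian noise on ST (absolute scale;
#'   default 0).
#' @param dropoutRate probability of zeroing a reference entry (default 0.3).
#' @param fracSpatialGenes fraction of genes given a spatial pattern
#'   (default 0.5).
#' @param smoothSigma spatial bump width in grid units (default 1.5).
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @return List with elements `ref` (reference values, cells x genes),
#'   `refCounts` (Poisson-sampled counts for sparsity features), `st`
#'   (spot expression), `coords` (Ns x 2 grid coordinates), and `truth`
#'   (list: `WTrue`, `clusterLabels`, `spatialGeneMask`, `targetMoransI`).
#' @export
simulateSpatialData <- function(nCells = 200L, nSpots = 100L, nGenes = 100L,
                                nClusters = 5L, grid = c(10L, 10L),
                                noiseSd = 0, dropoutRate = 0.3,
                                fracSpatialGenes = 0.5, smoothSigma = 1.5,
                                seed = 1L) {
  if (prod(grid) != nSpots)
    stop("grid rows * cols must equal nSpots")
  if (nClusters < 1L || nCells < nClusters)
    stop("need at least one cell per cluster")
  if (dropoutRate < 0 || dropoutRate >= 1) stop("dropoutRate must be in [0, 1)")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  set.seed(as.integer(seed))

  cellIds <- sprintf("cell_%03d", seq_len(nCells))
  geneIdsV <- sprintf("gene_%03d", seq_len(nGenes))
  spotIds <- sprintf("spot_%03d", seq_len(nSpots))
  clNames <- sprintf("c%02d", seq_len(nClusters))

  # cluster assignment: every cluster populated, remainder random
  labels <- factor(c(clNames,
                     sample(clNames, nCells - nClusters, replace = TRUE)),
                   levels = clNames)
  names(labels) <- cellIds

  # gene programs: spatial genes strongly cluster-differential, the rest flat
  nSpa <- round(fracSpatialGenes * nGenes)
  spatialMask <- c(rep(TRUE, nSpa), rep(FALSE, nGenes - nSpa))
  spatialMask <- spatialMask[sample.int(nGenes)]
  base <- exp(rnorm(nGenes, mean = 1, sd = 0.3))
  mu <- matrix(rep(base, each = nClusters), nClusters, nGenes)
  if (nSpa > 0)
    mu[, spatialMask] <- mu[, spatialMask] *
      exp(matrix(rnorm(nClusters * nSpa, sd = 1.2), nClusters, nSpa))

  # cell expression: program x lognormal cell jitter, then dropout
  clIdx <- as.integer(labels)
  refV <- mu[clIdx, , drop = FALSE] *
    exp(matrix(rnorm(nCells * nGenes, sd = 0.2), nCells, nGenes))
  if (dropoutRate > 0) {
    keep <- matrix(runif(nCells * nGenes) >= dropoutRate, nCells, nGenes)
    refV <- refV * keep
  }
  dimnames(refV) <- list(cellIds, geneIdsV)

  # counts: Poisson sample of a scaled copy (sparsity features need counts)
  counts <- matrix(rpois(nCells * nGenes, lambda = refV * 5), nCells, nGenes,
                   dimnames = dimnames(refV))

  # spot layout and spatially blocked cluster mixture weights
  coords <- as.matrix(expand.grid(x = seq_len(grid[2]), y = seq_len(grid[1])))
  coords <- coords[seq_len(nSpots), , drop = FALSE]
  rownames(coords) <- spotIds
  centers <- cbind(runif(nClusters, 1, grid[2]), runif(nClusters, 1, grid[1]))
  tau <- max(smoothSigma, 1e-3)
  d2 <- outer(coords[, 1], centers[, 1], "-")^2 +
        outer(coords[, 2], centers[, 2], "-")^2
  A <- exp(-d2 / (2 * tau^2))
  # keep at most the 3 nearest cluster bumps per spot, renormalize
  if (nClusters > 3L) {
    for (s in seq_len(nSpots)) {
      drop <- order(A[s, ], decreasing = TRUE)[-seq_len(3L)]
      A[s, drop] <- 0
    }
  }
  A <- A / pmax(rowSums(A), .Machine$double.eps)

  # within-cluster cell weights, fixed per cluster (W is rank <= nClusters)
  B <- matrix(0, nClusters, nCells)
  for (c in seq_len(nClusters)) {
    members <- which(clIdx == c)
    wgt <- runif(length(members), 0.5, 1.5)
    B[c, members] <- wgt / sum(wgt)
  }
  WTrue <- A %*% B
  dimnames(WTrue) <- list(spotIds, cellIds)

  stV <- WTrue %*% refV
  if (noiseSd > 0)
    stV <- pmax(stV + matrix(rnorm(nSpots * nGenes, sd = noiseSd),
                             nSpots, nGenes), 0)
  dimnames(stV) <- list(spotIds, geneIdsV)

  ref <- ExpressionMatrix(refV, axisRole = "cells")
  st <- ExpressionMatrix(stV, axisRole = "spots")
  graph <- buildSpatialGraph(coords, k = min(6L, nSpots - 1L))
  targetI <- as.numeric(moransI(WTrue %*% refV, graph))

  list(
    ref = ref,
    refCounts = ExpressionMatrix(counts, axisRole = "cells"),
    st = st,
    coords = coords,
    truth = list(WTrue = WTrue, clusterLabels = labels,
                 spatialGeneMask = setNames(spatialMask, geneIdsV),
                 targetMoransI = setNames(targetI, geneIdsV))
  )
}

#' Add seeded white noise to an expression matrix
#'
#' Adds i.i.d. Gaussian noise and clips at zero; large `sd` progressively
#' destroys spatial patterns (shrinks per-gene Moran's I toward 0), which
#' is useful for stress-testing spatial regularization and uncertainty
#' scoring.
#'
#' @param x an [ExpressionMatrix-class].
#' @param sd noise standard deviation (`sd = 0` returns `x` unchanged).
#' @param seed integer seed.
#' @param genes optional subset of gene ids to corrupt; default all.
#' @return `ExpressionMatrix` of the same shape.
#' @export
addWhiteNoise <- function(x, sd, seed = 1L, genes = NULL) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) return(x)
  v <- exprValues(x)
  set.seed(as.integer(seed))
  if (is.null(genes)) {
    v <- pmax(v + matrix(rnorm(length(v), sd = sd), nrow(v), ncol(v)), 0)
  } else {
    jj <- match(genes, geneIds(x))
    if (anyNA(jj)) stop("unknown genes in 'genes'")
    v[, jj] <- pmax(v[, jj] + matrix(rnorm(nrow(v) * length(jj), sd = sd),
                                     nrow(v), length(jj)), 0)
  }
  ExpressionMatrix(v, sampleIds(x), geneIds(x), axisRole(x))
}
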