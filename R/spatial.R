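# Spatial graph construction, global Moran's I, spatial regularization loss,
# and the Moran's I SHVG test with FDR control.

#' Build a kNN spatial graph over spot coordinates
#'
#' Connects each spot to its `k` nearest Euclidean neighbors, converts
#' distances to weights, symmetrizes by the elementwise maximum, and (by
#' default) row-normalizes.  Distance ties are broken deterministically in
#' favor of the lower spot index; duplicated coordinates are allowed (zero
#' distance receives the scheme's maximal weight).
#'
#' @param coords numeric Ns x 2 matrix of spot coordinates (rownames used
#'   as spot ids) or a data.frame with columns `x`, `y` (+ optional first
#'   id column).
#' @param k number of neighbors, `1 <= k < Ns`.
#' @param scheme distance-to-weight conversion: `"inverse_distance"`
#'   (`1 / (1 + d)`, default), `"gaussian"` (`exp(-d^2 / (2 sigma^2))`) or
#'   `"binary"`.
#' @param sigma bandwidth for the gaussian scheme; defaults to the mean
#'   kNN distance.
#' @param rowNormalize divide each nonempty row by its sum (default TRUE).
#' @return A [SpatialGraph-class].
#' @export
buildSpatialGraph <- function(coords, k = 6L,
                              scheme = c("inverse_distance", "gaussian", "binary"),
                              sigma = NULL, rowNormalize = TRUE) {
  scheme <- match.arg(scheme)
  xy <- .coerceCoords(coords)
  n <- nrow(xy)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k >= n) stop(sprintf("k = %d must be smaller than the number of spots (%d)", k, n))
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  # neighbor selection: order() breaks distance ties by lower index
  idx <- t(apply(d, 1L, function(row) order(row)[seq_len(k)]))
  i <- rep(seq_len(n), each = k)
  j <- as.vector(t(idx))
  dd <- d[cbind(i, j)]
  w <- switch(scheme,
    inverse_distance = 1 / (1 + dd),
    gaussian = {
      if (is.null(sigma)) sigma <- mean(dd)
      if (sigma <= 0) sigma <- 1
      exp(-dd^2 / (2 * sigma^2))
    },
    binary = rep(1, length(dd))
  )
  W <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  W <- .symmetrizeMax(W)
  Matrix::diag(W) <- 0
  W <- Matrix::drop0(W)
  if (rowNormalize) {
    rs <- Matrix::rowSums(W)
    rs[rs == 0] <- 1
    W <- Matrix::Diagonal(x = 1 / rs) %*% W
  }
  W <- methods::as(methods::as(W, "generalMatrix"), "CsparseMatrix")
  rownames(W) <- colnames(W) <- rownames(xy)
  new("SpatialGraph", weights = W, k = k, scheme = scheme,
      rowNormalized = rowNormalize)
}

.coerceCoords <- function(coords) {
  if (is.data.frame(coords)) {
    cols <- intersect(c("x", "y"), names(coords))
    if (length(cols) == 2L) {
      ids <- if ("spot_id" %in% names(coords)) as.character(coords$spot_id)
             else rownames(coords)
      xy <- as.matrix(coords[, c("x", "y")])
      rownames(xy) <- ids
    } else {
      xy <- as.matrix(coords[, seq_len(2L)])
    }
  } else {
    xy <- as.matrix(coords)
  }
  if (ncol(xy) != 2L) stop("coordinates must have two columns")
  if (anyNA(xy) || any(!is.finite(xy))) stop("coordinates must be finite")
  if (is.null(rownames(xy))) rownames(xy) <- sprintf("spot_%d", seq_len(nrow(xy)))
  storage.mode(xy) <- "double"
  xy
}

.symmetrizeMax <- function(W) {
  Wt <- Matrix::t(W)
  # elementwise max of two nonnegative sparse matrices
  (W + Wt + abs(W - Wt)) / 2
}

#' Global Moran's I, vectorized over genes
#'
#' Computes `I = (Ns / S0) * (z' W z) / (z' z)` per gene with
#' `z = x - mean(x)` and the graph's weights `W`.  Genes with zero variance
#' are assigned `I = 0` and flagged in the `"degenerate"` attribute (imputed
#' genes can be constant).  The computation is a composition of matrix
#' products, which is what the training loss differentiates through.
#'
#' @param values numeric vector (one gene), spots x genes matrix, or an
#'   [ExpressionMatrix-class] with spot rows.
#' @param graph a [SpatialGraph-class] over the same spots.
#' @return Numeric vector of Moran's I per gene, with a logical
#'   `"degenerate"` attribute marking zero-variance genes.
#' @export
moransI <- function(values, graph) {
  stopifnot(is(graph, "SpatialGraph"))
  V <- .coerceSpotMatrix(values)
  W <- graph@weights
  if (nrow(V) != nrow(W))
    stop(sprintf("values have %d spots but graph has %d", nrow(V), nrow(W)))
  if (anyNA(V)) stop("values contain NA")
  n <- nrow(V)
  s0 <- sum(W)
  Z <- sweep(V, 2L, colMeans(V))
  num <- colSums(Z * as.matrix(W %*% Z))
  den <- colSums(Z^2)
  degenerate <- den <= .Machine$double.eps * n
  I <- ifelse(degenerate, 0, (n / s0) * num / pmax(den, .Machine$double.eps))
  names(I) <- colnames(V)
  attr(I, "degenerate") <- unname(degenerate)
  I
}

.coerceSpotMatrix <- function(values) {
  if (is(values, "ExpressionMatrix")) return(exprValues(values))
  if (is.null(dim(values))) return(matrix(as.numeric(values), ncol = 1L))
  as.matrix(values)
}

#' Moran's I regularization loss
#'
#' Mean over genes of the squared difference between the Moran's I of
#' predicted and observed expression, the spatial term of the training
#' objective.
#'
#' @param pred,obs spots x genes matrices or [ExpressionMatrix-class]
#'   objects of identical shape.
#' @param graph a [SpatialGraph-class] over the spots.
#' @return Nonnegative scalar.
#' @export
spatialRegLoss <- function(pred, obs, graph) {
  P <- .coerceSpotMatrix(pred)
  Y <- .coerceSpotMatrix(obs)
  if (!all(dim(P) == dim(Y))) stop("pred and obs must have identical shapes")
  mean((moransI(P, graph) - moransI(Y, graph))^2)
}

#' Moran's I test for spatially variable genes
#'
#' One-sided (upper tail) test for positive spatial autocorrelation per
#' gene, with Benjamini-Hochberg adjustment across genes.  The permutation
#' test (default) permutes spot values within each gene; the normal
#' approximation uses the classical normality-assumption variance of global
#' Moran's I.
#'
#' @param values spots x genes matrix or [ExpressionMatrix-class].
#' @param graph a [SpatialGraph-class].
#' @param method `"permutation"` (default) or `"normal_approx"`.
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed for the permutation draws.
#' @return data.frame with columns `gene`, `I`, `expectedI`, `z`, `p`, `q`.
#' @export
moransITest <- function(values, graph,
                        method = c("permutation", "normal_approx"),
                        nPerm = 999L, seed = 1L) {
  method <- match.arg(method)
  V <- .coerceSpotMatrix(values)
  n <- nrow(V)
  if (n < 4L) stop("need at least 4 spots")
  Iobs <- moransI(V, graph)
  EI <- -1 / (n - 1)
  W <- graph@weights
  s0 <- sum(W)
  if (method == "normal_approx") {
    Wd <- as.matrix(W)
    s1 <- sum((Wd + t(Wd))^2) / 2
    s2 <- sum((rowSums(Wd) + colSums(Wd))^2)
    varI <- (n^2 * s1 - n * s2 + 3 * s0^2) / (s0^2 * (n^2 - 1)) - EI^2
    z <- (Iobs - EI) / sqrt(varI)
    p <- stats::pnorm(z, lower.tail = FALSE)
  } else {
    if (nPerm < 1L) stop("nPerm must be >= 1")
    set.seed(seed)
    ge <- integer(ncol(V))
    for (j in seq_len(ncol(V))) {
      zj <- V[, j] - mean(V[, j])
      den <- sum(zj^2)
      if (den <= .Machine$double.eps * n) { ge[j] <- nPerm; next }
      # each column is one permutation of zj
      Zp <- vapply(seq_len(nPerm), function(s) zj[sample.int(n)], numeric(n))
      Ip <- (n / s0) * colSums(Zp * as.matrix(W %*% Zp)) / den
      ge[j] <- sum(Ip >= Iobs[j])
    }
    p <- (1 + ge) / (1 + nPerm)
    z <- stats::qnorm(pmin(pmax(1 - p, 1e-12), 1 - 1e-12))
  }
  data.frame(
    gene = names(Iobs) %||% sprintf("gene_%d", seq_along(Iobs)),
    I = as.numeric(Iobs), expectedI = EI, z = as.numeric(z),
    p = as.numeric(p), q = bhAdjust(as.numeric(p)),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wrapper over [stats::p.adjust()]), used to call
#' spatially variable genes at a stated FDR.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return Monotone adjusted values clipped to 1.
#' @export
bhAdjust <- function(p) {
  if (anyNA(p)) stop("NA p-values")
  if (any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Write SHVG test results to TSV
#'
#' @param result data.frame from [moransITest()].
#' @param path output path.
#' @param fdr significance threshold recorded in the `significant` column.
#' @return `path`, invisibly.
#' @export
writeShvgResults <- function(result, path, fdr = 0.01) {
  out <- result
  out$significant <- out$q < fdr
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
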