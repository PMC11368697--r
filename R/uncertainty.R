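# Local within-cluster bootstrap, per-gene cosine scores, bootstrap score
# variance, the 3-feature uncertainty regression, and knee-point gene
# selection.

#' Local (within-cluster) bootstrap of a reference
#'
#' Resamples cells with replacement within each cluster, preserving every
#' cluster's size and each cell's cluster slot: the row at position `i`
#' is replaced by a draw from `i`'s own cluster, so a fitted per-cell
#' mapping stays aligned with the resampled matrix.  Draws are made
#' cluster by cluster in sorted cluster order (then original within-cluster
#' order), from the given seed.
#'
#' @param ref reference [ExpressionMatrix-class].
#' @param labels cluster labels (see [clusterLabels()]).
#' @param seed integer seed.
#' @return `ExpressionMatrix` with the same dimensions and cluster sizes;
#'   resampled sample ids are made unique.
#' @export
localBootstrap <- function(ref, labels, seed = 1L) {
  stopifnot(is(ref, "ExpressionMatrix"))
  f <- clusterLabels(labels, ref)
  if (any(table(f) == 0)) stop("empty cluster")
  set.seed(as.integer(seed))
  draw <- integer(length(f))
  for (cl in levels(f)) {
    members <- which(f == cl)
    draw[members] <- members[sample.int(length(members),
                                        length(members), replace = TRUE)]
  }
  v <- exprValues(ref)[draw, , drop = FALSE]
  ids <- make.unique(sampleIds(ref)[draw])
  ExpressionMatrix(v, sampleIds = ids, geneIds = geneIds(ref),
                   axisRole = axisRole(ref))
}

#' Per-gene cosine similarity scores (CSS)
#'
#' Column-wise cosine similarity between predicted and observed spot
#' expression; zero columns score 0 by convention.
#'
#' @param pred,obs spots x genes matrices or [ExpressionMatrix-class]
#'   objects of identical shape.
#' @return Named numeric vector in `[-1, 1]`.
#' @export
cssPerGene <- function(pred, obs) {
  P <- .coerceSpotMatrix(pred)
  Y <- .coerceSpotMatrix(obs)
  if (!all(dim(P) == dim(Y))) stop("pred and obs must have identical shapes")
  setNames(.colCosine(P, Y), colnames(P))
}

#' Bootstrap variance of per-gene imputation scores
#'
#' Post hoc uncertainty target: the fitted model translates `nSim`
#' locally bootstrapped references; each prediction is scored per gene
#' against the observed ST data with [cssPerGene()], and the unbiased
#' (n-1 denominator) variance of the scores is returned per gene.  The
#' model is NOT refitted per bootstrap.
#'
#' @param model fitted [MappingModel-class].
#' @param ref reference [ExpressionMatrix-class] (cells; pre-aggregation
#'   for cluster-mode models).
#' @param st observed spatial [ExpressionMatrix-class].
#' @param labels cluster labels for the bootstrap (and, for cluster-mode
#'   models, the aggregation).
#' @param nSim number of bootstrap replicates (default 20, must be >= 2).
#' @param seed integer seed; the per-replicate seeds are drawn from it so
#'   bootstrap randomness is isolated from training randomness.
#' @return Named numeric vector of per-gene score variances over the genes
#'   shared by `ref` and `st`.
#' @export
scoreVariance <- function(model, ref, st, labels, nSim = 20L, seed = 1L) {
  stopifnot(is(model, "MappingModel"))
  nSim <- as.integer(nSim)
  if (nSim < 2L) stop("nSim must be >= 2")
  al <- alignGenes(ref, st)
  refA <- ref[, al$refIndex]
  stA <- st[, al$stIndex]
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, nSim)
  scores <- matrix(NA_real_, nSim, length(al$gene),
                   dimnames = list(NULL, al$gene))
  for (s in seq_len(nSim)) {
    boot <- localBootstrap(refA, labels, seed = seeds[s])
    input <- if (model@clusterMode) aggregateByCluster(boot, labels) else boot
    pred <- translateExpression(model, input)
    scores[s, ] <- cssPerGene(pred, stA)
  }
  apply(scores, 2L, var)
}

#' Per-gene features of the uncertainty regression
#'
#' Computes the three predictors: reference count sparsity, and the mean
#' and variance over spots of each gene's imputed profile (prediction from
#' the original, non-bootstrapped reference).
#'
#' @param refCounts raw count [ExpressionMatrix-class] (for sparsity).
#' @param pred predicted spot expression [ExpressionMatrix-class].
#' @return data.frame with columns `gene`, `sparsity`, `predMean`,
#'   `predVar`.
#' @export
uncertaintyFeatures <- function(refCounts, pred) {
  stopifnot(is(refCounts, "ExpressionMatrix"), is(pred, "ExpressionMatrix"))
  genes <- geneIds(pred)
  sp <- geneSparsity(refCounts)
  if (!all(genes %in% names(sp)))
    stop("some predicted genes are absent from the count matrix")
  P <- exprValues(pred)
  data.frame(
    gene = genes,
    sparsity = as.numeric(sp[genes]),
    predMean = colMeans(P),
    predVar = apply(P, 2L, var),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Fit the per-gene uncertainty regression
#'
#' Ordinary least squares of the bootstrap score variance on the three
#' gene features (intercept + sparsity + predMean + predVar); features are
#' deliberately not standardized.
#'
#' @param features data.frame from [uncertaintyFeatures()].
#' @param variances named (or aligned) numeric vector of per-gene bootstrap
#'   score variances, `>= 0`.
#' @return An [UncertaintyModel-class].
#' @export
fitUncertainty <- function(features, variances) {
  if (!all(c("sparsity", "predMean", "predVar") %in% names(features)))
    stop("features must have columns sparsity, predMean, predVar")
  if (!is.null(names(variances)) && "gene" %in% names(features)) {
    if (!all(features$gene %in% names(variances)))
      stop("variances missing for some feature genes")
    variances <- variances[features$gene]
  }
  if (length(variances) != nrow(features))
    stop("features and variances must cover the same genes")
  if (nrow(features) < 5L)
    stop("need at least 5 training genes")
  if (any(variances < 0)) stop("variances must be >= 0")
  df <- data.frame(y = as.numeric(variances), sparsity = features$sparsity,
                   predMean = features$predMean, predVar = features$predVar)
  fit <- lm(y ~ sparsity + predMean + predVar, data = df)
  beta <- coef(fit)
  if (anyNA(beta))
    stop("rank-deficient design; supply more (or more varied) training genes")
  X <- stats::model.matrix(fit)
  sigma2 <- sum(stats::residuals(fit)^2) / (nrow(X) - ncol(X))
  se <- sqrt(diag(chol2inv(chol(crossprod(X)))) * sigma2)
  tss <- sum((df$y - mean(df$y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  new("UncertaintyModel", beta = unname(beta), se = unname(se),
      r2 = as.numeric(r2))
}

#' Predict per-gene uncertainty for new genes
#'
#' Applies the fitted linear model to gene features and ranks the scores
#' into quantiles (average ranks on ties).
#'
#' @param model an [UncertaintyModel-class].
#' @param features data.frame from [uncertaintyFeatures()].
#' @return data.frame with columns `gene`, `score`, `quantile`.
#' @export
predictUncertainty <- function(model, features) {
  stopifnot(is(model, "UncertaintyModel"))
  b <- model@beta
  score <- b[1] + b[2] * features$sparsity + b[3] * features$predMean +
    b[4] * features$predVar
  data.frame(
    gene = features$gene,
    score = as.numeric(score),
    quantile = rank(score, ties.method = "average") / length(score),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Select reliable genes by the knee of the CSS-vs-uncertainty curve
#'
#' Builds the curve of median CSS over genes whose uncertainty quantile is
#' at most `t`, for `t` on the quantile grid, then picks a threshold.
#' `method = "knee"` (default) takes the grid point with maximal
#' perpendicular distance to the chord joining the curve endpoints (a flat
#' curve falls back to the most stringent grid point); `method = "cv"`
#' splits the genes into folds and picks the quantile maximizing the mean
#' held-out median CSS.
#'
#' @param css named per-gene score (e.g. held-out CSS).
#' @param uncertainty data.frame from [predictUncertainty()] over the same
#'   genes.
#' @param grid quantile grid (default 0.1 to 1 by 0.1).
#' @param method `"knee"` or `"cv"`.
#' @param nFolds folds for `method = "cv"` (default 5).
#' @param seed seed for the CV fold split.
#' @return List with `threshold` (selected quantile), `selected`
#'   (gene ids at or below it), and `curve` (data.frame `quantile`,
#'   `medianCss`, `nGenes`).
#' @export
selectGenesByKnee <- function(css, uncertainty, grid = seq(0.1, 1, by = 0.1),
                              method = c("knee", "cv"), nFolds = 5L,
                              seed = 1L) {
  method <- match.arg(method)
  if (is.null(names(css))) names(css) <- uncertainty$gene
  common <- intersect(names(css), uncertainty$gene)
  if (length(common) < 3L) stop("need CSS and uncertainty for >= 3 genes")
  q <- setNames(uncertainty$quantile, uncertainty$gene)[common]
  css <- css[common]
  curve <- data.frame(
    quantile = grid,
    medianCss = vapply(grid, function(t) {
      sel <- css[q <= t + 1e-12]
      if (length(sel)) median(sel) else NA_real_
    }, numeric(1)),
    nGenes = vapply(grid, function(t) sum(q <= t + 1e-12), integer(1))
  )
  usable <- which(!is.na(curve$medianCss))
  if (length(usable) < 3L) stop("fewer than 3 grid points contain genes")

  if (method == "knee") {
    threshold <- .kneePoint(curve$quantile[usable], curve$medianCss[usable])
  } else {
    set.seed(as.integer(seed))
    fold <- sample(rep_len(seq_len(nFolds), length(common)))
    perf <- vapply(grid, function(t) {
      med <- vapply(seq_len(nFolds), function(k) {
        sel <- css[fold == k & q <= t + 1e-12]
        if (length(sel)) median(sel) else NA_real_
      }, numeric(1))
      mean(med, na.rm = TRUE)
    }, numeric(1))
    threshold <- grid[which.max(perf)]
  }
  list(threshold = threshold,
       selected = names(q)[q <= threshold + 1e-12],
       curve = curve)
}

# knee = point of maximal perpendicular distance to the endpoint chord;
# ties and flat curves resolve to the smallest (most stringent) quantile
.kneePoint <- function(x, y) {
  x0 <- x[1]; y0 <- y[1]
  x1 <- x[length(x)]; y1 <- y[length(y)]
  dx <- x1 - x0; dy <- y1 - y0
  nrm <- sqrt(dx^2 + dy^2)
  if (nrm == 0) return(x[1])
  d <- abs(dy * (x - x0) - dx * (y - y0)) / nrm
  if (max(d) <= 1e-12) return(x[1])
  x[which.max(d)]
}
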