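# Translation model surface: constraint materialization, prediction,
# losses, imputation and modality translation.  The trainer lives in
# train.R.

#' Materialize the constrained cell-to-spot mapping
#'
#' Applies the parameter constraints and returns the effective nonnegative
#' mapping matrix `W` (spots x cells, or spots x clusters in cluster mode):
#' full mode squares `rawW` elementwise; low-rank mode takes the
#' row-softmax of `rawU` times the transpose of `rawV^2`, with squared V
#' entries clamped to `vClip` when set.
#'
#' @param model a [MappingModel-class].
#' @return Nonnegative numeric matrix.
#' @export
materializeMapping <- function(model) {
  stopifnot(is(model, "MappingModel"))
  if (model@mode == "full") {
    W <- model@rawW^2
  } else {
    U <- .softmaxRows(model@rawU)
    V <- model@rawV^2
    if (!is.na(model@vClip)) V <- pmin(V, model@vClip)
    W <- U %*% t(V)
  }
  if (length(model@spotIds) == nrow(W)) rownames(W) <- model@spotIds
  if (length(model@cellIds) == ncol(W)) colnames(W) <- model@cellIds
  W
}

.softmaxRows <- function(M) {
  mx <- apply(M, 1L, max)
  E <- exp(M - mx)
  E / rowSums(E)
}

#' Translate a reference profile into spatial space
#'
#' Computes `Yhat = W %*% X` where `W` is the materialized mapping and `X`
#' the reference (cells x genes, or cluster pseudobulks x genes for
#' cluster-mode models).
#'
#' @param model a [MappingModel-class].
#' @param ref [ExpressionMatrix-class] whose rows match the model's column
#'   axis.
#' @return `ExpressionMatrix` of predicted spot expression (spots x genes).
#' @export
translateExpression <- function(model, ref) {
  stopifnot(is(model, "MappingModel"), is(ref, "ExpressionMatrix"))
  W <- materializeMapping(model)
  X <- exprValues(ref)
  if (ncol(W) != nrow(X))
    stop(sprintf("mapping has %d columns but reference has %d rows",
                 ncol(W), nrow(X)))
  sp <- if (length(model@spotIds) == nrow(W)) model@spotIds else
    sprintf("spot_%d", seq_len(nrow(W)))
  ExpressionMatrix(W %*% X, sampleIds = sp, geneIds = geneIds(ref),
                   axisRole = "spots")
}

#' Impute unprobed genes in spatial space
#'
#' Restricts the reference to `genes` and applies the fitted translation,
#' yielding predicted spatial profiles for genes never probed on the ST
#' platform.
#'
#' @param model fitted [MappingModel-class].
#' @param ref the full reference [ExpressionMatrix-class]; for cluster-mode
#'   models either pass cluster pseudobulks directly or supply `labels`.
#' @param genes character vector of genes to impute (subset of
#'   `geneIds(ref)`); may be empty.
#' @param labels optional cluster labels used to aggregate `ref` for
#'   cluster-mode models.
#' @return `ExpressionMatrix`, spots x `length(genes)`.
#' @export
imputeGenes <- function(model, ref, genes, labels = NULL) {
  stopifnot(is(model, "MappingModel"), is(ref, "ExpressionMatrix"))
  if (!model@fitted) stop("model is not fitted")
  missing <- setdiff(genes, geneIds(ref))
  if (length(missing))
    stop("genes absent from the reference: ", paste(missing, collapse = ", "))
  if (model@clusterMode && !is.null(labels))
    ref <- aggregateByCluster(ref, labels)
  translateExpression(model, ref[, match(genes, geneIds(ref))])
}

#' Translate an arbitrary per-cell feature modality into spatial space
#'
#' Applies the fitted linear map to any feature matrix defined over the
#' same cells (e.g. unspliced/spliced counts for downstream RNA-velocity
#' analysis).  Only cell-mode models carry a per-cell mapping; cluster-mode
#' models are rejected.
#'
#' @param model fitted cell-mode [MappingModel-class].
#' @param features [ExpressionMatrix-class] or matrix whose rows are the
#'   same cells, in the same order, the model was fitted on.
#' @return `ExpressionMatrix`, spots x features.
#' @export
translateFeatures <- function(model, features) {
  stopifnot(is(model, "MappingModel"))
  if (model@clusterMode)
    stop("cluster-mode models have no per-cell mapping; refit in cell mode")
  if (!is(features, "ExpressionMatrix"))
    features <- ExpressionMatrix(as.matrix(features), axisRole = "cells")
  W <- materializeMapping(model)
  if (nrow(exprValues(features)) != ncol(W))
    stop(sprintf("feature matrix has %d rows but the model maps %d cells",
                 nrow(exprValues(features)), ncol(W)))
  translateExpression(model, features)
}

# cosine of matching columns; zero vectors yield similarity 0 by convention
.colCosine <- function(A, B) {
  na <- sqrt(colSums(A^2))
  nb <- sqrt(colSums(B^2))
  dt <- colSums(A * B)
  ifelse(na > 0 & nb > 0, dt / (na * nb), 0)
}

#' Dual cosine translation loss
#'
#' `l_trans = mean_i(1 - cos(pred_i., obs_i.)) + mean_j(1 - cos(pred_.j, obs_.j))`:
#' the spot-wise plus the gene-wise mean cosine dissimilarity, capturing
#' both expression distributions.  Cosine with a zero vector is defined as
#' 0 (maximal penalty for that term); the loss lies in `[0, 4]`.
#'
#' @param pred,obs spots x genes matrices or [ExpressionMatrix-class]
#'   objects of identical shape.
#' @return Nonnegative scalar.
#' @export
translationLoss <- function(pred, obs) {
  P <- .coerceSpotMatrix(pred)
  Y <- .coerceSpotMatrix(obs)
  if (!all(dim(P) == dim(Y))) stop("pred and obs must have identical shapes")
  mean(1 - .colCosine(t(P), t(Y))) + mean(1 - .colCosine(P, Y))
}

#' Total training loss
#'
#' `l_total = l_trans + lambda * l_spa`, where the spatial term is the mean
#' squared difference of per-gene Moran's I between predicted and observed
#' expression.  With `lambdaSpa = 0` this is exactly [translationLoss()].
#'
#' @param pred,obs spots x genes matrices or [ExpressionMatrix-class]
#'   objects.
#' @param graph [SpatialGraph-class] over the spots; required when
#'   `lambdaSpa > 0`.
#' @param lambdaSpa nonnegative spatial-regularization weight.
#' @return Scalar loss.
#' @export
totalLoss <- function(pred, obs, graph = NULL, lambdaSpa = 0) {
  if (lambdaSpa < 0) stop("lambdaSpa must be >= 0")
  lt <- translationLoss(pred, obs)
  if (lambdaSpa == 0) return(lt)
  if (is.null(graph)) stop("lambdaSpa > 0 requires a spatial graph")
  lt + lambdaSpa * spatialRegLoss(pred, obs, graph)
}
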