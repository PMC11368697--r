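#' @import methods
#' @importFrom stats median quantile rnorm rpois runif sd var lm coef
#'   p.adjust dist cutree complete.cases setNames predict cor
#' @importFrom utils head read.delim write.table
NULL

# ---------------------------------------------------------------------------
# ExpressionMatrix
# ---------------------------------------------------------------------------

#' Expression matrix with axis labels
#'
#' Container for a samples x genes expression matrix.  The sample axis can
#' play either of two roles: `"cells"` for a single-cell reference or
#' `"spots"` for a spatial transcriptomics (ST) dataset.  Values are stored
#' densely; sparse input (any [Matrix::Matrix] subclass) is densified on
#' construction.
#'
#' @slot values numeric matrix, samples x genes, finite and nonnegative
#'   on the raw scale.
#' @slot sampleIds character, unique sample (cell/spot) identifiers.
#' @slot geneIds character, unique gene identifiers.
#' @slot axisRole `"cells"` or `"spots"`.
#'
#' @aliases ExpressionMatrix-class
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
  representation(
    values = "matrix",
    sampleIds = "character",
    geneIds = "character",
    axisRole = "character"
  )
)

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "'values' must be numeric")
  if (nrow(v) != length(object@sampleIds))
    msg <- c(msg, "nrow(values) must equal length(sampleIds)")
  if (ncol(v) != length(object@geneIds))
    msg <- c(msg, "ncol(values) must equal length(geneIds)")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "duplicate sampleIds")
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "duplicate geneIds")
  if (length(object@axisRole) != 1L ||
      !object@axisRole %in% c("cells", "spots"))
    msg <- c(msg, "axisRole must be 'cells' or 'spots'")
  if (length(v) && any(!is.finite(v)))
    msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix (samples x genes) or a sparse
#'   [Matrix::Matrix]; dimnames are used as default ids.
#' @param sampleIds,geneIds character identifiers; default to the dimnames
#'   of `values`, or generated `sample_i` / `gene_j` names.
#' @param axisRole `"cells"` (reference) or `"spots"` (spatial data).
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- ExpressionMatrix(matrix(1:6, 2, 3), axisRole = "cells")
#' dim(m)
#' @export
ExpressionMatrix <- function(values, sampleIds = NULL, geneIds = NULL,
                             axisRole = c("cells", "spots")) {
  axisRole <- match.arg(axisRole)
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sampleIds))
    sampleIds <- rownames(values) %||% sprintf("sample_%d", seq_len(nrow(values)))
  if (is.null(geneIds))
    geneIds <- colnames(values) %||% sprintf("gene_%d", seq_len(ncol(values)))
  dimnames(values) <- list(sampleIds, geneIds)
  new("ExpressionMatrix", values = values,
      sampleIds = as.character(sampleIds), geneIds = as.character(geneIds),
      axisRole = axisRole)
}

#' @describeIn ExpressionMatrix numeric matrix of expression values.
#' @param x an `ExpressionMatrix`.
#' @export
exprValues <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  x@values
}

#' @describeIn ExpressionMatrix sample (cell/spot) identifiers.
#' @export
sampleIds <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  x@sampleIds
}

#' @describeIn ExpressionMatrix gene identifiers.
#' @export
geneIds <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  x@geneIds
}

#' @describeIn ExpressionMatrix axis role of the sample dimension.
#' @export
axisRole <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  x@axisRole
}

#' @export
setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

#' Subset an ExpressionMatrix
#'
#' @param x an `ExpressionMatrix`.
#' @param i,j sample and gene indices (integer, logical or character).
#' @param ... ignored.
#' @param drop ignored; the result is always an `ExpressionMatrix`.
#' @export
setMethod("[", "ExpressionMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  ExpressionMatrix(x@values[i, j, drop = FALSE], axisRole = x@axisRole)
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d %s x %d genes\n",
              nrow(object@values), object@axisRole, ncol(object@values)))
  nz <- mean(object@values == 0)
  cat(sprintf("  zero fraction: %.3f\n", nz))
  cat("  sampleIds:", paste(head(object@sampleIds, 3), collapse = ", "),
      if (length(object@sampleIds) > 3) "..." else "", "\n")
  cat("  geneIds:  ", paste(head(object@geneIds, 3), collapse = ", "),
      if (length(object@geneIds) > 3) "..." else "", "\n")
})

# ---------------------------------------------------------------------------
# SpatialGraph
# ---------------------------------------------------------------------------

#' Spatial neighborhood graph over ST spots
#'
#' Sparse nonnegative adjacency built from spot coordinates with
#' [buildSpatialGraph()].  The weight matrix has a zero diagonal and, when
#' `rowNormalized`, every nonempty row sums to one.
#'
#' @slot weights sparse nonnegative Ns x Ns weight matrix ([Matrix::dgCMatrix]).
#' @slot k neighbor count used at construction.
#' @slot scheme distance-to-weight scheme.
#' @slot rowNormalized logical flag.
#'
#' @aliases SpatialGraph-class
#' @exportClass SpatialGraph
setClass("SpatialGraph",
  representation(
    weights = "Matrix",
    k = "integer",
    scheme = "character",
    rowNormalized = "logical"
  )
)

setValidity("SpatialGraph", function(object) {
  w <- object@weights
  msg <- character()
  if (nrow(w) != ncol(w)) msg <- c(msg, "weights must be square")
  dg <- Matrix::diag(w)
  if (any(dg != 0)) msg <- c(msg, "diagonal must be zero")
  if (any(w@x < 0)) msg <- c(msg, "weights must be nonnegative")
  if (object@rowNormalized) {
    rs <- Matrix::rowSums(w)
    bad <- rs > 0 & abs(rs - 1) > 1e-8
    if (any(bad)) msg <- c(msg, "nonempty rows must sum to 1 after normalization")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SpatialGraph sparse weight matrix.
#' @param graph a `SpatialGraph`.
#' @export
graphWeights <- function(graph) {
  stopifnot(is(graph, "SpatialGraph"))
  graph@weights
}

#' @describeIn SpatialGraph total weight sum S0 (denominator of Moran's I).
#' @export
totalWeight <- function(graph) {
  stopifnot(is(graph, "SpatialGraph"))
  sum(graph@weights)
}

setMethod("show", "SpatialGraph", function(object) {
  cat(sprintf("SpatialGraph: %d spots, k = %d, scheme = %s%s\n",
              nrow(object@weights), object@k, object@scheme,
              if (object@rowNormalized) " (row-normalized)" else ""))
  cat(sprintf("  edges: %d, S0 = %.4f\n",
              length(object@weights@x), sum(object@weights)))
})

# ---------------------------------------------------------------------------
# MappingModel
# ---------------------------------------------------------------------------

#' Cell-to-spot translation model
#'
#' Parameters of the linear translation from a reference (cells or cluster
#' pseudobulks) to ST spots.  Two parameterizations are supported:
#' \describe{
#'   \item{full}{`W = rawW^2` elementwise, a nonnegative Ns x Nc matrix.}
#'   \item{lowrank}{`W = softmax_rows(rawU) %*% t(clip(rawV^2, vClip))` with
#'     `rawU` Ns x K and `rawV` Nc x K; spot loadings are row-stochastic and
#'     cell loadings nonnegative.}
#' }
#' Cluster-mode models are full-mode models fitted over cluster pseudobulks
#' (`clusterMode = TRUE`); their column axis indexes clusters, not cells.
#'
#' @slot mode `"full"` or `"lowrank"`.
#' @slot clusterMode logical; TRUE when the column axis is clusters.
#' @slot K integer latent dimension (lowrank only; 0 for full).
#' @slot rawU,rawV,rawW unconstrained parameter matrices (unused slots are
#'   0 x 0).
#' @slot vClip optional positive clamp on the constrained V entries
#'   (`NA_real_` when off).
#' @slot geneIds genes used in training.
#' @slot cellIds column-axis identifiers (cells or cluster names).
#' @slot spotIds spot identifiers (rows of W).
#' @slot fitted logical.
#' @slot trace data.frame of per-epoch losses (epoch, total, trans, spa).
#' @slot config list echoing the training configuration.
#'
#' @aliases MappingModel-class
#' @exportClass MappingModel
setClass("MappingModel",
  representation(
    mode = "character",
    clusterMode = "logical",
    K = "integer",
    rawU = "matrix",
    rawV = "matrix",
    rawW = "matrix",
    vClip = "numeric",
    geneIds = "character",
    cellIds = "character",
    spotIds = "character",
    fitted = "logical",
    trace = "data.frame",
    config = "list"
  ),
  prototype(
    clusterMode = FALSE, K = 0L,
    rawU = matrix(0, 0, 0), rawV = matrix(0, 0, 0), rawW = matrix(0, 0, 0),
    vClip = NA_real_, fitted = FALSE,
    trace = data.frame(), config = list()
  )
)

setValidity("MappingModel", function(object) {
  msg <- character()
  if (!object@mode %in% c("full", "lowrank"))
    msg <- c(msg, "mode must be 'full' or 'lowrank'")
  if (object@mode == "full") {
    if (length(object@rawW) == 0)
      msg <- c(msg, "full mode requires rawW")
    if (length(object@rawU) || length(object@rawV))
      msg <- c(msg, "full mode must not carry rawU/rawV")
  } else {
    if (length(object@rawU) == 0 || length(object@rawV) == 0)
      msg <- c(msg, "lowrank mode requires rawU and rawV")
    if (length(object@rawW))
      msg <- c(msg, "lowrank mode must not carry rawW")
    if (length(object@rawU) && length(object@rawV) &&
        ncol(object@rawU) != ncol(object@rawV))
      msg <- c(msg, "rawU and rawV must share the latent dimension K")
  }
  if (!is.na(object@vClip) && object@vClip <= 0)
    msg <- c(msg, "vClip must be positive when set")
  if (length(msg)) msg else TRUE
})

#' Construct a MappingModel from raw parameters
#'
#' Mainly useful for testing and for building models with hand-fixed
#' parameters (e.g. a low-rank model whose constrained cell loadings are a
#' cluster indicator).  [fitTranslation()] is the usual entry point.
#'
#' @param mode `"full"` or `"lowrank"`.
#' @param rawW unconstrained Ns x Nc matrix (full mode); the materialized
#'   mapping is its elementwise square.
#' @param rawU,rawV unconstrained Ns x K and Nc x K matrices (lowrank mode).
#' @param vClip optional positive clamp applied to the squared V entries.
#' @param geneIds,cellIds,spotIds optional axis identifiers.
#' @param clusterMode logical; TRUE when columns index clusters.
#' @param fitted logical flag.
#' @return A [MappingModel-class].
#' @export
newMappingModel <- function(mode = c("lowrank", "full"), rawW = NULL,
                            rawU = NULL, rawV = NULL, vClip = NA_real_,
                            geneIds = character(), cellIds = character(),
                            spotIds = character(), clusterMode = FALSE,
                            fitted = TRUE) {
  mode <- match.arg(mode)
  empty <- matrix(0, 0, 0)
  new("MappingModel", mode = mode, clusterMode = clusterMode,
      K = if (mode == "lowrank") ncol(rawU) else 0L,
      rawU = if (is.null(rawU)) empty else rawU,
      rawV = if (is.null(rawV)) empty else rawV,
      rawW = if (is.null(rawW)) empty else rawW,
      vClip = as.numeric(vClip),
      geneIds = as.character(geneIds), cellIds = as.character(cellIds),
      spotIds = as.character(spotIds), fitted = fitted)
}

#' @describeIn newMappingModel per-epoch loss trace of a fitted model.
#' @param model a `MappingModel`.
#' @export
lossTrace <- function(model) {
  stopifnot(is(model, "MappingModel"))
  model@trace
}

setMethod("show", "MappingModel", function(object) {
  dims <- if (object@mode == "full") dim(object@rawW) else
    c(nrow(object@rawU), nrow(object@rawV))
  cat(sprintf("MappingModel (%s%s): %d spots x %d %s%s\n",
              object@mode, if (object@clusterMode) ", cluster mode" else "",
              dims[1], dims[2],
              if (object@clusterMode) "clusters" else "cells",
              if (object@mode == "lowrank") sprintf(", K = %d", object@K) else ""))
  if (!is.na(object@vClip)) cat(sprintf("  vClip = %.3g\n", object@vClip))
  cat(sprintf("  fitted: %s; training genes: %d\n",
              object@fitted, length(object@geneIds)))
  if (nrow(object@trace))
    cat(sprintf("  final loss: total %.5f (trans %.5f, spa %.5f)\n",
                object@trace$total[nrow(object@trace)],
                object@trace$trans[nrow(object@trace)],
                object@trace$spa[nrow(object@trace)]))
})

# ---------------------------------------------------------------------------
# UncertaintyModel
# ---------------------------------------------------------------------------

#' Per-gene imputation-uncertainty regression
#'
#' Linear model predicting the bootstrap variance of a gene's cosine
#' similarity score from three features: reference count sparsity, and the
#' mean and variance over spots of the gene's imputed profile:
#' `uncertainty = beta0 + beta1 * sparsity + beta2 * predMean + beta3 * predVar`.
#'
#' @slot beta numeric(4) coefficients (intercept, sparsity, predMean, predVar).
#' @slot se numeric(4) standard errors.
#' @slot r2 R-squared on the training genes.
#' @slot featureNames the three feature names, fixed.
#'
#' @aliases UncertaintyModel-class
#' @exportClass UncertaintyModel
setClass("UncertaintyModel",
  representation(beta = "numeric", se = "numeric", r2 = "numeric",
                 featureNames = "character"),
  prototype(featureNames = c("sparsity", "predMean", "predVar"))
)

setValidity("UncertaintyModel", function(object) {
  if (length(object@beta) != 4L || any(!is.finite(object@beta)))
    "beta must be 4 finite coefficients" else TRUE
})

#' @describeIn UncertaintyModel coefficient vector (beta0..beta3).
#' @param object an `UncertaintyModel`.
#' @export
uncertaintyCoef <- function(object) {
  stopifnot(is(object, "UncertaintyModel"))
  setNames(object@beta, c("(Intercept)", object@featureNames))
}

#' @describeIn UncertaintyModel coefficient standard errors.
#' @export
uncertaintySE <- function(object) {
  stopifnot(is(object, "UncertaintyModel"))
  setNames(object@se, c("(Intercept)", object@featureNames))
}

#' @describeIn UncertaintyModel training R-squared.
#' @export
uncertaintyR2 <- function(object) {
  stopifnot(is(object, "UncertaintyModel"))
  object@r2
}

setMethod("show", "UncertaintyModel", function(object) {
  cat("UncertaintyModel: variance ~ sparsity + predMean + predVar\n")
  b <- uncertaintyCoef(object)
  cat("  ", paste(sprintf("%s = %.4g", names(b), b), collapse = ", "), "\n")
  cat(sprintf("  training R^2 = %.3f\n", object@r2))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
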