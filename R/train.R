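# Gradient training of the translation model: forward losses, analytic
# gradients of the dual cosine loss and of the Moran's I regularizer, and
# an AdamW (decoupled weight decay) optimizer.  Written as vectorized
# matrix algebra; the analytic gradients are verified against finite
# differences in the test suite.

# Gradient of the translation loss w.r.t. the prediction matrix P.
# For a row pair (p, y): d/dp [1 - cos(p, y)] = -(y/(|p||y|) - cos * p/|p|^2);
# rows/columns where either vector is zero use the cos := 0 convention and
# receive a zero (sub)gradient.
.transLossGrad <- function(P, Y) {
  ns <- nrow(P); ng <- ncol(P)
  npr <- sqrt(rowSums(P^2)); nyr <- sqrt(rowSums(Y^2))
  dotr <- rowSums(P * Y)
  okr <- npr > 0 & nyr > 0
  cr <- ifelse(okr, dotr / (npr * nyr), 0)
  npc <- sqrt(colSums(P^2)); nyc <- sqrt(colSums(Y^2))
  dotc <- colSums(P * Y)
  okc <- npc > 0 & nyc > 0
  cc <- ifelse(okc, dotc / (npc * nyc), 0)
  loss <- mean(1 - cr) + mean(1 - cc)

  G <- matrix(0, ns, ng)
  if (any(okr)) {
    a <- ifelse(okr, 1 / (npr * nyr), 0)
    b <- ifelse(okr, cr / npr^2, 0)
    G <- G - (Y * a - P * b) / ns
  }
  if (any(okc)) {
    a <- ifelse(okc, 1 / (npc * nyc), 0)
    b <- ifelse(okc, cc / npc^2, 0)
    G <- G - (sweep(Y, 2L, a, "*") - sweep(P, 2L, b, "*")) / ng
  }
  list(loss = loss, grad = G)
}

# Loss and gradient of the Moran's I MSE regularizer w.r.t. P.
# I_j = (n/s0) z_j' W z_j / (z_j' z_j), z_j = P[,j] - mean;
# dI/dz = (n/s0) [ (W + W') z * den - 2 z * num ] / den^2, then re-centered
# (the centering operator is its own adjoint).  Zero-variance genes take
# I := 0 with zero gradient.
.spaLossGrad <- function(P, W, Wt, s0, Iobs) {
  n <- nrow(P); ng <- ncol(P)
  Z <- sweep(P, 2L, colMeans(P))
  Q <- as.matrix(W %*% Z)
  Qt <- as.matrix(Wt %*% Z)
  num <- colSums(Z * Q)
  den <- colSums(Z^2)
  ok <- den > .Machine$double.eps * n
  denS <- pmax(den, .Machine$double.eps)
  Ihat <- ifelse(ok, (n / s0) * num / denS, 0)
  diffI <- Ihat - Iobs
  loss <- mean(diffI^2)

  coefA <- ifelse(ok, (n / s0) / denS, 0)              # multiplies (Q + Qt)
  coefB <- ifelse(ok, (n / s0) * 2 * num / denS^2, 0)  # multiplies z
  Gz <- sweep(Q + Qt, 2L, coefA, "*") - sweep(Z, 2L, coefB, "*")
  Gz <- sweep(Gz, 2L, (2 / ng) * diffI, "*")
  G <- sweep(Gz, 2L, colMeans(Gz))
  list(loss = loss, grad = G)
}

.adamwInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamwStep <- function(params, grads, state, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / c1
    vhat <- state$v[[nm]] / c2
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + wd * params[[nm]])
  }
  list(params = params, state = state)
}

# forward pass: returns effective W, prediction P, and constraint
# intermediates needed for the backward pass
.forwardMapping <- function(params, mode, vClip, X) {
  if (mode == "full") {
    W <- params$rawW^2
    list(W = W, P = W %*% X)
  } else {
    U <- .softmaxRows(params$rawU)
    Vsq <- params$rawV^2
    V <- if (!is.na(vClip)) pmin(Vsq, vClip) else Vsq
    W <- U %*% t(V)
    list(W = W, P = W %*% X, U = U, V = V, Vsq = Vsq)
  }
}

# backward pass: gradient of the loss w.r.t. raw parameters given dL/dP
.backwardMapping <- function(G, fw, params, mode, vClip, X) {
  dW <- G %*% t(X)
  if (mode == "full") {
    list(rawW = 2 * params$rawW * dW)
  } else {
    dU <- dW %*% fw$V
    dV <- t(dW) %*% fw$U
    if (!is.na(vClip)) dV[fw$Vsq >= vClip] <- 0  # clamp is flat beyond vClip
    gRawV <- 2 * params$rawV * dV
    gRawU <- fw$U * (dU - rowSums(dU * fw$U))    # softmax Jacobian per row
    list(rawU = gRawU, rawV = gRawV)
  }
}

#' Fit a translation model by gradient descent
#'
#' Trains the cell-to-spot mapping on the genes shared between reference
#' and ST data, minimizing the dual cosine translation loss plus, when
#' `lambdaSpa > 0`, the Moran's I regularizer, with an AdamW optimizer
#' (full batch, decoupled weight decay).  The four canonical
#' configurations are: low-rank cell mode with/without spatial
#' regularization, and full cluster mode with/without it.
#'
#' @param ref reference [ExpressionMatrix-class] (cells x genes).
#' @param st observed spatial [ExpressionMatrix-class] (spots x genes).
#'   Genes are aligned to the ST order via [alignGenes()] internally.
#' @param mode `"lowrank"` (cell mode, default), `"cluster"` (full mapping
#'   over cluster pseudobulks; requires `labels`), or `"full"` (full
#'   mapping over individual cells).
#' @param labels cluster labels for `mode = "cluster"`.
#' @param graph [SpatialGraph-class] over the ST spots; required when
#'   `lambdaSpa > 0`.
#' @param K latent dimension of the low-rank factorization (default 256).
#' @param lambdaSpa spatial regularization weight (default 0 = off; 1 is
#'   the standard strength when on).
#' @param vClip optional positive clamp on squared V entries (guards
#'   against overfitting on some datasets; default off).
#' @param epochs training epochs (default 2000).
#' @param learningRate AdamW learning rate (default 0.01).
#' @param weightDecay decoupled weight decay (default 0.01).
#' @param seed integer seed for parameter initialization.
#' @param initSd standard deviation of the Gaussian parameter init.
#' @param verbose print loss every 200 epochs.
#' @return A fitted [MappingModel-class]; its per-epoch loss trace is
#'   available via [lossTrace()].
#' @export
fitTranslation <- function(ref, st, mode = c("lowrank", "cluster", "full"),
                           labels = NULL, graph = NULL, K = 256L,
                           lambdaSpa = 0, vClip = NULL, epochs = 2000L,
                           learningRate = 0.01, weightDecay = 0.01,
                           seed = 1L, initSd = 0.1, verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is(ref, "ExpressionMatrix"), is(st, "ExpressionMatrix"))
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (lambdaSpa < 0) stop("lambdaSpa must be >= 0")
  if (lambdaSpa > 0 && is.null(graph))
    stop("spatial regularization (lambdaSpa > 0) requires a spatial graph")
  vClip <- if (is.null(vClip)) NA_real_ else as.numeric(vClip)

  al <- alignGenes(ref, st)
  refA <- ref[, al$refIndex]
  stA <- st[, al$stIndex]
  clusterMode <- mode == "cluster"
  if (clusterMode) {
    if (is.null(labels)) stop("cluster mode requires cluster labels")
    refA <- aggregateByCluster(refA, labels)
  }
  X <- exprValues(refA)
  Y <- exprValues(stA)
  ns <- nrow(Y); nc <- nrow(X)
  paramMode <- if (mode == "lowrank") "lowrank" else "full"

  Wg <- NULL; Wgt <- NULL; s0 <- NULL; Iobs <- NULL
  if (lambdaSpa > 0) {
    Wg <- graph@weights
    if (nrow(Wg) != ns)
      stop(sprintf("graph has %d spots but ST has %d", nrow(Wg), ns))
    Wgt <- Matrix::t(Wg)
    s0 <- sum(Wg)
    Iobs <- as.numeric(moransI(Y, graph))
  }

  set.seed(as.integer(seed))
  params <- if (paramMode == "full") {
    list(rawW = matrix(rnorm(ns * nc, sd = initSd), ns, nc))
  } else {
    K <- as.integer(K)
    if (K < 1L) stop("K must be >= 1")
    list(rawU = matrix(rnorm(ns * K, sd = initSd), ns, K),
         rawV = matrix(rnorm(nc * K, sd = initSd), nc, K))
  }

  state <- .adamwInit(params)
  trace <- data.frame(epoch = seq_len(epochs), total = NA_real_,
                      trans = NA_real_, spa = NA_real_)
  for (ep in seq_len(epochs)) {
    fw <- .forwardMapping(params, paramMode, vClip, X)
    tl <- .transLossGrad(fw$P, Y)
    if (lambdaSpa > 0) {
      sl <- .spaLossGrad(fw$P, Wg, Wgt, s0, Iobs)
      total <- tl$loss + lambdaSpa * sl$loss
      G <- tl$grad + lambdaSpa * sl$grad
      spa <- sl$loss
    } else {
      total <- tl$loss
      G <- tl$grad
      spa <- 0
    }
    if (!is.finite(total))
      stop(sprintf(
        "non-finite loss at epoch %d (trans = %g, spa = %g); try a smaller learning rate",
        ep, tl$loss, spa))
    trace$total[ep] <- total
    trace$trans[ep] <- tl$loss
    trace$spa[ep] <- spa
    grads <- .backwardMapping(G, fw, params, paramMode, vClip, X)
    upd <- .adamwStep(params, grads, state, learningRate, weightDecay)
    params <- upd$params
    state <- upd$state
    if (verbose && (ep %% 200L == 0L || ep == 1L))
      message(sprintf("epoch %5d  total %.6f  trans %.6f  spa %.6f",
                      ep, total, tl$loss, spa))
  }

  model <- newMappingModel(
    mode = paramMode,
    rawW = params$rawW, rawU = params$rawU, rawV = params$rawV,
    vClip = vClip, geneIds = al$gene, cellIds = sampleIds(refA),
    spotIds = sampleIds(stA), clusterMode = clusterMode, fitted = TRUE)
  model@trace <- trace
  model@config <- list(mode = mode, K = if (paramMode == "lowrank") K else NA,
                       lambdaSpa = lambdaSpa, vClip = vClip, epochs = epochs,
                       learningRate = learningRate, weightDecay = weightDecay,
                       seed = as.integer(seed), initSd = initSd)
  model
}
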