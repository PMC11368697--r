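test_that("constraint materialization: squares, softmax, clipping", {
  # elementwise square for V
  m <- newMappingModel("lowrank",
                       rawU = matrix(0, 1, 2),
                       rawV = matrix(c(-2, 3), 1, 2))
  W <- materializeMapping(m)  # uniform softmax row x squared V row (4, 9)
  expect_equal(unname(W), matrix(0.5 * (4 + 9), 1, 1))
  # uniform softmax for an all-zero raw row
  m2 <- newMappingModel("lowrank", rawU = matrix(0, 1, 4),
                        rawV = diag(4))
  U <- spotimpute:::.softmaxRows(matrix(0, 1, 4))
  expect_equal(unname(U), matrix(0.25, 1, 4))
  # clip applied after squaring
  m3 <- newMappingModel("lowrank", rawU = matrix(c(100, 0), 1, 2),
                        rawV = matrix(c(1, 0.6), 1, 2), vClip = 0.5)
  # constrained V row should be (0.5, 0.36); pick it off via one-hot U
  expect_equal(unname(materializeMapping(m3)), matrix(0.5, 1, 1))
  m4 <- newMappingModel("full", rawW = matrix(c(-2, 0.5), 1, 2))
  expect_equal(unname(materializeMapping(m4)), matrix(c(4, 0.25), 1, 2))
})

test_that("softmax rows are row-stochastic and mappings nonnegative", {
  set.seed(31)
  m <- newMappingModel("lowrank", rawU = matrix(rnorm(40), 8, 5),
                       rawV = matrix(rnorm(30), 6, 5))
  U <- spotimpute:::.softmaxRows(m@rawU)
  expect_true(all(abs(rowSums(U) - 1) < 1e-6))
  expect_true(all(materializeMapping(m) >= 0))
})

test_that("prediction is the mapping-reference product", {
  set.seed(32)
  W <- matrix(runif(12), 4, 3)
  X <- matrix(runif(15), 3, 5)
  m <- newMappingModel("full", rawW = sqrt(W))
  ref <- ExpressionMatrix(X, axisRole = "cells")
  P <- exprValues(translateExpression(m, ref))
  # naive triple-loop oracle
  O <- matrix(0, 4, 5)
  for (i in 1:4) for (j in 1:5) for (k in 1:3)
    O[i, j] <- O[i, j] + W[i, k] * X[k, j]
  expect_equal(unname(P), O, tolerance = 1e-12)
  # identity and zero mappings
  mI <- newMappingModel("full", rawW = diag(3))
  expect_equal(unname(exprValues(translateExpression(mI, ref))), X)
  m0 <- newMappingModel("full", rawW = matrix(0, 4, 3))
  expect_true(all(exprValues(translateExpression(m0, ref)) == 0))
  expect_error(translateExpression(m, ExpressionMatrix(matrix(1, 5, 2))),
               "columns")
})

test_that("translation loss identities: zero, scale invariance, orthogonality", {
  set.seed(33)
  Y <- matrix(runif(30) + 0.1, 5, 6)
  expect_equal(translationLoss(Y, Y), 0)
  expect_equal(translationLoss(3.7 * Y, Y), 0, tolerance = 1e-12)
  # orthogonal in every row and column -> each mean term contributes 1
  A <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  B <- rbind(c(0, 1, 0, 1), c(1, 0, 1, 0))
  expect_equal(translationLoss(A, B), 2)
  expect_error(translationLoss(Y, Y[, 1:3]), "shapes")
})

test_that("total loss composes translation and spatial terms", {
  gg <- gridGraph(5, 5, k = 4)
  set.seed(34)
  Y <- matrix(runif(25 * 8), 25, 8)
  P <- Y + matrix(rnorm(200, sd = 0.3), 25, 8)
  expect_equal(totalLoss(P, Y, lambdaSpa = 0), translationLoss(P, Y))
  expect_equal(totalLoss(Y, Y, gg$graph, lambdaSpa = 2.5), 0)
  expect_equal(totalLoss(P, Y, gg$graph, lambdaSpa = 1),
               translationLoss(P, Y) + spatialRegLoss(P, Y, gg$graph),
               tolerance = 1e-12)
  # continuity in lambda at a midpoint
  expect_equal(totalLoss(P, Y, gg$graph, 0.5),
               translationLoss(P, Y) + 0.5 * spatialRegLoss(P, Y, gg$graph))
  expect_error(totalLoss(P, Y, lambdaSpa = 1), "graph")
})

test_that("analytic gradients match finite differences", {
  set.seed(35)
  coords <- cbind(runif(20), runif(20))
  g <- buildSpatialGraph(coords, k = 4)
  P <- matrix(runif(20 * 3), 20, 3)
  Y <- matrix(runif(20 * 3), 20, 3)
  Wg <- graphWeights(g); Wt <- Matrix::t(Wg); s0 <- sum(Wg)
  Iobs <- as.numeric(moransI(Y, g))
  eps <- 1e-6
  sl <- spotimpute:::.spaLossGrad(P, Wg, Wt, s0, Iobs)
  tl <- spotimpute:::.transLossGrad(P, Y)
  fdS <- fdT <- matrix(0, 20, 3)
  for (i in 1:20) for (j in 1:3) {
    Pp <- P; Pp[i, j] <- Pp[i, j] + eps
    Pm <- P; Pm[i, j] <- Pm[i, j] - eps
    fdS[i, j] <- (spatialRegLoss(Pp, Y, g) - spatialRegLoss(Pm, Y, g)) / (2 * eps)
    fdT[i, j] <- (translationLoss(Pp, Y) - translationLoss(Pm, Y)) / (2 * eps)
  }
  expect_lt(max(abs(fdS - sl$grad)) / max(abs(fdS)), 1e-4)
  expect_lt(max(abs(fdT - tl$grad)) / max(abs(fdT)), 1e-4)
  expect_equal(sl$loss, spatialRegLoss(P, Y, g), tolerance = 1e-12)
  expect_equal(tl$loss, translationLoss(P, Y), tolerance = 1e-12)
})

test_that("raw-parameter gradients (softmax, square, clip) pass FD checks", {
  set.seed(36)
  X <- matrix(runif(5 * 4), 5, 4)
  Y <- matrix(runif(6 * 4), 6, 4)
  params <- list(rawU = matrix(rnorm(6 * 3), 6, 3),
                 rawV = matrix(rnorm(5 * 3), 5, 3))
  vClip <- 0.8
  lossAt <- function(p) {
    fw <- spotimpute:::.forwardMapping(p, "lowrank", vClip, X)
    translationLoss(fw$P, Y)
  }
  fw <- spotimpute:::.forwardMapping(params, "lowrank", vClip, X)
  tl <- spotimpute:::.transLossGrad(fw$P, Y)
  gr <- spotimpute:::.backwardMapping(tl$grad, fw, params, "lowrank", vClip, X)
  eps <- 1e-6
  for (nm in names(params)) {
    fd <- params[[nm]] * 0
    for (idx in seq_along(fd)) {
      pp <- params; pp[[nm]][idx] <- pp[[nm]][idx] + eps
      pm <- params; pm[[nm]][idx] <- pm[[nm]][idx] - eps
      fd[idx] <- (lossAt(pp) - lossAt(pm)) / (2 * eps)
    }
    expect_lt(max(abs(fd - gr[[nm]])) / max(max(abs(fd)), 1e-8), 1e-4)
  }
})

test_that("training is deterministic and improves the loss", {
  sim <- smallSim(seed = 2)
  fit1 <- fitTranslation(sim$ref, sim$st, mode = "lowrank", K = 8,
                         epochs = 150, seed = 7)
  fit2 <- fitTranslation(sim$ref, sim$st, mode = "lowrank", K = 8,
                         epochs = 150, seed = 7)
  expect_identical(lossTrace(fit1), lossTrace(fit2))
  expect_identical(materializeMapping(fit1), materializeMapping(fit2))
  tr <- lossTrace(fit1)
  expect_lt(tr$total[nrow(tr)], tr$total[1])
  expect_true(all(is.finite(tr$total)))
})

test_that("cluster mode equals a low-rank model with indicator cell loadings", {
  sim <- smallSim(seed = 3)
  labs <- sim$truth$clusterLabels
  agg <- aggregateByCluster(sim$ref, labs)
  ncl <- nrow(exprValues(agg))
  ns <- nrow(exprValues(sim$st))
  set.seed(37)
  rawU <- matrix(rnorm(ns * ncl), ns, ncl)
  Weff <- spotimpute:::.softmaxRows(rawU)
  ind <- outer(as.integer(labs), seq_len(ncl), `==`) * 1  # cells x clusters
  mCls <- newMappingModel("full", rawW = sqrt(Weff), clusterMode = TRUE)
  mLR <- newMappingModel("lowrank", rawU = rawU, rawV = sqrt(ind))
  pCls <- exprValues(translateExpression(mCls, agg))
  pLR <- exprValues(translateExpression(mLR, sim$ref))
  expect_lt(max(abs(pCls - pLR)), 1e-5)
})

test_that("imputation restricts prediction to requested genes", {
  sim <- smallSim(seed = 4)
  m <- fitTranslation(sim$ref, sim$st, mode = "lowrank", K = 8,
                      epochs = 100, seed = 1)
  genes <- geneIds(sim$ref)
  imp <- imputeGenes(m, sim$ref, genes[1:5])
  full <- translateExpression(m, sim$ref)
  expect_equal(exprValues(imp), exprValues(full)[, 1:5])
  empty <- imputeGenes(m, sim$ref, character(0))
  expect_equal(dim(empty), c(36L, 0L))
  expect_error(imputeGenes(m, sim$ref, c("nope", genes[1])), "nope")
})

test_that("feature translation applies the same linear map", {
  sim <- smallSim(seed = 5)
  m <- fitTranslation(sim$ref, sim$st, mode = "lowrank", K = 8,
                      epochs = 100, seed = 1)
  W <- materializeMapping(m)
  # one-hot feature column for cell c pulls out column c of W
  nc <- ncol(W)
  oneHot <- matrix(0, nc, 2); oneHot[3, 1] <- 1; oneHot[7, 2] <- 1
  out <- exprValues(translateFeatures(m, oneHot))
  expect_equal(unname(out[, 1]), unname(W[, 3]), tolerance = 1e-12)
  expect_equal(unname(out[, 2]), unname(W[, 7]), tolerance = 1e-12)
  # same map as translateExpression on the training features
  expect_equal(exprValues(translateFeatures(m, exprValues(sim$ref))),
               unname(exprValues(translateExpression(m, sim$ref))),
               ignore_attr = TRUE)
  # cluster-mode models are rejected
  mc <- fitTranslation(sim$ref, sim$st, mode = "cluster",
                       labels = sim$truth$clusterLabels,
                       epochs = 50, seed = 1)
  expect_error(translateFeatures(mc, oneHot), "cluster-mode")
  expect_error(translateFeatures(m, matrix(0, nc + 1, 2)), "rows")
})

test_that("lambda = 0 exactly reproduces the unregularized path", {
  sim <- smallSim(seed = 6)
  g <- buildSpatialGraph(sim$coords, k = 4)
  f0 <- fitTranslation(sim$ref, sim$st, mode = "lowrank", K = 8,
                       epochs = 120, seed = 9)
  f0g <- fitTranslation(sim$ref, sim$st, mode = "lowrank", K = 8,
                        graph = g, lambdaSpa = 0, epochs = 120, seed = 9)
  expect_identical(lossTrace(f0)$total, lossTrace(f0g)$total)
})

test_that("checkpoint round-trips through save/load", {
  sim <- smallSim(seed = 7)
  m <- fitTranslation(sim$ref, sim$st, mode = "lowrank", K = 8,
                      epochs = 60, seed = 2)
  path <- tempfile(fileext = ".rds")
  saveMappingModel(m, path)
  m2 <- loadMappingModel(path)
  expect_equal(materializeMapping(m2), materializeMapping(m))
  expect_identical(lossTrace(m2), lossTrace(m))
  expect_error(loadMappingModel(tempfile()), "not found")
})
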