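test_that("local bootstrap preserves cluster sizes and slots", {
  sim <- smallSim(seed = 1)
  labs <- sim$truth$clusterLabels
  sizes <- table(labs)
  for (s in 1:25) {
    b <- localBootstrap(sim$ref, labs, seed = s)
    expect_equal(dim(b), dim(sim$ref))
    # each position is filled from its own cluster
    orig <- exprValues(sim$ref)
    boot <- exprValues(b)
    for (cl in levels(labs)) {
      members <- which(labs == cl)
      for (i in members) {
        hit <- which(apply(orig[members, , drop = FALSE], 1,
                           function(r) all(r == boot[i, ])))
        expect_gt(length(hit), 0)
      }
    }
  }
})

test_that("bootstrap draw frequencies are binomial for a 2-cell cluster", {
  m <- ExpressionMatrix(rbind(c(1, 0), c(0, 1)), sampleIds = c("a", "b"))
  lab <- c(a = "c1", b = "c1")
  hits <- vapply(1:1000, function(s) {
    exprValues(localBootstrap(m, lab, seed = s))[1, 1] == 1
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.5), 0.05)
  # singleton clusters reproduce the input exactly
  lab2 <- c(a = "c1", b = "c2")
  expect_identical(exprValues(localBootstrap(m, lab2, seed = 1)),
                   unname(exprValues(m)), ignore_attr = TRUE)
})

test_that("per-gene CSS hits the cosine identities", {
  A <- cbind(c(1, 2), c(1, 0), c(2, 0))
  B <- cbind(c(1, 2), c(0, 1), c(-2, 0))
  css <- cssPerGene(A, B)
  expect_equal(unname(css), c(1, 0, -1))
  expect_equal(unname(cssPerGene(A, 5 * A)), rep(1, 3))
  expect_equal(unname(cssPerGene(cbind(c(0, 0)), cbind(c(1, 1)))), 0)
})

test_that("score variance: degenerate zero cases and loop oracle", {
  sim <- smallSim(seed = 2)
  m <- fitTranslation(sim$ref, sim$st, mode = "lowrank", K = 8,
                      epochs = 80, seed = 1)
  # singleton clusters: every bootstrap identical, variance exactly 0
  singletons <- setNames(sampleIds(sim$ref), sampleIds(sim$ref))
  v0 <- scoreVariance(m, sim$ref, sim$st, singletons, nSim = 4, seed = 5)
  expect_true(all(v0 == 0))
  # oracle recomputation with the same seed stream
  labs <- sim$truth$clusterLabels
  v <- scoreVariance(m, sim$ref, sim$st, labs, nSim = 5, seed = 11)
  al <- alignGenes(sim$ref, sim$st)
  set.seed(11)
  seeds <- sample.int(.Machine$integer.max - 1L, 5)
  mat <- sapply(seeds, function(s) {
    b <- localBootstrap(sim$ref[, al$refIndex], labs, seed = s)
    cssPerGene(translateExpression(m, b), sim$st[, al$stIndex])
  })
  expect_equal(unname(v), unname(apply(t(mat), 2, var)), tolerance = 1e-12)
  expect_error(scoreVariance(m, sim$ref, sim$st, labs, nSim = 1), "nSim")
})

test_that("uncertainty features are sparsity plus prediction moments", {
  counts <- ExpressionMatrix(cbind(g1 = c(0, 0, 2, 1), g2 = c(0, 0, 0, 0),
                                   g3 = c(5, 1, 2, 2)))
  pred <- ExpressionMatrix(cbind(g1 = c(1, 2, 3), g2 = rep(4, 3),
                                 g3 = c(0, 1, 5)), axisRole = "spots")
  f <- uncertaintyFeatures(counts, pred)
  expect_equal(f$sparsity, c(0.5, 1, 0))
  expect_equal(f$predMean, c(2, 4, 2))
  expect_equal(f$predVar, c(1, 0, 7))
  bad <- ExpressionMatrix(matrix(1, 3, 1, dimnames = list(NULL, "gX")),
                          axisRole = "spots")
  expect_error(uncertaintyFeatures(counts, bad), "absent")
})

test_that("OLS recovers exact and noisy coefficients", {
  set.seed(41)
  n <- 200
  f <- data.frame(gene = sprintf("g%d", 1:n), sparsity = runif(n),
                  predMean = rnorm(n, 2), predVar = runif(n, 0, 3))
  beta <- c(0.1, 0.5, -0.2, 0.3)
  yExact <- beta[1] + beta[2] * f$sparsity + beta[3] * f$predMean +
    beta[4] * f$predVar
  yExact <- yExact - min(yExact)  # keep variances nonnegative
  mExact <- fitUncertainty(f, yExact)
  expect_equal(unname(uncertaintyCoef(mExact))[-1], beta[-1],
               tolerance = 1e-8)
  expect_gt(uncertaintyR2(mExact), 0.999999)
  # constant target gives zero slopes
  mConst <- fitUncertainty(f, rep(0.7, n))
  expect_equal(unname(uncertaintyCoef(mConst)),
               c(0.7, 0, 0, 0), tolerance = 1e-10)
  # rank-deficient design is rejected with advice
  fBad <- f; fBad$predVar <- fBad$sparsity
  expect_error(fitUncertainty(fBad, yExact), "rank-deficient")
})

test_that("uncertainty prediction is the stated affine map with rank quantiles", {
  f <- data.frame(gene = c("a", "b", "c"), sparsity = c(0.1, 0.5, 0.9),
                  predMean = c(1, 1, 1), predVar = c(2, 2, 2))
  m0 <- new("UncertaintyModel", beta = c(0, 0, 0, 0), se = rep(0, 4), r2 = 1)
  expect_equal(predictUncertainty(m0, f)$score, rep(0, 3))
  m1 <- new("UncertaintyModel", beta = c(1, 0, 0, 0), se = rep(0, 4), r2 = 1)
  p1 <- predictUncertainty(m1, f)
  expect_equal(p1$score, rep(1, 3))
  expect_equal(p1$quantile, rep(2 / 3, 3))  # all tied at the average rank
  mS <- new("UncertaintyModel", beta = c(0, 1, 0, 0), se = rep(0, 4), r2 = 1)
  pS <- predictUncertainty(mS, f)
  expect_equal(order(pS$score), order(f$sparsity))
})

test_that("knee selection finds corners and honors tie-breaks", {
  unc <- data.frame(gene = sprintf("g%d", 1:100), score = seq(0, 1, length = 100),
                    quantile = (1:100) / 100)
  # flat curve -> most stringent grid point
  cssFlat <- setNames(rep(0.8, 100), unc$gene)
  selFlat <- selectGenesByKnee(cssFlat, unc)
  expect_equal(selFlat$threshold, 0.1)
  expect_equal(selFlat$curve$medianCss,
               rep(0.8, 10))
  expect_equal(selFlat$curve$nGenes[10], 100)
  # knee geometry: a piecewise-linear curve with one sharp corner is
  # resolved at the corner (max perpendicular distance to the chord)
  xg <- seq(0.1, 1, by = 0.1)
  yCorner <- c(0.90, 0.90, 0.90, 0.90, 0.90, 0.90, 0.75, 0.60, 0.45, 0.30)
  expect_equal(spotimpute:::.kneePoint(xg, yCorner), 0.6)
  # steep early drop: the farthest point from the chord is the drop's foot
  yCorner2 <- c(0.95, 0.94, 0.93, 0.40, 0.39, 0.38, 0.37, 0.36, 0.35, 0.34)
  expect_equal(spotimpute:::.kneePoint(xg, yCorner2), 0.4)
  # declining css with uncertainty: selection keeps the low-uncertainty set
  cssKnee <- setNames(seq(1, 0, length = 100), unc$gene)
  selKnee <- selectGenesByKnee(cssKnee, unc)
  expect_true(selKnee$threshold %in% xg)
  expect_setequal(selKnee$selected,
                  unc$gene[unc$quantile <= selKnee$threshold + 1e-12])
  # last curve point is the global median
  expect_equal(selKnee$curve$medianCss[10], median(cssKnee))
  # cross-validated alternative picks a sensible quantile on the same curve
  selCv <- selectGenesByKnee(cssKnee, unc, method = "cv", seed = 3)
  expect_true(selCv$threshold %in% seq(0.1, 1, 0.1))
})
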