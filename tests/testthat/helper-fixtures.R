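# Shared fixtures, built in code.

# tiny expression pair with a known gene overlap
tinyPair <- function() {
  ref <- ExpressionMatrix(
    matrix(c(1, 2, 3, 4, 5, 6), 2, 3,
           dimnames = list(c("c1", "c2"), c("A", "B", "C"))),
    axisRole = "cells")
  st <- ExpressionMatrix(
    matrix(c(1, 0, 2, 1, 3, 5), 2, 3,
           dimnames = list(c("s1", "s2"), c("B", "C", "D"))),
    axisRole = "spots")
  list(ref = ref, st = st)
}

# regular grid graph fixture
gridGraph <- function(nrowg = 7, ncolg = 7, k = 4, scheme = "binary",
                      rowNormalize = FALSE) {
  coords <- as.matrix(expand.grid(x = seq_len(ncolg), y = seq_len(nrowg)))
  list(coords = coords,
       graph = buildSpatialGraph(coords, k = k, scheme = scheme,
                                 rowNormalize = rowNormalize))
}

# independent O(N^2) double-loop Moran's I oracle
moranOracle <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# textbook BH step-up oracle
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (r in m:1) {
    val <- min(prev, p[o[r]] * m / r)
    q[o[r]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# small simulated dataset reused by several files
smallSim <- function(seed = 1, ...) {
  simulateSpatialData(nCells = 80L, nSpots = 36L, nGenes = 30L,
                      nClusters = 3L, grid = c(6L, 6L), seed = seed, ...)
}
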