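linePoints <- function(x) cbind(0, 0, x)

test_that("knn windows follow physical distance with the focal excluded", {
  pts <- linePoints(c(0, 1, 2))
  expect_setequal(knnWindow(pts, 2, 2), c(1, 3))
  pts2 <- linePoints(c(0, 1, 3))
  expect_equal(knnWindow(pts2, 1, 1), 2)
  expect_error(knnWindow(pts, 1, 3), "exceeds")
})

test_that("knn equals brute-force all-pairs sorting on random clouds", {
  set.seed(40)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    pts <- matrix(runif(3 * n, 0, 100), n, 3)
    K <- sample.int(n - 1, 1)
    f <- sample.int(n, 1)
    d <- apply(pts, 1, function(p) sqrt(sum((p - pts[f, ])^2)))
    oracle <- setdiff(order(d), f)[seq_len(K)]
    expect_equal(knnWindow(pts, f, K), oracle)
  }
})

test_that("localization score matches direct hand computation", {
  # all one clone: Lo == 1 for every K
  set.seed(41)
  ps <- CellPointSet(matrix(runif(30), 10, 3), rep("X", 10))
  for (K in c(2, 5, 9)) {
    expect_equal(localizationScore(ps, "X", K)$Lo, 1)
  }

  # engineered single-cell window: R_x = 0.5, 3 of 5 neighbours X
  pts <- linePoints(c(0, 1, 2, 3, 4, 5, 20, 11, 12, 13))
  clone <- c("X", "X", "X", "X", "B", "B", "X", "B", "B", "B")
  psE <- CellPointSet(pts, clone)
  res <- localizationScore(psE, "X", 5)
  expect_equal(res$Rx, 0.5)
  expect_equal(res$Lc[1], 3 / (5 * 0.5)) # focal at 0: nn 1,2,3,4,5

  expect_error(localizationScore(psE, "Z", 3), "clone absent")
  expect_error(localizationScore(psE, "X", 10), "need at least")
})

test_that("mean Lo over all labelings equals the hypergeometric expectation", {
  set.seed(42)
  n <- 7
  nX <- 3
  pts <- matrix(runif(3 * n, 0, 10), n, 3)
  combos <- utils::combn(n, nX)
  los <- apply(combos, 2, function(ix) {
    clone <- rep("B", n)
    clone[ix] <- "X"
    localizationScore(CellPointSet(pts, clone), "X", K = 3)$Lo
  })
  rx <- nX / n
  expected <- (nX - 1) / ((n - 1) * rx)
  expect_equal(mean(los), expected, tolerance = 1e-12)
})

test_that("radial scores satisfy their closed forms", {
  set.seed(43)
  ps <- CellPointSet(matrix(runif(36, 0, 50), 12, 3), rep("X", 12))
  for (i in c(2L, 6L)) {
    # sparse random clouds can leave a cell without neighbours at small r_i
    res <- suppressWarnings(radialLocalizationScore(ps, "X", i))
    expect_equal(res$Lo, 1)
  }

  clone <- rep(c("X", "B"), 6)
  psM <- CellPointSet(ps@points, clone)
  res <- radialLocalizationScore(psM, "X", 6L)
  nX <- 6
  n <- 12
  expect_equal(res$Lo, ((nX - 1) / (n - 1)) / (nX / n), tolerance = 1e-12)
})

test_that("clustered patterns score above their label-shuffled versions", {
  ps <- simulateOrganoidPoints(80, radius = 45, fraction = 0.5, alpha = 1,
    seed = 51)
  obs <- radialLocalizationScore(ps, "A", 2L)$Lo
  set.seed(52)
  shuffled <- CellPointSet(ps@points, sample(ps@clone))
  expect_gt(obs, radialLocalizationScore(shuffled, "A", 2L)$Lo)

  # windowed and radial agree in sign of (score - 1)
  lo5 <- localizationScore(ps, "A", 5)$Lo
  expect_gt(lo5, 1)
  expect_gt(obs, 1)
})

test_that("Lo is invariant to rigid motion and uniform scaling", {
  set.seed(44)
  pts <- matrix(rnorm(60), 20, 3)
  clone <- sample(c("X", "B"), 20, replace = TRUE, prob = c(0.4, 0.6))
  base <- localizationScore(CellPointSet(pts, clone), "X", 4)$Lo
  qr0 <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  moved <- sweep(pts %*% qr0 * 3.7, 2, c(10, -4, 2), "+")
  expect_equal(localizationScore(CellPointSet(moved, clone), "X", 4)$Lo,
    base, tolerance = 1e-10)
})

test_that("permutation nulls give exact extreme p-values", {
  # two spatially separated clone blocks: observed Lo is maximal
  pts <- rbind(
    matrix(runif(60, 0, 10), 20, 3),
    matrix(runif(60, 1000, 1010), 20, 3)
  )
  clone <- rep(c("X", "B"), each = 20)
  ps <- CellPointSet(pts, clone)
  res <- permutationNull(ps, "X", K = 5, nPerm = 100L, seed = 3)
  expect_equal(res$p, 1 / 101)

  # perfectly alternating labels on a line: every cell's nearest
  # neighbour is the other clone, so the observed score is minimal
  psAlt <- CellPointSet(linePoints(1:40), rep(c("X", "B"), 20))
  resAlt <- permutationNull(psAlt, "X", K = 1, nPerm = 200L, seed = 4)
  expect_gt(resAlt$p, 0.9)
  expect_error(permutationNull(ps, "X", 5, nPerm = 10L), "nPerm")
})

test_that("fraction stratification bins and filters correctly", {
  df <- data.frame(fraction = c(0.35, 0.5, 0.95, 0.12), score = 1:4)
  out <- stratifyByFraction(df, 0.2)
  expect_equal(out$bin_lo[out$n == 1 & out$mean == 1], 0.2)
  expect_equal(nrow(out), 4) # empty bins omitted
  kept <- filterComparableFractions(df)
  expect_equal(kept$score, 2)
})

test_that("nucleus tables convert to point sets in physical units", {
  nuc <- data.frame(
    organoid_label = c(1, 1, 1, 2),
    centroid_z = c(0, 1, 2, 0), centroid_y = c(0, 0, 1, 0),
    centroid_x = c(0, 3, 1, 0),
    channel = c("EGFP", "mCherry", "EGFP", "EGFP"),
    is_dead = c(FALSE, FALSE, TRUE, FALSE)
  )
  ps <- pointSetsFromNuclei(nuc, c(5, 1, 1))
  expect_length(ps, 1) # organoid 2 has < 2 live cells
  expect_equal(nrow(ps[["1"]]@points), 2)
  expect_equal(ps[["1"]]@points[2, ], c(5, 0, 3), ignore_attr = TRUE)
})
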