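test_that("organoid crops respect bboxes, padding and clipping", {
  layout <- tinyLayout(nz = 6L, h = 20L, w = 20L, channels = c("a", "b"))
  arr <- array(seq_len(2 * 6 * 400), c(2, 6, 20, 20))
  vol <- WellVolume(arr, layout, dtypeMax = max(arr))
  rec <- data.frame(label = 1, bbox_zmin = 0, bbox_ymin = 0, bbox_xmin = 0,
    bbox_zmax = 2, bbox_ymax = 3, bbox_xmax = 4)
  cr <- cropOrganoid(vol, rec, padVoxels = c(0L, 0L, 0L))
  expect_equal(dim(cr$crop), c(2, 2, 3, 4))
  expect_equal(cr$offset, c(0L, 0L, 0L))
  expect_identical(cr$crop[1, , , ], arr[1, 1:2, 1:3, 1:4])

  # padding beyond the edge clips and records the clipped offset
  cr2 <- cropOrganoid(vol, rec, padVoxels = c(5L, 5L, 5L))
  expect_equal(cr2$offset, c(0L, 0L, 0L))
  expect_equal(dim(cr2$crop), c(2, 6, 8, 9))

  bad <- rec
  bad$bbox_zmax <- 0
  expect_error(cropOrganoid(vol, bad), "empty bounding box")
})

test_that("percentile normalization follows the formula and its edge cases", {
  x <- array(0:100, c(101, 1, 1))
  out <- normalizePercentile(x, 0, 100)
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
  expect_equal(out[51, 1, 1], 0.5)

  expect_message(z <- normalizePercentile(array(5, c(3, 3, 3))), "constant")
  expect_true(all(z == 0))

  # formula oracle with a manually computed type-7 quantile
  set.seed(8)
  v <- array(rnorm(500), c(5, 10, 10))
  manualQ <- function(x, p) {
    s <- sort(x)
    h <- (length(s) - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
  }
  qlo <- manualQ(as.numeric(v), 0.01)
  qhi <- manualQ(as.numeric(v), 0.998)
  expected <- pmin(pmax((v - qlo) / (qhi - qlo), 0), 1)
  expect_equal(normalizePercentile(v, 1, 99.8), expected, tolerance = 1e-12)
})

test_that("the watershed backend separates spherical nuclei", {
  # two uniform spheres, radius 4 um, centres 12 um apart (isotropic voxels)
  s <- 28
  m1 <- ballMask(s, 4, center = c(14, 14, 9))
  m2 <- ballMask(s, 4, center = c(14, 14, 21))
  x <- array(0, c(s, s, s))
  x[m1 | m2] <- 1
  lv <- segmentNuclei(x, nucleiBackendConfig(), c(1, 1, 1))
  expect_equal(nObjects(lv), 2L)
  lab <- labelData(lv)
  l1 <- as.integer(names(which.max(table(lab[m1]))))
  l2 <- as.integer(names(which.max(table(lab[m2]))))
  expect_true(l1 != l2 && l1 > 0 && l2 > 0)
  expect_gte(sum(lab[m1] == l1) / sum(m1), 0.9)
  expect_gte(sum(lab[m2] == l2) / sum(m2), 0.9)

  # a single nucleus yields one label
  one <- array(0, c(s, s, s))
  one[ballMask(s, 4)] <- 1
  expect_equal(nObjects(segmentNuclei(one, nucleiBackendConfig(),
    c(1, 1, 1))), 1L)

  # empty crop: zero labels
  expect_equal(nObjects(segmentNuclei(array(0, c(8, 8, 8)),
    nucleiBackendConfig(), c(1, 1, 1))), 0L)
})

test_that("a touching pair with an intensity valley splits in two", {
  s <- 30
  m1 <- ballMask(s, 4.4, center = c(15, 15, 11))
  m2 <- ballMask(s, 4.4, center = c(15, 15, 20))
  x <- array(0, c(s, s, s))
  x[m1] <- 1
  x[m2 & !m1] <- 1
  x[, , 15:16][x[, , 15:16] > 0] <- 0.4 # valley plane between the two
  lv <- segmentNuclei(x, nucleiBackendConfig(), c(1, 1, 1))
  expect_equal(nObjects(lv), 2L)
})

test_that("non-normalized input warns", {
  x <- array(0, c(8, 8, 8))
  x[ballMask(8, 3)] <- 900
  expect_warning(segmentNuclei(x, nucleiBackendConfig(), c(1, 1, 1)),
    "normalized")
})

test_that("nucleus features carry frame offsets and symmetry measures", {
  s <- 15
  ball <- ballMask(s, 3)
  lv <- LabeledVolume(array(as.integer(ball), dim(ball)), c(1, 1, 1))
  crop <- array(0.7, c(s, s, s))
  df <- nucleusFeatures(lv, crop, organoidLabel = 9L, channel = "EGFP",
    offset = c(10L, 20L, 30L))
  expect_equal(df$volume, sum(ball))
  expect_gte(df$eccentricity, 0.9)
  expect_equal(df$organoid_label, 9L)
  expect_equal(df$channel, "EGFP")
  expect_equal(df$centroid_z, (s - 1) / 2 + 10)
  expect_equal(df$centroid_y, (s - 1) / 2 + 20)
  expect_equal(df$intensity_min, df$intensity_max)
  expect_false(df$border_touching)
  expect_false(df$is_dead)

  # a nucleus clipped by the crop border is flagged
  edgeBall <- ballMask(s, 3, center = c(2, 8, 8))
  lvE <- LabeledVolume(array(as.integer(edgeBall), dim(edgeBall)),
    c(1, 1, 1))
  dfE <- nucleusFeatures(lvE, crop, 1L, "EGFP")
  expect_true(dfE$border_touching)
})

test_that("segmenting in a crop maps back to the well frame", {
  layout <- tinyLayout(nz = 9L, h = 40L, w = 40L, channels = "a",
    voxel = c(2, 1, 1))
  arr <- array(0, c(1, 9, 40, 40))
  truthVox <- c(5, 25, 30) # 1-based voxel centre
  idx <- arrayInd(seq_len(9 * 1600), c(9, 40, 40))
  m <- array(((idx[, 1] - truthVox[1]) * 2)^2 + (idx[, 2] - truthVox[2])^2 +
    (idx[, 3] - truthVox[3])^2 <= 16, c(9, 40, 40))
  arr[1, , , ][m] <- 1
  vol <- WellVolume(arr, layout, dtypeMax = 1)
  rec <- data.frame(label = 1,
    bbox_zmin = 1, bbox_ymin = 18, bbox_xmin = 23,
    bbox_zmax = 8, bbox_ymax = 33, bbox_xmax = 38)
  cr <- cropOrganoid(vol, rec, padVoxels = c(1L, 2L, 2L))
  raw <- array(cr$crop[1, , , ], dim(cr$crop)[2:4])
  lv <- segmentNuclei(raw, nucleiBackendConfig(), voxelSize(vol))
  df <- nucleusFeatures(lv, raw, 1L, "a", offset = cr$offset)
  expect_equal(nrow(df), 1L)
  expect_equal(df$centroid_z, truthVox[1] - 1, tolerance = 0.5)
  expect_equal(df$centroid_y, truthVox[2] - 1, tolerance = 0.5)
  expect_equal(df$centroid_x, truthVox[3] - 1, tolerance = 0.5)
})

test_that("channels are segmented independently of their order", {
  sim <- smallSimWell()
  seg <- smallSegmented()
  a <- segmentWellNuclei(sim$vol, seg$features,
    fluorChannels = c("EGFP", "mCherry"))
  b <- segmentWellNuclei(sim$vol, seg$features,
    fluorChannels = c("mCherry", "EGFP"))
  key <- function(df) {
    df <- df[order(df$channel, df$organoid_label, df$centroid_z,
      df$centroid_y, df$centroid_x), ]
    rownames(df) <- NULL
    df
  }
  expect_equal(key(a), key(b))
})

test_that("unknown backends fail loudly and registered ones are used", {
  x <- array(0, c(6, 6, 6))
  expect_error(
    segmentNuclei(x, nucleiBackendConfig(backend = "cnn"), c(1, 1, 1)),
    "register"
  )
  registerNucleiBackend("toy", function(crop, cfg) {
    array(as.integer(crop > 0.5), dim(crop))
  })
  x[ballMask(6, 2)] <- 1
  lv <- segmentNuclei(x, nucleiBackendConfig(backend = "toy"), c(1, 1, 1))
  expect_equal(nObjects(lv), 1L)
})
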