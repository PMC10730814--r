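test_that("field cleaning keeps blobs and removes isolated hot pixels", {
  # one channel, 3 planes, 40x40: a bright 9-px-radius disc plus isolated
  # hot pixels well above the debris threshold
  fld <- array(0, c(1, 3, 40, 40))
  disc <- outer((1:40) - 15, (1:40) - 15,
    function(a, b) a^2 + b^2 <= 81)
  for (z in 1:3) fld[1, z, , ] <- 5000 * disc
  hot <- rbind(c(35, 5), c(5, 35), c(38, 38))
  for (k in seq_len(nrow(hot))) fld[1, 2, hot[k, 1], hot[k, 2]] <- 30000
  cleaned <- cleanField(fld)
  for (k in seq_len(nrow(hot))) {
    expect_equal(cleaned[1, 2, hot[k, 1], hot[k, 2]], 0)
  }
  # the disc interior survives (dilation may extend the mask outward)
  core <- outer((1:40) - 15, (1:40) - 15, function(a, b) a^2 + b^2 <= 36)
  expect_equal(cleaned[1, 1, , ][core], fld[1, 1, , ][core])

  expect_equal(cleanField(array(0, c(1, 2, 8, 8))),
    array(0, c(1, 2, 8, 8)))
})

makeSphereField <- function(nz = 24, s = 192, r = 8, value = 12000,
                            bg = 120, noiseSd = 30,
                            centers = list(c(12, 96, 96)), seed = 5) {
  set.seed(seed)
  fld <- array(rnorm(nz * s * s, bg, noiseSd), c(nz, s, s))
  masks <- list()
  idx <- arrayInd(seq_len(nz * s * s), c(nz, s, s))
  for (ctr in centers) {
    m <- array((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 +
      (idx[, 3] - ctr[3])^2 <= r^2, c(nz, s, s))
    fld[m] <- value
    masks[[length(masks) + 1]] <- m
  }
  fld[fld < 0] <- 0
  list(field = array(fld, c(1, nz, s, s)), masks = masks)
}

test_that("per-field segmentation recovers synthetic spheres", {
  sph <- makeSphereField()
  cleaned <- cleanField(sph$field)
  mask <- segmentField(cleaned)
  truth <- sph$masks[[1]]
  expect_gte(sum(mask & truth) / sum(truth), 0.95)
  expect_lte(sum(mask & !truth) / sum(!truth), 0.01)

  two <- makeSphereField(centers = list(c(12, 48, 48), c(12, 144, 144)))
  mask2 <- segmentField(cleanField(two$field))
  expect_gte(sum(mask2 & two$masks[[1]]) / sum(two$masks[[1]]), 0.9)
  expect_gte(sum(mask2 & two$masks[[2]]) / sum(two$masks[[2]]), 0.9)

  expect_message(
    empty <- segmentField(array(0, c(1, 4, 16, 16))),
    "degenerate"
  )
  expect_false(any(empty))
})

test_that("stitching before labeling keeps border-spanning organoids whole", {
  layout <- tinyLayout(nz = 6L, h = 20L, w = 20L, channels = "a",
    grid = c(1L, 2L))
  # sphere centred exactly on the border between field 1 and field 2
  full <- ballMask(40, 7, center = c(3, 10, 20))[1:6, 1:20, 1:40]
  masks <- list(full[, , 1:20], full[, , 21:40])
  lv <- stitchLabelFilter(masks, layout, organoidSegParams(
    minVolumeVoxels = 10L))
  expect_equal(nObjects(lv), 1L)
  expect_equal(sum(labelData(lv) > 0), sum(full))
})

test_that("small objects are filtered and labels renumbered from 1", {
  layout <- tinyLayout(nz = 10L, h = 30L, w = 30L, channels = "a")
  m <- array(FALSE, c(10, 30, 30))
  m[2:6, 2:8, 2:8] <- TRUE # 245 voxels
  m[2:3, 15:16, 15:16] <- TRUE # 8 voxels, below the cutoff
  m[5:9, 20:26, 20:26] <- TRUE # 245 voxels
  lv <- stitchLabelFilter(list(m), layout,
    organoidSegParams(minVolumeVoxels = 100L))
  expect_equal(nObjects(lv), 2L)
  expect_setequal(setdiff(unique(as.vector(labelData(lv))), 0L), c(1L, 2L))

  empty <- stitchLabelFilter(list(array(FALSE, c(10, 30, 30))), layout,
    organoidSegParams())
  expect_equal(nObjects(empty), 0L)
  expect_error(
    stitchLabelFilter(list(m[1:5, , ]), layout, organoidSegParams()),
    "mask shape"
  )
})

test_that("cuboid features match closed forms", {
  # 4 z-planes x 10 x 10 at voxel (5, 1, 1) um: 400 voxels -> 2000 um^3
  lv <- cuboidLabels(c(8, 16, 16), 2:5, 3:12, 4:13, voxel = c(5, 1, 1))
  layout <- tinyLayout(nz = 8L, h = 16L, w = 16L, channels = "a",
    voxel = c(5, 1, 1))
  arr <- array(7, c(1, 8, 16, 16))
  vol <- WellVolume(arr, layout)
  ft <- organoidFeatures(lv, vol)
  expect_equal(nrow(ft), 1L)
  expect_equal(ft$volume, 2000)
  expect_equal(ft$volume_filled, 2000)
  expect_equal(ft$volume_convex, 2000)
  expect_equal(ft$volume_bbox, 2000)
  expect_equal(ft$euler_number, 1)
  expect_equal(ft$solidity, 1)
  expect_equal(ft$extent, 1)
  expect_equal(ft$bbox_zmin, 1)
  expect_equal(ft$bbox_zmax, 5) # half-open
  # uniform intensity: min == mean == max
  expect_equal(ft$intensity_min_a, 7)
  expect_equal(ft$intensity_mean_a, 7)
  expect_equal(ft$intensity_max_a, 7)
})

test_that("an interior cavity raises the Euler number and filled volume", {
  a <- array(0L, c(10, 12, 12))
  a[2:8, 2:10, 2:10] <- 1L
  a[4:6, 5:7, 5:7] <- 0L # cavity
  lv <- LabeledVolume(a, c(1, 1, 1))
  layout <- tinyLayout(nz = 10L, h = 12L, w = 12L, channels = "a")
  vol <- WellVolume(array(1, c(1, 10, 12, 12)), layout)
  ft <- organoidFeatures(lv, vol)
  expect_lt(ft$volume, ft$volume_filled)
  expect_equal(ft$volume_filled, 7 * 9 * 9)
  expect_equal(ft$euler_number, 2)
})

test_that("feature chain inequalities and voxel conservation hold on random shapes", {
  set.seed(31)
  layout <- tinyLayout(nz = 14L, h = 40L, w = 40L, channels = "a",
    voxel = c(3, 1, 1))
  for (rep in 1:5) {
    m <- array(FALSE, c(14, 40, 40))
    for (b in 1:4) {
      ctr <- c(sample(4:11, 1), sample(8:32, 1), sample(8:32, 1))
      r <- runif(1, 2.5, 5.5)
      idx <- arrayInd(seq_len(14 * 40 * 40), c(14, 40, 40))
      m <- m | array((idx[, 1] - ctr[1])^2 * 9 + (idx[, 2] - ctr[2])^2 +
        (idx[, 3] - ctr[3])^2 <= (r * 3)^2, c(14, 40, 40))
    }
    lv <- stitchLabelFilter(list(m), layout,
      organoidSegParams(minVolumeVoxels = 5L))
    vol <- WellVolume(array(runif(14 * 40 * 40), c(1, 14, 40, 40)),
      layout, dtypeMax = 1)
    ft <- organoidFeatures(lv, vol)
    expect_true(all(ft$volume <= ft$volume_filled + 1e-9))
    expect_true(all(ft$volume_filled <= ft$volume_convex + 1e-9))
    expect_true(all(ft$volume_convex <= ft$volume_bbox + 1e-9))
    expect_true(all(ft$solidity > 0 & ft$solidity <= 1))
    expect_true(all(ft$intensity_min_a <= ft$intensity_mean_a &
      ft$intensity_mean_a <= ft$intensity_max_a))
    # conservation: per-object voxel counts sum to the foreground
    expect_equal(sum(ft$volume) / prod(voxelSize(lv)),
      sum(labelData(lv) > 0))
    # order stability: labels sorted by first-voxel scan position
    firsts <- vapply(ft$label, function(l) {
      min(which(labelData(lv) == l))
    }, numeric(1))
    expect_true(all(diff(firsts) > 0))
  }
})

test_that("axis lengths reproduce ellipsoid eccentricity", {
  # prolate ellipsoid, semi-axes (8, 4, 4) um -> minor/major = 0.5
  s <- 21
  idx <- arrayInd(seq_len(s^3), c(s, s, s))
  ctr <- (s + 1) / 2
  m <- array(((idx[, 1] - ctr) / 8)^2 + ((idx[, 2] - ctr) / 4)^2 +
    ((idx[, 3] - ctr) / 4)^2 <= 1, c(s, s, s))
  df <- organoid3d:::regionProps3D(array(as.integer(m), dim(m)),
    c(1, 1, 1), eccentricity = TRUE)
  expect_equal(df$eccentricity, 0.5, tolerance = 0.08)
  expect_equal(df$major_axis_length, 16, tolerance = 0.1)

  ball <- ballMask(15, 5)
  dfb <- organoid3d:::regionProps3D(array(as.integer(ball), dim(ball)),
    c(1, 1, 1), eccentricity = TRUE)
  expect_gte(dfb$eccentricity, 0.9)
  expect_equal(dfb$volume, sum(ball))
})
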