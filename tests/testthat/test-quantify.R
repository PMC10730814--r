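test_that("imaged area matches the closed form for a rectangle", {
  a <- array(0L, c(3, 300, 300))
  a[2, 101:200, 101:200] <- 1L # 100 x 100 px
  lv <- LabeledVolume(a, c(5, 1, 1))
  area <- imagedArea(lv, imagedAreaParams(dilationRadius = 0L,
    closingRadius = 0L))
  expect_equal(area, 0.01)

  empty <- LabeledVolume(array(0L, c(3, 20, 20)), c(5, 1, 1))
  expect_warning(z <- imagedArea(empty), "0")
  expect_equal(z, 0)
})

test_that("gap closing between adjacent organoids matches a naive oracle", {
  a <- array(0L, c(1, 40, 60))
  a[1, 11:30, 11:25] <- 1L
  a[1, 11:30, 29:43] <- 2L # 3-px gap between the two blocks
  lv <- LabeledVolume(a, c(5, 1, 1))
  params <- imagedAreaParams(dilationRadius = 0L, closingRadius = 3L)
  area <- imagedArea(lv, params)

  brush <- EBImage::makeBrush(7L, shape = "disc") > 0
  proj <- a[1, , ] > 0
  expected <- naiveErode(naiveDilate(proj, brush), brush)
  expect_equal(area, sum(expected) / 1e6)
  # the gap midline is bridged
  expect_gt(area, sum(proj) / 1e6)
})

test_that("imaged area is monotone in the closing radius", {
  sim <- smallSimWell()
  seg <- smallSegmented()
  areas <- vapply(c(0L, 5L, 12L), function(r) {
    imagedArea(seg$labels, imagedAreaParams(dilationRadius = r,
      closingRadius = r))
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("dead classification applies a strict threshold on the bbox mean", {
  crop <- array(0, c(10, 10, 30))
  crop[1, 1, 1] <- 65535 # pins the min-max range
  crop[2:5, 2:5, 1:4] <- 0.5 * 65535
  crop[2:5, 2:5, 11:14] <- 0
  crop[2:5, 2:5, 21:24] <- 6553.5 # exactly 0.1 after normalization
  nuc <- data.frame(
    nucleus_label = 1:3, organoid_label = 1L,
    bbox_zmin = c(1, 1, 1), bbox_ymin = c(1, 1, 1),
    bbox_xmin = c(0, 10, 20),
    bbox_zmax = c(5, 5, 5), bbox_ymax = c(5, 5, 5),
    bbox_xmax = c(4, 14, 24),
    is_dead = NA
  )
  out <- classifyDead(nuc, crop)
  expect_equal(out$is_dead, c(TRUE, FALSE, FALSE)) # 0.1 itself is live

  # a no-signal dye channel leaves everything alive
  noise <- array(runif(1000, 0, 100), c(10, 10, 10))
  expect_message(
    out2 <- classifyDead(nuc[2, ], noise),
    "no signal"
  )
  expect_false(out2$is_dead)
})

test_that("exactly the programmed dye-positive nuclei are flagged", {
  cfg <- smallSimConfig(seed = 23L, deadFraction = 0.15)
  sim <- simulateWell(cfg)
  vs <- voxelSize(sim$vol)
  deadIdx <- match("DRAQ7", channelNames(sim$vol))
  flagged <- 0L
  programmed <- sum(sim$nuclei$dead)
  for (k in sort(unique(sim$nuclei$organoid))) {
    tr <- sim$nuclei[sim$nuclei$organoid == k, ]
    # truth-tight nucleus bboxes (0-based half-open) in well voxels
    lo <- cbind(
      floor((tr$z_um - tr$radius_um) / vs[1]),
      floor((tr$y_um - tr$radius_um) / vs[2]),
      floor((tr$x_um - tr$radius_um) / vs[3])
    )
    hi <- cbind(
      ceiling((tr$z_um + tr$radius_um) / vs[1]) + 1,
      ceiling((tr$y_um + tr$radius_um) / vs[2]) + 1,
      ceiling((tr$x_um + tr$radius_um) / vs[3]) + 1
    )
    d <- dim(sim$vol@data)[2:4]
    nuc <- data.frame(
      nucleus_label = seq_len(nrow(tr)), organoid_label = k,
      bbox_zmin = pmax(lo[, 1], 0), bbox_ymin = pmax(lo[, 2], 0),
      bbox_xmin = pmax(lo[, 3], 0),
      bbox_zmax = pmin(hi[, 1], d[1]), bbox_ymax = pmin(hi[, 2], d[2]),
      bbox_xmax = pmin(hi[, 3], d[3]), is_dead = NA
    )
    org <- sim$organoids[sim$organoids$organoid == k, ]
    ctr <- c(org$z_um, org$y_um, org$x_um)
    olo <- pmax(floor((ctr - org$radius_um - 10) / vs), 0)
    ohi <- pmin(ceiling((ctr + org$radius_um + 10) / vs) + 1, d)
    crop <- sim$vol@data[deadIdx, (olo[1] + 1):ohi[1], (olo[2] + 1):ohi[2],
      (olo[3] + 1):ohi[3]]
    out <- suppressMessages(classifyDead(nuc, crop, offset = olo))
    expect_equal(out$is_dead, tr$dead)
    flagged <- flagged + sum(out$is_dead)
  }
  expect_equal(flagged, programmed)
})

test_that("well summaries compute densities and guarded ratios", {
  nuc <- data.frame(
    organoid_label = rep(1:2, each = 100),
    channel = rep(c("EGFP", "mCherry"), 100),
    is_dead = FALSE
  )
  ws <- wellSummary(data.frame(label = 1:2), nuc, areaMm2 = 2)
  expect_equal(ws$summary$n_cells_EGFP, 100)
  expect_equal(ws$summary$density_EGFP, 50)
  expect_equal(ws$summary$density_mCherry, 50)
  expect_equal(ws$summary$ratio, 1)
  expect_true(ws$summary$ratio_defined)
  expect_equal(ws$organoidClones$frac_EGFP, c(0.5, 0.5))

  allDead <- nuc
  allDead$is_dead <- TRUE
  ws2 <- wellSummary(data.frame(label = 1:2), allDead, areaMm2 = 2)
  expect_equal(ws2$summary$n_cells_EGFP, 0)
  expect_false(ws2$summary$ratio_defined)

  # scaling counts by c scales densities by c (same area)
  tripled <- nuc[rep(seq_len(nrow(nuc)), 3), ]
  ws3 <- wellSummary(data.frame(label = 1:2), tripled, areaMm2 = 2)
  expect_equal(ws3$summary$density_EGFP, 3 * ws$summary$density_EGFP)
})

test_that("control normalization rescales proportions per dose", {
  df <- data.frame(
    dose = rep(c(0, 1, 2), each = 3),
    value = c(0.5, 0.5, 0.5, 0.6, 0.62, 0.58, 0.25, 0.25, 0.25)
  )
  agg <- normalizeToControl(df)
  expect_equal(agg$mean[agg$dose == 0], 1)
  expect_equal(agg$mean[agg$dose == 1], 1.2)
  expect_equal(agg$mean[agg$dose == 2], 0.5)
  expect_error(normalizeToControl(df[df$dose > 0, ]), "no control")
})

test_that("clone ratios are stable under uniform subsampling", {
  set.seed(17)
  nuc <- data.frame(
    organoid_label = 1L,
    channel = sample(c("EGFP", "mCherry"), 4000, replace = TRUE,
      prob = c(0.6, 0.4)),
    is_dead = FALSE
  )
  full <- wellSummary(data.frame(label = 1), nuc, 1)$summary$ratio
  sub <- nuc[sample.int(4000, 1200), ]
  half <- wellSummary(data.frame(label = 1), sub, 1)$summary$ratio
  expect_equal(half, full, tolerance = 0.15)
})
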