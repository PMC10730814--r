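writeLayoutYaml <- function(lines) {
  f <- tempfile(fileext = ".yaml")
  writeLines(lines, f)
  f
}

fullLayoutLines <- c(
  "rows: 1", "cols: 1", "field_grid: [5, 5]", "planes_per_field: 101",
  "channels: [brightfield, EGFP, mCherry]", "field_shape_px: [1016, 1016]",
  "voxel_size_um: [5, 1, 1]"
)

test_that("plate layout config parses and validates", {
  layout <- parsePlateLayout(writeLayoutYaml(fullLayoutLines))
  expect_equal(fieldsPerWell(layout), 25)
  expect_equal(layout@planesPerField, 101L)
  expect_equal(length(channelNames(layout)), 3L)
  expect_equal(voxelSize(layout), c(5, 1, 1))

  single <- parsePlateLayout(writeLayoutYaml(c(
    "rows: 1", "cols: 1", "field_grid: [1, 1]", "planes_per_field: 1",
    "channels: [ch1]", "field_shape_px: [8, 8]", "voxel_size_um: [1, 1, 1]"
  )))
  expect_equal(fieldsPerWell(single), 1)
})

test_that("layout config errors name the offending key", {
  noChan <- fullLayoutLines[-5]
  expect_error(parsePlateLayout(writeLayoutYaml(noChan)), "channels")
  degenerate <- sub("voxel_size_um: \\[5, 1, 1\\]",
    "voxel_size_um: [0, 1, 1]", fullLayoutLines)
  expect_error(parsePlateLayout(writeLayoutYaml(degenerate)), "voxel")
  expect_warning(
    parsePlateLayout(writeLayoutYaml(c(fullLayoutLines, "exposure_ms: 50"))),
    "exposure_ms"
  )
  expect_error(parsePlateLayout(tempfile()), "not found")
})

test_that("tiles assemble edge-to-edge in row-major field order", {
  layout <- tinyLayout(nz = 1L, h = 10L, w = 10L, channels = "a",
    grid = c(2L, 2L))
  imgs <- lapply(1:4, function(f) matrix(f * 100 + seq_len(100), 10, 10))
  tiles <- lapply(1:4, function(f) {
    list(field = f, plane = 1L, channel = 1L, image = imgs[[f]])
  })
  vol <- assembleWell(tiles, layout)
  expect_equal(dim(vol@data), c(1, 1, 20, 20))
  expect_identical(vol@data[1, 1, 1:10, 1:10], imgs[[1]])
  expect_identical(vol@data[1, 1, 1:10, 11:20], imgs[[2]])
  expect_identical(vol@data[1, 1, 11:20, 1:10], imgs[[3]])
  expect_identical(vol@data[1, 1, 11:20, 11:20], imgs[[4]])
})

test_that("assembly validates completeness, duplicates and tile shape", {
  layout <- tinyLayout(nz = 3L, h = 6L, w = 6L, channels = c("a", "b"))
  mk <- function(f, p, ch) list(field = f, plane = p, channel = ch,
    image = matrix(p * 10 + ch, 6, 6))
  tiles <- list()
  for (p in 1:3) for (ch in 1:2) tiles[[length(tiles) + 1]] <- mk(1, p, ch)
  vol <- assembleWell(tiles, layout)
  expect_equal(dim(vol@data), c(2, 3, 6, 6))

  expect_error(assembleWell(tiles[-1], layout), "missing tile")
  expect_error(assembleWell(c(tiles, tiles[1]), layout), "duplicate")
  bad <- tiles
  bad[[1]]$image <- matrix(0, 5, 6)
  expect_error(assembleWell(bad, layout), "shape")
})

test_that("disassembly inverts assembly bit-exactly", {
  layout <- tinyLayout(nz = 2L, h = 5L, w = 7L, channels = c("a", "b"),
    grid = c(2L, 3L))
  set.seed(4)
  arr <- array(sample.int(65535, 2 * 2 * 10 * 21, replace = TRUE),
    c(2, 2, 10, 21))
  vol <- WellVolume(arr, layout)
  tiles <- disassembleWell(vol)
  expect_length(tiles, 2 * 2 * 6)
  vol2 <- assembleWell(tiles, layout)
  expect_identical(vol2@data, vol@data)
})

test_that("chunked store round-trips losslessly and reads planes lazily", {
  layout <- tinyLayout(nz = 3L, h = 8L, w = 8L, channels = c("a", "b"))
  set.seed(7)
  arr <- array(sample.int(65536, 2 * 3 * 64, replace = TRUE) - 1L,
    c(2, 3, 8, 8))
  vol <- WellVolume(arr, layout)
  store <- file.path(tempfile(), "r1c1")
  writeWellStore(vol, store)
  back <- readWellStore(store)
  expect_equal(back@data, vol@data + 0) # elementwise, numeric compare
  expect_equal(voxelSize(back), voxelSize(vol))

  # one plane comes from exactly one chunk file
  pl <- readStorePlane(store, 2, 3)
  expect_equal(pl, vol@data[2, 3, , ] + 0)
  chunks <- list.files(store, pattern = "^[0-9]")
  expect_length(chunks, 2 * 3)
  oneChunk <- file.size(file.path(store, "1.2.0.0"))
  totalChunks <- sum(file.size(file.path(store, chunks)))
  expect_lte(oneChunk, totalChunks / layout@planesPerField)

  expect_error(readWellStore(tempfile()), "no .zarray")
})

test_that("max projection matches a per-pixel loop oracle", {
  layout <- tinyLayout(nz = 5L, h = 6L, w = 6L, channels = c("a", "b"))
  set.seed(12)
  arr <- array(runif(2 * 5 * 36), c(2, 5, 6, 6))
  vol <- WellVolume(arr, layout, dtypeMax = 1)
  mp <- maxProjection(vol, "b")
  oracle <- matrix(0, 6, 6)
  for (y in 1:6) {
    for (x in 1:6) {
      oracle[y, x] <- max(arr[2, , y, x])
    }
  }
  expect_equal(mp, oracle)

  # single plane: identity; zero plane + image: the image
  one <- WellVolume(arr[, 1, , , drop = FALSE],
    tinyLayout(nz = 1L, h = 6L, w = 6L, channels = c("a", "b")),
    dtypeMax = 1)
  expect_equal(maxProjection(one, 1), arr[1, 1, , ])
  arr2 <- arr[, 1:2, , ]
  arr2[1, 1, , ] <- 0
  two <- WellVolume(arr2,
    tinyLayout(nz = 2L, h = 6L, w = 6L, channels = c("a", "b")),
    dtypeMax = 1)
  expect_equal(maxProjection(two, 1), arr2[1, 2, , ])
  expect_error(maxProjection(vol, "nope"), "unknown channel")
})

test_that("TIFF tile export and reimport reproduce the volume", {
  layout <- tinyLayout(nz = 2L, h = 6L, w = 6L, channels = c("a", "b"),
    grid = c(1L, 2L))
  set.seed(3)
  arr <- array(sample.int(65536, 2 * 2 * 6 * 12, replace = TRUE) - 1L,
    c(2, 2, 6, 12))
  vol <- WellVolume(arr, layout)
  dir <- tempfile()
  writeWellTiles(vol, dir)
  back <- readWellTiles(dir)
  expect_equal(back@data, vol@data + 0)
})
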