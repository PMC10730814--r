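# Shared fixtures; heavy simulated wells are cached for the session.

.o3dCache <- local({
  env <- new.env(parent = emptyenv())
  function(key, build) {
    if (!exists(key, envir = env)) assign(key, build(), envir = env)
    get(key, envir = env)
  }
})

tinyLayout <- function(nz = 5L, h = 16L, w = 16L, channels = c("a", "b"),
                       grid = c(1L, 1L), voxel = c(1, 1, 1)) {
  PlateLayout(
    fieldGrid = grid, planesPerField = nz, channels = channels,
    fieldShapePx = c(h, w), voxelSizeUm = voxel
  )
}

# reduced generator settings for unit tests (problem size only; intensity
# model and voxel geometry are the package defaults)
smallSimConfig <- function(seed = 1L, ...) {
  layout <- PlateLayout(
    fieldGrid = c(2L, 1L), planesPerField = 28L,
    channels = c("EGFP", "mCherry", "DRAQ7"),
    fieldShapePx = c(160L, 160L), voxelSizeUm = c(5, 1, 1)
  )
  args <- utils::modifyList(list(
    layout = layout, nOrganoids = 4L,
    organoidRadiusUm = c(35, 4, 28, 45), nucleiPerOrganoid = 40,
    seed = seed
  ), list(...))
  do.call(SimulationConfig, args)
}

smallSimWell <- function() {
  .o3dCache("smallWell", function() simulateWell(smallSimConfig(seed = 11L)))
}

smallSegmented <- function() {
  .o3dCache("smallSeg", function() {
    segmentOrganoids(smallSimWell()$vol)
  })
}

# solid axis-aligned cuboid label volume: dims (nz, ny, nx), object spans
# the given index ranges
cuboidLabels <- function(dims, zr, yr, xr, voxel = c(1, 1, 1)) {
  a <- array(0L, dims)
  a[zr, yr, xr] <- 1L
  LabeledVolume(a, voxel)
}

# digital ball mask centred in a cube of side s (1-based indices)
ballMask <- function(s, r, center = rep((s + 1) / 2, 3),
                     voxel = c(1, 1, 1)) {
  idx <- arrayInd(seq_len(s^3), c(s, s, s))
  phys <- sweep(idx - 1, 2, voxel, "*")
  ctr <- (center - 1) * voxel
  d2 <- rowSums(sweep(phys, 2, ctr)^2)
  array(d2 <= r^2, c(s, s, s))
}

# Independent geometric oracle: perpendicular distance of each bin's
# (index, scaled count) point from the peak-to-tail chord, computed by
# projecting out the chord direction (different formula from the
# implementation's implicit line equation).
triangleOracle <- function(counts) {
  nbins <- length(counts)
  peak <- which.max(counts)
  nz <- which(counts > 0)
  tail <- nz[which.max(abs(nz - peak))]
  ys <- counts * (nbins - 1) / counts[peak]
  p1 <- c(peak, ys[peak])
  p2 <- c(tail, ys[tail])
  v <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  bs <- if (tail > peak) peak:tail else seq(peak, tail, by = -1)
  d <- vapply(bs, function(b) {
    w <- c(b, ys[b]) - p1
    perp <- w - sum(w * v) * v
    sqrt(sum(perp^2))
  }, numeric(1))
  bs[which.max(d)]
}


# independent naive morphology with the same disc brush
naiveDilate <- function(m, brush) {
  r <- (nrow(brush) - 1) / 2
  out <- matrix(FALSE, nrow(m), ncol(m))
  hits <- which(m, arr.ind = TRUE)
  for (k in seq_len(nrow(hits))) {
    for (dy in -r:r) {
      for (dx in -r:r) {
        if (!brush[dy + r + 1, dx + r + 1]) next
        y <- hits[k, 1] + dy
        x <- hits[k, 2] + dx
        if (y >= 1 && y <= nrow(m) && x >= 1 && x <= ncol(m)) {
          out[y, x] <- TRUE
        }
      }
    }
  }
  out
}
naiveErode <- function(m, brush) {
  r <- (nrow(brush) - 1) / 2
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (y in seq_len(nrow(m))) {
    for (x in seq_len(ncol(m))) {
      ok <- TRUE
      for (dy in -r:r) {
        for (dx in -r:r) {
          if (!brush[dy + r + 1, dx + r + 1]) next
          yy <- y + dy
          xx <- x + dx
          if (yy < 1 || yy > nrow(m) || xx < 1 || xx > ncol(m) ||
            !m[yy, xx]) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      out[y, x] <- ok
    }
  }
  out
}

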