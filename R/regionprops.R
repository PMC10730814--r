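# Per-object 3D measurements shared by the organoid and nucleus stages.
# Voxel-count features are converted to um^3 with dz*dy*dx; axis lengths use
# the physical (anisotropic) voxel coordinates. Conventions: coordinates are
# 0-based, bounding boxes half-open [start, stop).

# Euler characteristic of the cubical complex spanned by the voxel set:
# vertices - edges + faces - cubes. A solid block gives 1; each enclosed
# cavity adds 1; each tunnel subtracts 1.
eulerNumber3D <- function(mask) {
  d <- dim(mask)
  countCells <- function(axes) {
    dd <- d + as.integer(1:3 %in% axes)
    acc <- array(FALSE, dd)
    offs <- expand.grid(lapply(1:3, function(a) {
      if (a %in% axes) 0:1 else 0
    }))
    for (r in seq_len(nrow(offs))) {
      o <- as.integer(offs[r, ])
      acc[o[1] + seq_len(d[1]), o[2] + seq_len(d[2]),
        o[3] + seq_len(d[3])] <-
        acc[o[1] + seq_len(d[1]), o[2] + seq_len(d[2]),
          o[3] + seq_len(d[3]), drop = FALSE] | mask
    }
    sum(acc)
  }
  v <- countCells(1:3)
  e <- countCells(c(2, 3)) + countCells(c(1, 3)) + countCells(c(1, 2))
  f <- countCells(1) + countCells(2) + countCells(3)
  v - e + f - sum(mask)
}

# Voxel count of the union over z-slices of the 2D convex hull of each
# (hole-filled) slice; >= the filled count by construction and <= bbox.
convexCountSlices <- function(mask) {
  d <- dim(mask)
  total <- 0L
  eps <- 1e-9
  for (z in seq_len(d[1])) {
    sl <- mask[z, , ]
    npx <- sum(sl)
    if (npx == 0L) next
    pts <- which(matrix(sl, nrow = d[2]), arr.ind = TRUE)
    if (npx < 3L) {
      total <- total + npx
      next
    }
    h <- grDevices::chull(pts[, 1], pts[, 2])
    hx <- pts[h, 1]
    hy <- pts[h, 2]
    if (length(h) < 3L) {
      total <- total + npx
      next
    }
    gy <- seq(min(pts[, 1]), max(pts[, 1]))
    gx <- seq(min(pts[, 2]), max(pts[, 2]))
    gr <- expand.grid(y = gy, x = gx)
    inside <- rep(TRUE, nrow(gr))
    nh <- length(h)
    for (i in seq_len(nh)) {
      j <- if (i == nh) 1L else i + 1L
      cr <- (hx[j] - hx[i]) * (gr$x - hy[i]) - (hy[j] - hy[i]) * (gr$y - hx[i])
      inside <- inside & (cr <= eps)
    }
    total <- total + sum(inside)
  }
  total
}

# One row of measurements per label. `intensity` is a named list of 3D
# arrays aligned with `labels`. `offset` shifts reported coordinates into a
# parent frame (0-based voxels). Eccentricity (minor/major) is emitted when
# `eccentricity = TRUE` (nucleus tables).
regionProps3D <- function(labels, voxelSizeUm, intensity = list(),
                          offset = c(0L, 0L, 0L), eccentricity = FALSE) {
  d <- dim(labels)
  dV <- prod(voxelSizeUm)
  idx <- which(labels > 0L)
  emptyCols <- function() {
    df <- data.frame(label = integer())
    df
  }
  if (!length(idx)) {
    return(emptyCols())
  }
  labv <- labels[idx]
  coords <- arrayInd(idx, d) # 1-based (z, y, x)
  groups <- split(seq_along(idx), labv)
  labsU <- as.integer(names(groups))
  # keep label order = first-voxel scan order
  first <- vapply(groups, function(g) min(idx[g]), numeric(1))
  ordL <- order(first)
  groups <- groups[ordL]
  labsU <- labsU[ordL]
  rows <- lapply(seq_along(groups), function(k) {
    g <- groups[[k]]
    cz <- coords[g, 1]
    cy <- coords[g, 2]
    cx <- coords[g, 3]
    n <- length(g)
    b0 <- c(min(cz), min(cy), min(cx)) - 1L # 0-based half-open box
    b1 <- c(max(cz), max(cy), max(cx))
    bdim <- b1 - b0
    crop <- array(FALSE, bdim)
    crop[cbind(cz - b0[1], cy - b0[2], cx - b0[3])] <- TRUE
    filled <- array(
      cpp_fill_holes3d(as.vector(crop), as.integer(bdim)),
      bdim
    )
    nFilled <- sum(filled)
    nConvex <- convexCountSlices(filled)
    eul <- eulerNumber3D(crop)
    # physical coordinates for shape moments
    pz <- (cz - 1) * voxelSizeUm[1]
    py <- (cy - 1) * voxelSizeUm[2]
    px <- (cx - 1) * voxelSizeUm[3]
    P <- cbind(pz, py, px)
    ctr <- colMeans(P)
    Pc <- sweep(P, 2, ctr)
    C <- crossprod(Pc) / n
    ev <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
      decreasing = TRUE)
    ev[ev < 0] <- 0
    # uniform solid ellipsoid: Cov = diag(a^2, b^2, c^2) / 5
    majorLen <- 2 * sqrt(5 * ev[1])
    minorLen <- 2 * sqrt(5 * ev[3])
    inert <- sort(sum(ev) - ev, decreasing = TRUE) # inertia tensor eigvals
    row <- data.frame(
      label = labsU[k],
      centroid_z = mean(cz) - 1 + offset[1],
      centroid_y = mean(cy) - 1 + offset[2],
      centroid_x = mean(cx) - 1 + offset[3],
      bbox_zmin = b0[1] + offset[1], bbox_ymin = b0[2] + offset[2],
      bbox_xmin = b0[3] + offset[3],
      bbox_zmax = b1[1] + offset[1], bbox_ymax = b1[2] + offset[2],
      bbox_xmax = b1[3] + offset[3],
      volume = n * dV,
      volume_bbox = prod(bdim) * dV,
      volume_filled = nFilled * dV,
      volume_convex = nConvex * dV,
      major_axis_length = majorLen,
      minor_axis_length = minorLen,
      euler_number = eul,
      extent = n / prod(bdim),
      solidity = nFilled / nConvex
    )
    if (eccentricity) {
      row$eccentricity <- if (majorLen > 0) minorLen / majorLen else 1
    }
    for (ch in names(intensity)) {
      vals <- intensity[[ch]][idx[g]]
      row[[paste0("intensity_max_", ch)]] <- max(vals)
      row[[paste0("intensity_min_", ch)]] <- min(vals)
      row[[paste0("intensity_mean_", ch)]] <- mean(vals)
    }
    row$inertia_tensor_eigvals1 <- inert[1]
    row$inertia_tensor_eigvals2 <- inert[2]
    row$inertia_tensor_eigvals3 <- inert[3]
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
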