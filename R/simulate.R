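# Ground-truthed synthetic plate generator.
#
# A well is a slab of anisotropic voxels holding non-overlapping spherical
# organoids; each organoid is a weakly fluorescent body packed with
# minimum-separation nuclei rendered as anisotropy-aware Gaussian blobs in
# their clone's channel. Dead nuclei are additionally rendered in the
# dead-dye channel; Gaussian read noise and optional point debris complete
# the image. Truth coordinates are micrometres in the well frame with the
# same 0-based voxel-centre convention as the measurement code.

truncNorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  v <- stats::rnorm(n, mean, sd)
  pmin(pmax(v, lo), hi)
}

# Labels n points with clone A at rate `fraction`; alpha interpolates from
# uniform random labeling (0) to a contiguous cluster grown by
# nearest-neighbour contagion from a seed cell (1).
assignClones <- function(points, fraction, alpha,
                         clones = c("A", "B")) {
  n <- nrow(points)
  nA <- stats::rbinom(1, n, fraction)
  lab <- rep(clones[2], n)
  if (nA == 0) {
    return(lab)
  }
  if (nA == n) {
    return(rep(clones[1], n))
  }
  D <- as.matrix(stats::dist(points))
  isA <- rep(FALSE, n)
  seedIdx <- sample.int(n, 1)
  isA[seedIdx] <- TRUE
  while (sum(isA) < nA) {
    cand <- which(!isA)
    if (stats::runif(1) < alpha) {
      # contagion: closest unlabeled cell to the current A cluster
      dmin <- apply(D[cand, isA, drop = FALSE], 1, min)
      pick <- cand[which.min(dmin)]
    } else {
      pick <- cand[sample.int(length(cand), 1)]
    }
    isA[pick] <- TRUE
  }
  lab[isA] <- clones[1]
  lab
}

#' Pack nucleus centres inside one organoid
#'
#' Rejection-samples points uniformly in a sphere of radius
#' `radius - nucleusRadius` with a minimum centre-to-centre separation.
#'
#' @param n points requested.
#' @param radius organoid radius (um).
#' @param nucleusRadius nucleus radius kept clear of the boundary (um).
#' @param minSep minimum separation (um).
#' @param maxTry placement attempts per point.
#' @return m x 3 matrix (z, y, x) relative to the organoid centre; m <= n
#'   when packing saturates.
#' @export
packNuclei <- function(n, radius, nucleusRadius, minSep, maxTry = 200L) {
  rmax <- radius - nucleusRadius
  if (rmax <= 0) stop("organoid radius smaller than nucleus radius")
  pts <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(maxTry)) {
      p <- stats::runif(3, -rmax, rmax)
      if (sum(p^2) > rmax^2) next
      if (nrow(pts) &&
        min(sqrt(colSums((t(pts) - p)^2))) < minSep) {
        next
      }
      pts <- rbind(pts, p)
      placed <- TRUE
      break
    }
    if (!placed) break
  }
  unname(pts)
}

# Sample non-overlapping organoid centres in the imaged slab.
packOrganoids <- function(cfg, maxAttempts = 5000L) {
  lay <- cfg@layout
  vs <- lay@voxelSizeUm
  sizeUm <- c(
    (lay@planesPerField - 1) * vs[1],
    (lay@fieldGrid[1] * lay@fieldShapePx[1] - 1) * vs[2],
    (lay@fieldGrid[2] * lay@fieldShapePx[2] - 1) * vs[3]
  )
  margin <- 5
  gap <- 15
  centers <- matrix(numeric(0), ncol = 3)
  radii <- numeric(0)
  attempts <- 0L
  while (length(radii) < cfg@nOrganoids) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts) {
      stop(
        "infeasible packing: placed ", length(radii), " of ",
        cfg@nOrganoids, " organoids after ", maxAttempts, " attempts"
      )
    }
    r <- truncNorm(
      1, cfg@organoidRadiusUm[1], cfg@organoidRadiusUm[2],
      cfg@organoidRadiusUm[3], cfg@organoidRadiusUm[4]
    )
    lo <- r + margin
    hi <- sizeUm - r - margin
    if (any(hi <= lo)) next
    c0 <- stats::runif(3, lo, hi)
    if (nrow(centers)) {
      d <- sqrt(colSums((t(centers) - c0)^2))
      if (any(d < radii + r + gap)) next
    }
    centers <- rbind(centers, c0)
    radii <- c(radii, r)
  }
  list(centers = unname(centers), radii = radii)
}

# PSF width tied to the nucleus radius; the soft skirt this produces is
# what gives the watershed an intensity valley between touching nuclei.
blobSigmaUm <- function(radius) pmax(1, 0.25 * radius)

# Add one soft-edged nucleus blob: a sphere of the truth radius convolved
# with an isotropic PSF (erf edge profile), so the half-maximum contour
# sits exactly at the truth radius.
addBlob <- function(vol, centerUm, radiusUm, amplitude, vs,
                    sigmaUm = blobSigmaUm(radiusUm)) {
  d <- dim(vol)
  ext <- radiusUm + 3 * sigmaUm
  lo <- pmax(floor((centerUm - ext) / vs) + 1, 1)
  hi <- pmin(ceiling((centerUm + ext) / vs) + 1, d)
  if (any(hi < lo)) {
    return(vol)
  }
  iz <- lo[1]:hi[1]
  iy <- lo[2]:hi[2]
  ix <- lo[3]:hi[3]
  dz2 <- (((iz - 1) * vs[1] - centerUm[1]))^2
  dy2 <- (((iy - 1) * vs[2] - centerUm[2]))^2
  dx2 <- (((ix - 1) * vs[3] - centerUm[3]))^2
  dist <- sqrt(outer(outer(dz2, dy2, "+"), dx2, "+"))
  vol[iz, iy, ix] <- vol[iz, iy, ix] +
    amplitude * stats::pnorm((radiusUm - dist) / sigmaUm)
  vol
}

addBall <- function(vol, centerUm, radius, amplitude, vs) {
  d <- dim(vol)
  lo <- pmax(floor((centerUm - radius) / vs) + 1, 1)
  hi <- pmin(ceiling((centerUm + radius) / vs) + 1, d)
  iz <- lo[1]:hi[1]
  iy <- lo[2]:hi[2]
  ix <- lo[3]:hi[3]
  dz2 <- (((iz - 1) * vs[1] - centerUm[1]))^2
  dy2 <- (((iy - 1) * vs[2] - centerUm[2]))^2
  dx2 <- (((ix - 1) * vs[3] - centerUm[3]))^2
  inside <- outer(outer(dz2, dy2, "+"), dx2, "+") <= radius^2
  vol[iz, iy, ix] <- vol[iz, iy, ix] + amplitude * inside
  vol
}

#' Simulate one well with ground truth
#'
#' Draws organoid centres and radii, packs clone-labelled nuclei inside
#' each, optionally thins nuclei per clone (dose survival), renders the
#' image volume and returns the truth tables. Fully deterministic given
#' `cfg@seed`.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param survival named per-clone survival probabilities (binomial
#'   thinning), e.g. `c(A = 1, B = 0.5)`; names A/B refer to the first and
#'   second fluorescence channels.
#' @param volumeMultiplier nucleus volume multiplier (dose effect).
#' @param intensityMultiplier nucleus intensity multiplier (dose effect).
#' @param render FALSE skips image rendering and returns truth only (fast
#'   path for point-pattern and dose studies).
#' @param wellId well (row, col).
#' @return list with `vol` (\linkS4class{WellVolume} or NULL), `organoids`
#'   and `nuclei` truth data.frames. Nucleus truth columns: organoid id,
#'   centroid (z, y, x) in um (well frame), radius, clone ("A"/"B"), clone
#'   channel name, dead flag.
#' @export
simulateWell <- function(cfg, survival = c(A = 1, B = 1),
                         volumeMultiplier = 1, intensityMultiplier = 1,
                         render = TRUE, wellId = c(1L, 1L)) {
  set.seed(cfg@seed)
  lay <- cfg@layout
  vs <- lay@voxelSizeUm
  orgs <- packOrganoids(cfg)
  nOrg <- length(orgs$radii)
  fluor <- setdiff(lay@channels, cfg@deadChannel)[1:2]
  nucRows <- list()
  orgRows <- list()
  for (k in seq_len(nOrg)) {
    nWant <- stats::rpois(1, cfg@nucleiPerOrganoid)
    rel <- packNuclei(
      nWant, orgs$radii[k], cfg@nucleusRadiusUm[1],
      cfg@nucleusMinSepUm
    )
    m <- nrow(rel)
    if (m == 0) next
    clone <- if (m == 1) {
      if (stats::runif(1) < cfg@cloneFraction) "A" else "B"
    } else {
      assignClones(rel, cfg@cloneFraction, cfg@affinity)
    }
    # binomial thinning by per-clone survival
    keep <- stats::runif(m) <= unname(survival[clone])
    rel <- rel[keep, , drop = FALSE]
    clone <- clone[keep]
    m <- nrow(rel)
    if (m == 0) next
    radii <- truncNorm(
      m, cfg@nucleusRadiusUm[1], cfg@nucleusRadiusUm[2],
      lo = 0.5 * cfg@nucleusRadiusUm[1]
    ) * volumeMultiplier^(1 / 3)
    dead <- stats::runif(m) < cfg@deadFraction
    amp <- truncNorm(
      m, cfg@nucleusIntensity[1], cfg@nucleusIntensity[2],
      lo = 0.25 * cfg@nucleusIntensity[1]
    ) * intensityMultiplier
    ctr <- sweep(rel, 2, orgs$centers[k, ], "+")
    nucRows[[length(nucRows) + 1L]] <- data.frame(
      organoid = k,
      z_um = ctr[, 1], y_um = ctr[, 2], x_um = ctr[, 3],
      radius_um = radii, clone = clone,
      channel = fluor[match(clone, c("A", "B"))],
      dead = dead, amplitude = amp
    )
    orgRows[[length(orgRows) + 1L]] <- data.frame(
      organoid = k,
      z_um = orgs$centers[k, 1], y_um = orgs$centers[k, 2],
      x_um = orgs$centers[k, 3], radius_um = orgs$radii[k],
      n_nuclei = m, frac_A = mean(clone == "A")
    )
  }
  nuclei <- do.call(rbind, nucRows)
  organoids <- do.call(rbind, orgRows)
  rownames(nuclei) <- rownames(organoids) <- NULL
  vol <- NULL
  if (render) {
    d <- c(
      length(lay@channels), lay@planesPerField,
      lay@fieldGrid[1] * lay@fieldShapePx[1],
      lay@fieldGrid[2] * lay@fieldShapePx[2]
    )
    deadIdx <- match(cfg@deadChannel, lay@channels)
    fluorIdx <- match(fluor, lay@channels)
    # signal volume with channel as the last axis so per-organoid crops can
    # be pasted without copying the full array
    sig <- array(0, c(d[2], d[3], d[4], d[1]))
    for (k in seq_len(nrow(organoids))) {
      octr <- c(organoids$z_um[k], organoids$y_um[k], organoids$x_um[k])
      ext <- organoids$radius_um[k] + 12
      lo <- pmax(floor((octr - ext) / vs) + 1, 1)
      hi <- pmin(ceiling((octr + ext) / vs) + 1, d[2:4])
      cd <- hi - lo + 1
      originUm <- (lo - 1) * vs
      cropCh <- lapply(seq_len(d[1]), function(i) array(0, cd))
      for (ci in fluorIdx) {
        cropCh[[ci]] <- addBall(
          cropCh[[ci]], octr - originUm,
          organoids$radius_um[k], cfg@bodyIntensity, vs
        )
      }
      rows <- which(nuclei$organoid == organoids$organoid[k])
      for (i in rows) {
        nctr <- c(nuclei$z_um[i], nuclei$y_um[i], nuclei$x_um[i]) - originUm
        ci <- match(nuclei$channel[i], lay@channels)
        cropCh[[ci]] <- addBlob(
          cropCh[[ci]], nctr, nuclei$radius_um[i], nuclei$amplitude[i], vs
        )
        if (nuclei$dead[i] && !is.na(deadIdx)) {
          cropCh[[deadIdx]] <- addBlob(
            cropCh[[deadIdx]], nctr, nuclei$radius_um[i],
            cfg@deadIntensity, vs
          )
        }
      }
      iz <- lo[1]:hi[1]
      iy <- lo[2]:hi[2]
      ix <- lo[3]:hi[3]
      for (ci in seq_len(d[1])) {
        blk <- sig[iz, iy, ix, ci, drop = FALSE]
        sig[iz, iy, ix, ci] <- blk + array(cropCh[[ci]], dim(blk))
      }
    }
    # point debris: short bright streaks of 1-3 px in one plane
    if (cfg@debrisRate > 0) {
      nf <- fieldsPerWell(lay)
      for (f in seq_len(nf)) {
        nd <- stats::rpois(1, cfg@debrisRate)
        if (nd == 0) next
        off <- fieldOffset(lay, f)
        for (j in seq_len(nd)) {
          ci <- sample(fluorIdx, 1)
          z <- sample.int(d[2], 1)
          y <- off[1] + sample.int(lay@fieldShapePx[1], 1)
          x <- off[2] + sample.int(lay@fieldShapePx[2], 1)
          len <- sample.int(3, 1)
          ys <- pmin(y + seq_len(len) - 1, d[3])
          sig[z, ys, x, ci] <- sig[z, ys, x, ci] + cfg@debrisIntensity
        }
      }
    }
    arr <- aperm(sig, c(4, 1, 2, 3))
    arr <- arr + cfg@background +
      stats::rnorm(length(arr), 0, cfg@noiseSd)
    arr <- round(arr)
    arr[arr < 0] <- 0
    arr[arr > 65535] <- 65535
    vol <- WellVolume(arr, lay, wellId = wellId)
  }
  nuclei$amplitude <- NULL
  list(vol = vol, organoids = organoids, nuclei = nuclei)
}

#' Simulate a dose ladder of wells
#'
#' One well per (dose, replicate): each clone's nuclei are binomially
#' thinned by its survival curve at that dose, and nucleus volume/intensity
#' multipliers model treatment morphology effects. Seeds are derived
#' deterministically from `cfg@seed`, dose index and replicate.
#'
#' @param cfg base \linkS4class{SimulationConfig}.
#' @param doses numeric vector of doses (uM); include 0 for controls.
#' @param survivalA,survivalB functions dose -> survival in \[0, 1\].
#' @param volumeMultiplier,intensityMultiplier functions dose ->
#'   multiplier (default constant 1).
#' @param replicates wells per dose.
#' @param render render image volumes (FALSE = truth only).
#' @return list of elements with `dose`, `replicate` and the
#'   [simulateWell()] result.
#' @export
simulateDoseLadder <- function(cfg, doses, survivalA, survivalB,
                               volumeMultiplier = function(d) 1,
                               intensityMultiplier = function(d) 1,
                               replicates = 3L, render = FALSE) {
  out <- list()
  for (di in seq_along(doses)) {
    d <- doses[di]
    sv <- c(A = survivalA(d), B = survivalB(d))
    stopifnot(all(sv >= 0 & sv <= 1))
    for (r in seq_len(replicates)) {
      cfgd <- cfg
      cfgd@seed <- as.integer(
        (cfg@seed + 7919L * di + 104729L * r) %% .Machine$integer.max
      )
      res <- simulateWell(cfgd,
        survival = sv,
        volumeMultiplier = volumeMultiplier(d),
        intensityMultiplier = intensityMultiplier(d),
        render = render, wellId = c(di, r)
      )
      out[[length(out) + 1L]] <- c(list(dose = d, replicate = r), res)
    }
  }
  out
}

#' Simulate a single organoid point pattern
#'
#' Fast path used by the spatial statistics: one organoid's nucleus centres
#' and clone labels, no rendering.
#'
#' @param n nuclei requested.
#' @param radius organoid radius (um).
#' @param fraction clone-A fraction.
#' @param alpha spatial affinity in \[0, 1\].
#' @param minSep minimum nucleus separation (um).
#' @param seed RNG seed.
#' @return a \linkS4class{CellPointSet}.
#' @export
simulateOrganoidPoints <- function(n, radius = 45, fraction = 0.5,
                                   alpha = 0, minSep = 9, seed = 1L) {
  set.seed(seed)
  pts <- packNuclei(n, radius, 5, minSep)
  clone <- assignClones(pts, fraction, alpha)
  CellPointSet(pts, clone)
}
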