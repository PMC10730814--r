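# Stage 2: per-organoid nuclei segmentation.
#
# Each organoid is cropped by its (padded) 3D bounding box, each fluorescence
# channel is percentile-normalized and segmented independently, and nucleus
# coordinates are mapped back into the well frame via the recorded offset.
# The segmentation backend is a contract: any function mapping a normalized
# [0,1] crop to an integer label volume can be registered. The default
# backend is a classical anisotropy-aware watershed; an adapter for external
# star-convex CNN models can be registered by the user with the same
# contract (such models are trained elsewhere and their weights are not part
# of this package; note that strongly non-star-convex nuclei are a known
# failure mode of that family).

.backends <- new.env(parent = emptyenv())

#' Register a nuclei segmentation backend
#'
#' @param name backend name.
#' @param fun function(cropChannel, cfg) returning an integer label array of
#'   the crop's shape; every label must be one connected component.
#' @return invisibly, the previous binding (or NULL).
#' @export
registerNucleiBackend <- function(name, fun) {
  old <- if (exists(name, envir = .backends)) get(name, envir = .backends)
  assign(name, fun, envir = .backends)
  invisible(old)
}

#' Configuration of the nuclei segmentation backend
#'
#' The reference star-convex CNN configuration for this imaging regime is
#' anisotropy (9, 1, 1), 64 rays, patch size (16, 128, 128) and a receptive
#' field of (17, 30, 30); it is recorded here for users plugging in such a
#' model. The default classical backend uses: Gaussian smoothing (physical
#' sigma), Otsu threshold, Euclidean distance transform under the physical
#' voxel spacing, then seeds at the local maxima of the distance-weighted
#' smoothed intensity (at least `minSeedSepUm` apart) and a seeded
#' watershed on that map's negation. Weighting the distance map by
#' intensity keeps seeds at nucleus centres both for uniform-intensity
#' objects and for dense blob-shaped nuclei whose thresholded masks merge;
#' a pure distance transform under-segments the latter.
#'
#' @param backend backend name (default "watershed").
#' @param pLow,pHigh normalization percentiles (default 1.0 / 99.8).
#' @param minSeedSepUm minimum physical separation of watershed seeds (um).
#' @param minNucleusVolUm3 nuclei smaller than this are dropped (um^3).
#' @param smoothSigmaUm Gaussian sigma in um before thresholding.
#' @param anisotropy relative (z, y, x) scale factors, recorded for
#'   CNN-style backends.
#' @param rays,patchSize star-convex adapter settings (recorded only).
#' @return a named list.
#' @export
nucleiBackendConfig <- function(backend = "watershed",
                                pLow = 1.0, pHigh = 99.8,
                                minSeedSepUm = 6,
                                minNucleusVolUm3 = 50,
                                smoothSigmaUm = 1,
                                anisotropy = c(9, 1, 1),
                                rays = 64L,
                                patchSize = c(16L, 128L, 128L)) {
  stopifnot(pLow < pHigh, all(anisotropy > 0))
  list(
    backend = backend, pLow = pLow, pHigh = pHigh,
    minSeedSepUm = minSeedSepUm, minNucleusVolUm3 = minNucleusVolUm3,
    smoothSigmaUm = smoothSigmaUm, anisotropy = anisotropy,
    rays = rays, patchSize = patchSize
  )
}

#' Crop one organoid from the well volume
#'
#' Extracts all channels over the organoid's padded half-open bounding box,
#' clipping at the volume edge, and records the crop's 0-based (z, y, x)
#' offset so nucleus coordinates can be mapped back to the well frame.
#'
#' @param vol a \linkS4class{WellVolume}.
#' @param rec one row of the organoid feature table (bbox_* columns).
#' @param padVoxels integer (z, y, x) padding, default (1, 3, 3).
#' @return list with `crop` (channel, z, y, x array) and `offset` (0-based).
#' @export
cropOrganoid <- function(vol, rec, padVoxels = c(1L, 3L, 3L)) {
  d <- dim(vol@data)[2:4]
  raw0 <- c(rec$bbox_zmin, rec$bbox_ymin, rec$bbox_xmin)
  raw1 <- c(rec$bbox_zmax, rec$bbox_ymax, rec$bbox_xmax)
  if (any(raw1 <= raw0)) {
    stop("empty bounding box for organoid ", rec$label)
  }
  lo <- pmax(raw0 - padVoxels, 0)
  hi <- pmin(c(rec$bbox_zmax, rec$bbox_ymax, rec$bbox_xmax) + padVoxels, d)
  if (any(hi <= lo)) stop("empty bounding box for organoid ", rec$label)
  crop <- vol@data[, (lo[1] + 1):hi[1], (lo[2] + 1):hi[2],
    (lo[3] + 1):hi[3], drop = FALSE]
  list(crop = crop, offset = as.integer(lo))
}

#' Percentile normalization of one channel crop
#'
#' `(x - P(pLow)) / (P(pHigh) - P(pLow))`, clipped to \[0, 1\]. A constant
#' crop returns all zeros with a message.
#'
#' @param x numeric array.
#' @param pLow,pHigh percentiles in \[0, 100\].
#' @return array of the same shape, values in \[0, 1\].
#' @export
normalizePercentile <- function(x, pLow = 1.0, pHigh = 99.8) {
  q <- stats::quantile(as.numeric(x), c(pLow, pHigh) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    message("constant crop; normalization returns zeros")
    out <- array(0, dim(x))
    return(out)
  }
  out <- (x - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

watershedBackend <- function(cropChannel, cfg, voxelSizeUm) {
  d <- dim(cropChannel)
  sigmaVox <- cfg$smoothSigmaUm / voxelSizeUm
  sm <- array(
    cpp_gaussian3d(as.numeric(cropChannel), as.integer(d),
      as.numeric(sigmaVox)),
    d
  )
  empty <- array(0L, d)
  if (diff(range(sm)) == 0) {
    return(empty)
  }
  thr <- EBImage::otsu(EBImage::Image(as.numeric(sm), dim = c(length(sm), 1)),
    range = range(sm, 0, 1))
  mask <- sm > thr
  if (!any(mask)) {
    return(empty)
  }
  edt <- cpp_edt3d(as.vector(mask), as.integer(d), as.numeric(voxelSizeUm))
  # distance-weighted intensity: peaks sit at nucleus centres both for
  # uniform-intensity objects (distance dominates) and for blob-shaped
  # nuclei whose above-threshold masks merge (intensity dominates)
  seedMap <- as.numeric(sm) * edt
  cand <- cpp_local_maxima26(seedMap, as.vector(mask), as.integer(d))
  if (!length(cand)) {
    return(empty)
  }
  co <- arrayInd(cand, d)
  phys <- sweep(co - 1, 2, voxelSizeUm, "*")
  keep <- cpp_prune_peaks(phys, seedMap[cand], cfg$minSeedSepUm)
  seeds <- array(0L, d)
  seeds[cand[keep]] <- seq_along(keep)
  lab <- array(
    cpp_watershed3d(-seedMap, as.vector(seeds), as.vector(mask),
      as.integer(d), 6L),
    d
  )
  # drop fragments below the physical size floor, relabel consecutively
  minVox <- cfg$minNucleusVolUm3 / prod(voxelSizeUm)
  counts <- tabulate(lab[lab > 0L])
  keepL <- which(counts >= minVox)
  relab <- integer(length(counts))
  relab[keepL] <- seq_along(keepL)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

#' Segment nuclei in one normalized channel crop
#'
#' Dispatches to the configured backend; the contract is identical for all
#' backends (integer labels, each one connected component). Input is
#' expected normalized to \[0, 1\]; values far outside trigger a warning.
#'
#' @param cropChannel normalized 3D (z, y, x) array.
#' @param cfg [nucleiBackendConfig()].
#' @param voxelSizeUm physical voxel size (dz, dy, dx).
#' @return a \linkS4class{LabeledVolume}.
#' @export
segmentNuclei <- function(cropChannel, cfg = nucleiBackendConfig(),
                          voxelSizeUm = c(1, 1, 1)) {
  if (max(cropChannel) > 1.5 || min(cropChannel) < -0.5) {
    warning("input does not look normalized to [0, 1]")
  }
  fun <- switch(cfg$backend,
    watershed = function(x, cfg) watershedBackend(x, cfg, voxelSizeUm),
    {
      if (!exists(cfg$backend, envir = .backends)) {
        stop(
          "unknown nuclei backend '", cfg$backend,
          "'; register it with registerNucleiBackend()"
        )
      }
      get(cfg$backend, envir = .backends)
    }
  )
  lab <- fun(cropChannel, cfg)
  LabeledVolume(lab, voxelSizeUm)
}

#' Per-nucleus feature table for one organoid channel
#'
#' Same measurement set as [organoidFeatures()] plus eccentricity
#' (minor/major axis length); coordinates are shifted into the well frame by
#' the crop offset. Nuclei touching the crop border are kept but flagged.
#'
#' @param labels \linkS4class{LabeledVolume} from [segmentNuclei()].
#' @param cropChannel the (un- or normalized) intensity crop measured.
#' @param organoidLabel parent organoid id.
#' @param channel channel name recorded in the table.
#' @param offset 0-based (z, y, x) crop offset in the well frame.
#' @return data.frame of nucleus records (`is_dead` initialised FALSE).
#' @export
nucleusFeatures <- function(labels, cropChannel, organoidLabel, channel,
                            offset = c(0L, 0L, 0L)) {
  if (!all(dim(labels@labels) == dim(cropChannel))) {
    stop("label and intensity crop shapes differ")
  }
  df <- regionProps3D(labels@labels, voxelSize(labels),
    intensity = list(own = cropChannel), offset = offset,
    eccentricity = TRUE)
  if (!nrow(df)) {
    return(df)
  }
  names(df)[names(df) == "label"] <- "nucleus_label"
  # intensity statistics refer to the nucleus's own channel, so the columns
  # carry generic names and tables from different channels stack
  names(df) <- sub("^intensity_(max|min|mean)_own$", "intensity_\\1",
    names(df))
  d <- dim(labels@labels)
  df$organoid_label <- organoidLabel
  df$channel <- channel
  df$border_touching <-
    df$bbox_zmin - offset[1] <= 0 | df$bbox_zmax - offset[1] >= d[1] |
    df$bbox_ymin - offset[2] <= 0 | df$bbox_ymax - offset[2] >= d[2] |
    df$bbox_xmin - offset[3] <= 0 | df$bbox_xmax - offset[3] >= d[3]
  df$is_dead <- FALSE
  df
}

#' Segment nuclei in every organoid of a well
#'
#' For each organoid: crop by padded bbox, percentile-normalize each
#' fluorescence channel independently, segment with the configured backend
#' and measure. Channels are processed separately, so a clone's nuclei only
#' appear in its own channel's rows.
#'
#' @param vol a \linkS4class{WellVolume}.
#' @param organoids organoid feature table from [segmentOrganoids()].
#' @param cfg [nucleiBackendConfig()].
#' @param fluorChannels channels to segment (default: all except "DRAQ7" /
#'   "brightfield").
#' @param padVoxels crop padding, see [cropOrganoid()].
#' @return data.frame of nucleus records across all organoids and channels.
#' @export
segmentWellNuclei <- function(vol, organoids, cfg = nucleiBackendConfig(),
                              fluorChannels = NULL,
                              padVoxels = c(1L, 3L, 3L)) {
  layout <- vol@layout
  if (is.null(fluorChannels)) {
    fluorChannels <- setdiff(
      layout@channels,
      c("DRAQ7", "brightfield", "Brightfield")
    )
  }
  vs <- voxelSize(vol)
  out <- list()
  for (i in seq_len(nrow(organoids))) {
    rec <- organoids[i, ]
    cr <- cropOrganoid(vol, rec, padVoxels)
    for (ch in fluorChannels) {
      ci <- resolveChannel(layout, ch)
      raw <- array(cr$crop[ci, , , ], dim = dim(cr$crop)[2:4])
      nrm <- normalizePercentile(raw, cfg$pLow, cfg$pHigh)
      lab <- segmentNuclei(nrm, cfg, vs)
      df <- nucleusFeatures(lab, raw, rec$label, ch, offset = cr$offset)
      if (nrow(df)) out[[length(out) + 1L]] <- df
    }
  }
  if (!length(out)) {
    return(data.frame())
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
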