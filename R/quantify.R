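# Well-level derived quantities: imaged area, dead-cell filtering, counts,
# densities, clone ratios and control normalization.

#' Parameters for the imaged-area estimate
#'
#' @param hugeObjectFrac 2D objects covering more than this fraction of the
#'   projection are discarded as non-organoid artefacts (default 0.25).
#' @param dilationRadius,closingRadius disc radii (px) of the dilation and
#'   binary closing that bridge the space between adjacent organoids.
#' @return named list.
#' @export
imagedAreaParams <- function(hugeObjectFrac = 0.25, dilationRadius = 10L,
                             closingRadius = 10L) {
  list(
    hugeObjectFrac = hugeObjectFrac,
    dilationRadius = as.integer(dilationRadius),
    closingRadius = as.integer(closingRadius)
  )
}

#' Area of the imaged well actually containing organoids
#'
#' Works on the 2D z-maximum projection of the organoid label mask: very
#' large non-organoid objects are removed, the mask is dilated and closed so
#' gaps between adjacent organoids are bridged, and the remaining pixel
#' count is converted to mm^2 with the (dy, dx) pixel size.
#'
#' @param labels \linkS4class{LabeledVolume} from the organoid stage.
#' @param params [imagedAreaParams()].
#' @param pixelSizeUm (dy, dx) in um; defaults to the label volume's voxel
#'   size.
#' @return area in mm^2 (0 with a warning when the mask is empty).
#' @export
imagedArea <- function(labels, params = imagedAreaParams(),
                       pixelSizeUm = NULL) {
  if (is.null(pixelSizeUm)) pixelSizeUm <- voxelSize(labels)[2:3]
  m <- labels@labels > 0L
  proj <- apply(m, c(2, 3), any)
  if (!any(proj)) {
    warning("no organoids labeled; imaged area is 0")
    return(0)
  }
  lab2 <- EBImage::bwlabel(proj)
  areas <- tabulate(lab2[lab2 > 0])
  huge <- which(areas > params$hugeObjectFrac * length(proj))
  if (length(huge)) proj[lab2 %in% huge] <- FALSE
  mask <- proj
  if (params$dilationRadius > 0) {
    mask <- EBImage::dilate(mask, discBrush(params$dilationRadius)) > 0
  }
  if (params$closingRadius > 0) {
    mask <- EBImage::closing(mask, discBrush(params$closingRadius)) > 0
  }
  sum(mask) * prod(pixelSizeUm) / 1e6
}

#' Flag dead nuclei by the dead-cell dye channel
#'
#' Per organoid crop: min-max normalize the dead-dye channel to \[0, 1\], then
#' flag each nucleus whose mean normalized intensity over its bounding box
#' is strictly greater than `threshold` (default 0.1). A crop whose dynamic
#' range is below `minSignalFrac` of the dtype range carries no dye signal
#' (normalizing pure noise would flag everything), so all its nuclei are
#' kept alive.
#'
#' @param nuclei nucleus feature table of one organoid (well-frame bboxes).
#' @param deadCrop 3D (z, y, x) dead-channel crop of that organoid.
#' @param offset 0-based (z, y, x) offset of the crop in the well frame.
#' @param threshold dead cutoff on mean normalized intensity (strict >).
#' @param minSignalFrac minimum (max - min)/dtypeMax to trust the dye.
#' @param dtypeMax storage dtype ceiling.
#' @return `nuclei` with `is_dead` updated.
#' @export
classifyDead <- function(nuclei, deadCrop, offset = c(0L, 0L, 0L),
                         threshold = 0.1, minSignalFrac = 0.05,
                         dtypeMax = 65535) {
  if (!nrow(nuclei)) {
    return(nuclei)
  }
  rng <- range(deadCrop)
  if (diff(rng) < minSignalFrac * dtypeMax) {
    message("dead channel carries no signal in this organoid; all live")
    nuclei$is_dead <- FALSE
    return(nuclei)
  }
  nrm <- (deadCrop - rng[1]) / diff(rng)
  d <- dim(deadCrop)
  for (i in seq_len(nrow(nuclei))) {
    lo <- pmax(c(
      nuclei$bbox_zmin[i], nuclei$bbox_ymin[i],
      nuclei$bbox_xmin[i]
    ) - offset, 0L)
    hi <- pmin(c(
      nuclei$bbox_zmax[i], nuclei$bbox_ymax[i],
      nuclei$bbox_xmax[i]
    ) - offset, d)
    mu <- mean(nrm[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3]])
    nuclei$is_dead[i] <- mu > threshold
  }
  nuclei
}

#' Apply the dead-cell filter to every organoid of a well
#'
#' @param vol a \linkS4class{WellVolume} with a dead-dye channel.
#' @param organoids organoid feature table.
#' @param nuclei nucleus feature table of the well.
#' @param deadChannel channel name of the dead-cell dye.
#' @param padVoxels crop padding (must match the nuclei stage so bboxes fit).
#' @param ... passed to [classifyDead()].
#' @return `nuclei` with `is_dead` updated.
#' @export
classifyDeadWell <- function(vol, organoids, nuclei, deadChannel = "DRAQ7",
                             padVoxels = c(1L, 3L, 3L), ...) {
  if (!nrow(nuclei)) {
    return(nuclei)
  }
  ci <- resolveChannel(vol@layout, deadChannel)
  for (i in seq_len(nrow(organoids))) {
    rec <- organoids[i, ]
    rows <- which(nuclei$organoid_label == rec$label)
    if (!length(rows)) next
    cr <- cropOrganoid(vol, rec, padVoxels)
    deadCrop <- array(cr$crop[ci, , , ], dim = dim(cr$crop)[2:4])
    nuclei[rows, ] <- classifyDead(nuclei[rows, ], deadCrop,
      offset = cr$offset, dtypeMax = vol@dtypeMax, ...)
  }
  nuclei
}

#' Summarise one well
#'
#' Live-cell counts per fluorescence channel, densities over the imaged
#' area, the clone ratio (first : second fluorescence channel) and the
#' per-organoid clone fractions used by the spatial statistics.
#'
#' @param organoids organoid feature table.
#' @param nuclei nucleus feature table with `is_dead` set.
#' @param areaMm2 imaged area from [imagedArea()].
#' @param wellId integer (row, col).
#' @param channels the two fluorescence channel names (default: the two
#'   distinct channels present in `nuclei`).
#' @param dose,treatment metadata carried into the summary row.
#' @return list with `summary` (one-row data.frame; `ratio_defined` is FALSE
#'   when the denominator clone has no live cells) and `organoidClones`
#'   (per-organoid live counts and fractions).
#' @export
wellSummary <- function(organoids, nuclei, areaMm2, wellId = c(1L, 1L),
                        channels = NULL, dose = NA_real_, treatment = "") {
  live <- nuclei[!nuclei$is_dead, , drop = FALSE]
  if (is.null(channels)) channels <- sort(unique(nuclei$channel))
  counts <- vapply(channels, function(ch) sum(live$channel == ch), numeric(1))
  dens <- if (areaMm2 > 0) counts / areaMm2 else rep(NA_real_, length(counts))
  ratioDefined <- length(channels) >= 2 && counts[2] > 0
  ratio <- if (ratioDefined) counts[1] / counts[2] else NA_real_
  summary <- data.frame(
    well_row = wellId[1], well_col = wellId[2],
    imaged_area_mm2 = areaMm2, n_organoids = nrow(organoids),
    dose = dose, treatment = treatment,
    ratio = ratio, ratio_defined = ratioDefined
  )
  for (i in seq_along(channels)) {
    summary[[paste0("n_cells_", channels[i])]] <- counts[i]
    summary[[paste0("density_", channels[i])]] <- dens[i]
  }
  orgLabels <- sort(unique(live$organoid_label))
  organoidClones <- do.call(rbind, lapply(orgLabels, function(l) {
    sub <- live[live$organoid_label == l, ]
    row <- data.frame(organoid_label = l, n_total = nrow(sub))
    for (ch in channels) {
      row[[paste0("n_", ch)]] <- sum(sub$channel == ch)
      row[[paste0("frac_", ch)]] <- sum(sub$channel == ch) / nrow(sub)
    }
    row
  }))
  list(summary = summary, organoidClones = organoidClones)
}

#' Normalize per-dose clone proportions to the untreated control
#'
#' Divides each well's clone proportion by the mean proportion of the
#' control (dose == `controlDose`) wells, then reports the replicate mean
#' and standard deviation per dose.
#'
#' @param df data.frame with columns `dose` and `value` (one row per well).
#' @param controlDose dose identifying the control wells (default 0).
#' @return data.frame with per-dose `mean` and `sd` of the normalized value;
#'   the per-well normalized values are in attribute "wells".
#' @export
normalizeToControl <- function(df, controlDose = 0) {
  ctrl <- df$value[df$dose == controlDose]
  if (!length(ctrl)) stop("no control wells (dose == ", controlDose, ")")
  ref <- mean(ctrl)
  if (!is.finite(ref) || ref == 0) stop("control mean is zero or undefined")
  df$normalized <- df$value / ref
  agg <- do.call(rbind, lapply(split(df, df$dose), function(s) {
    data.frame(
      dose = s$dose[1], mean = mean(s$normalized),
      sd = stats::sd(s$normalized)
    )
  }))
  agg <- agg[order(agg$dose), ]
  rownames(agg) <- NULL
  attr(agg, "wells") <- df
  agg
}
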