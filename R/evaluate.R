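# Benchmarking against generator ground truth: IoU-based instance matching
# for organoids and nuclei.

# Voxelize a truth sphere into (z, y, x) index ranges + mask, clipped to d.
voxelSphere <- function(centerUm, radiusUm, voxelSizeUm, d) {
  lo <- pmax(floor((centerUm - radiusUm) / voxelSizeUm) + 1, 1)
  hi <- pmin(ceiling((centerUm + radiusUm) / voxelSizeUm) + 1, d)
  if (any(hi < lo)) {
    return(NULL)
  }
  iz <- lo[1]:hi[1]
  iy <- lo[2]:hi[2]
  ix <- lo[3]:hi[3]
  dz2 <- ((iz - 1) * voxelSizeUm[1] - centerUm[1])^2
  dy2 <- ((iy - 1) * voxelSizeUm[2] - centerUm[2])^2
  dx2 <- ((ix - 1) * voxelSizeUm[3] - centerUm[3])^2
  list(
    iz = iz, iy = iy, ix = ix,
    mask = outer(outer(dz2, dy2, "+"), dx2, "+") <= radiusUm^2
  )
}

#' Match segmented organoids to truth spheres by IoU
#'
#' Each truth organoid (sphere) is matched to the predicted label with the
#' highest intersection-over-union; matches at or above the threshold count
#' as true positives. Precision = TP / predicted, recall = TP / truth.
#'
#' @param labels \linkS4class{LabeledVolume} from [segmentOrganoids()].
#' @param truth organoid truth table from [simulateWell()] (`z_um`, `y_um`,
#'   `x_um`, `radius_um`).
#' @param iouThreshold match threshold (default 0.5).
#' @return list with `precision`, `recall`, `f1`, `nMatched`, `iou` (per
#'   truth organoid, best IoU).
#' @export
matchOrganoids <- function(labels, truth, iouThreshold = 0.5) {
  lab <- labels@labels
  vs <- voxelSize(labels)
  d <- dim(lab)
  nPred <- nObjects(labels)
  labVols <- tabulate(lab[lab > 0L])
  best <- numeric(nrow(truth))
  usedLab <- integer(0)
  for (k in seq_len(nrow(truth))) {
    sp <- voxelSphere(
      c(truth$z_um[k], truth$y_um[k], truth$x_um[k]),
      truth$radius_um[k], vs, d
    )
    if (is.null(sp)) next
    sub <- array(lab[sp$iz, sp$iy, sp$ix], dim(sp$mask))
    tvol <- sum(sp$mask)
    cands <- setdiff(unique(as.vector(sub[sp$mask])), c(0L, usedLab))
    bestL <- 0L
    for (l in cands) {
      inter <- sum(sub[sp$mask] == l)
      iou <- inter / (tvol + labVols[l] - inter)
      if (iou > best[k]) {
        best[k] <- iou
        bestL <- l
      }
    }
    if (best[k] >= iouThreshold) usedLab <- c(usedLab, bestL)
  }
  tp <- sum(best >= iouThreshold)
  list(
    precision = if (nPred > 0) tp / nPred else NA_real_,
    recall = tp / nrow(truth),
    f1 = if (nPred + nrow(truth) > 0) 2 * tp / (nPred + nrow(truth))
         else NA_real_,
    nMatched = tp, iou = best
  )
}

#' Nucleus segmentation F1 against truth spheres
#'
#' Re-runs the nuclei backend on every organoid crop and greedily matches
#' truth nuclei (voxelized spheres) to predicted labels at the given IoU
#' threshold, per channel.
#'
#' @param vol the rendered \linkS4class{WellVolume}.
#' @param organoids organoid feature table from [segmentOrganoids()].
#' @param truthNuclei nucleus truth table from [simulateWell()].
#' @param cfg [nucleiBackendConfig()].
#' @param iouThreshold match threshold (default 0.4).
#' @param channels fluorescence channels (default the channels appearing in
#'   the truth table).
#' @param padVoxels crop padding, as in [segmentWellNuclei()].
#' @return list with `f1`, `precision`, `recall`, `nPred`, `nTruth`, `tp`.
#' @export
nucleusSegmentationF1 <- function(vol, organoids, truthNuclei,
                                  cfg = nucleiBackendConfig(),
                                  iouThreshold = 0.4, channels = NULL,
                                  padVoxels = c(1L, 3L, 3L)) {
  if (is.null(channels)) channels <- unique(truthNuclei$channel)
  vs <- voxelSize(vol)
  tp <- 0L
  nPred <- 0L
  nTruth <- 0L
  for (k in seq_len(nrow(organoids))) {
    rec <- organoids[k, ]
    cr <- cropOrganoid(vol, rec, padVoxels)
    cd <- dim(cr$crop)[2:4]
    for (ch in channels) {
      ci <- resolveChannel(vol@layout, ch)
      raw <- array(cr$crop[ci, , , ], cd)
      lab <- labelData(segmentNuclei(normalizePercentile(
        raw, cfg$pLow, cfg$pHigh), cfg, vs))
      nPred <- nPred + length(setdiff(unique(as.vector(lab)), 0L))
      tr <- truthNuclei[truthNuclei$channel == ch, , drop = FALSE]
      if (!nrow(tr)) next
      trVox <- cbind(tr$z_um / vs[1], tr$y_um / vs[2], tr$x_um / vs[3])
      inCrop <- trVox[, 1] >= cr$offset[1] &
        trVox[, 1] < cr$offset[1] + cd[1] &
        trVox[, 2] >= cr$offset[2] &
        trVox[, 2] < cr$offset[2] + cd[2] &
        trVox[, 3] >= cr$offset[3] &
        trVox[, 3] < cr$offset[3] + cd[3]
      tr <- tr[inCrop, , drop = FALSE]
      nTruth <- nTruth + nrow(tr)
      if (!nrow(tr)) next
      labVols <- tabulate(lab[lab > 0L])
      usedLab <- integer(0)
      for (i in seq_len(nrow(tr))) {
        ctr <- c(tr$z_um[i], tr$y_um[i], tr$x_um[i]) - cr$offset * vs
        sp <- voxelSphere(ctr, tr$radius_um[i], vs, cd)
        if (is.null(sp)) next
        sub <- array(lab[sp$iz, sp$iy, sp$ix], dim(sp$mask))
        cands <- setdiff(unique(as.vector(sub[sp$mask])), c(0L, usedLab))
        bestIou <- 0
        bestL <- 0L
        for (l in cands) {
          inter <- sum(sub[sp$mask] == l)
          iou <- inter / (sum(sp$mask) + labVols[l] - inter)
          if (iou > bestIou) {
            bestIou <- iou
            bestL <- l
          }
        }
        if (bestIou >= iouThreshold) {
          tp <- tp + 1L
          usedLab <- c(usedLab, bestL)
        }
      }
    }
  }
  list(
    f1 = if (nPred + nTruth > 0) 2 * tp / (nPred + nTruth) else NA_real_,
    precision = if (nPred > 0) tp / nPred else NA_real_,
    recall = if (nTruth > 0) tp / nTruth else NA_real_,
    nPred = nPred, nTruth = nTruth, tp = tp
  )
}
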