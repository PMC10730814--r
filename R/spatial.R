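# Clone co-localization statistics on per-organoid point sets.
#
# For clone X in one organoid, the per-cell score is Lc = X_n / (K * R_x)
# where X_n counts clone-X cells among the focal cell's K nearest
# neighbours (focal excluded from its window) and R_x is clone X's overall
# fraction in the organoid (focal included). The organoid score Lo is the
# mean of Lc over clone-X cells; 1 corresponds to random mixing. The radial
# variant replaces the K-cell window by a ball of radius r_i = i * r_max/6.

#' Per-organoid cell point set
#'
#' Nucleus centroids in physical micrometres together with per-cell clone
#' labels; the input of the localization statistics. At least two cells are
#' required for any score.
#'
#' @slot points n x 3 matrix of (z, y, x) centroids in um.
#' @slot clone character vector of per-point clone labels.
#' @slot organoidLabel id of the parent organoid.
#' @export
setClass("CellPointSet",
  representation(
    points = "matrix", clone = "character",
    organoidLabel = "integer"
  )
)

setValidity("CellPointSet", function(object) {
  if (ncol(object@points) != 3L) return("points must be n x 3 (z, y, x)")
  if (nrow(object@points) != length(object@clone)) {
    return("one clone label per point is required")
  }
  if (nrow(object@points) < 2L) return("at least 2 points required")
  TRUE
})

#' @rdname CellPointSet-class
#' @param points,clone,organoidLabel see slots.
#' @return a validated \code{CellPointSet}.
#' @export
CellPointSet <- function(points, clone, organoidLabel = 1L) {
  new("CellPointSet",
    points = as.matrix(points), clone = as.character(clone),
    organoidLabel = as.integer(organoidLabel)
  )
}

#' Build CellPointSets from a nucleus feature table
#'
#' Converts voxel centroids to physical um and groups live nuclei by
#' organoid; the clone label is the nucleus channel.
#'
#' @param nuclei nucleus feature table (`is_dead` rows are dropped).
#' @param voxelSizeUm (dz, dy, dx) in um.
#' @param minCells organoids with fewer live cells are skipped.
#' @return named list of \linkS4class{CellPointSet}, one per organoid.
#' @export
pointSetsFromNuclei <- function(nuclei, voxelSizeUm, minCells = 2L) {
  live <- nuclei[!nuclei$is_dead, , drop = FALSE]
  out <- list()
  for (l in sort(unique(live$organoid_label))) {
    sub <- live[live$organoid_label == l, ]
    if (nrow(sub) < minCells) next
    pts <- cbind(
      sub$centroid_z * voxelSizeUm[1],
      sub$centroid_y * voxelSizeUm[2],
      sub$centroid_x * voxelSizeUm[3]
    )
    out[[as.character(l)]] <- CellPointSet(pts, sub$channel, l)
  }
  out
}

setMethod("show", "CellPointSet", function(object) {
  tab <- table(object@clone)
  cat(
    "CellPointSet (organoid ", object@organoidLabel, "): ",
    nrow(object@points), " cells [",
    paste(names(tab), tab, sep = "=", collapse = ", "), "]\n",
    sep = ""
  )
})

pairwiseDistances <- function(points) {
  as.matrix(stats::dist(points))
}

#' K nearest neighbours of one cell
#'
#' Euclidean distances in the point set's physical units; the focal cell is
#' excluded from its own window; exact ties are broken by stable index
#' order.
#'
#' @param points n x 3 coordinate matrix (um).
#' @param focal 1-based index of the focal cell.
#' @param K window size; must satisfy `K <= n - 1`.
#' @param D optional precomputed distance matrix.
#' @return integer vector of K neighbour indices, nearest first.
#' @export
knnWindow <- function(points, focal, K, D = NULL) {
  n <- nrow(points)
  if (K > n - 1L) {
    stop("K = ", K, " exceeds the number of available neighbours (", n - 1,
      ")")
  }
  d <- if (is.null(D)) {
    sqrt(colSums((t(points) - points[focal, ])^2))
  } else {
    D[focal, ]
  }
  ord <- order(d, seq_len(n))
  ord <- ord[ord != focal]
  ord[seq_len(K)]
}

cloneFraction <- function(ps, cloneX) {
  mean(ps@clone == cloneX)
}

#' Windowed clone localization score
#'
#' @param ps a \linkS4class{CellPointSet}.
#' @param cloneX clone label to score.
#' @param K number of neighbouring cells per window.
#' @param includeFocalInRx include the focal cell in the organoid-wide clone
#'   fraction R_x (default TRUE, the organoid-wide proportion).
#' @return list with `clone`, `K`, `Lo`, per-cell `Lc`, `Rx` and `n` (number
#'   of clone-X cells).
#' @export
localizationScore <- function(ps, cloneX, K, includeFocalInRx = TRUE) {
  n <- nrow(ps@points)
  if (n < K + 1L) {
    stop("organoid has ", n, " cells; need at least K + 1 = ", K + 1)
  }
  isX <- ps@clone == cloneX
  if (!any(isX)) stop("clone absent: ", cloneX)
  D <- pairwiseDistances(ps@points)
  focals <- which(isX)
  lc <- vapply(focals, function(i) {
    rx <- if (includeFocalInRx) {
      mean(isX)
    } else {
      mean(isX[-i])
    }
    nb <- knnWindow(ps@points, i, K, D = D)
    sum(isX[nb]) / (K * rx)
  }, numeric(1))
  list(
    clone = cloneX, K = K, Lo = mean(lc), Lc = lc,
    Rx = mean(isX), n = length(focals)
  )
}

#' Radial clone localization score
#'
#' Neighbourhoods are balls of radius r_i = i * r_max / 6 around each
#' clone-X cell, where r_max is the largest pairwise distance in the
#' organoid; the focal cell is excluded. Cells with no neighbour within r_i
#' are skipped with a warning; if all are skipped an error is raised.
#' Results are conventionally reported at i = 2.
#'
#' @param ps a \linkS4class{CellPointSet}.
#' @param cloneX clone label to score.
#' @param i radius step in 1..6.
#' @return list with `clone`, `i`, `radius`, `Lo`, per-cell `Lc`, `n`.
#' @export
radialLocalizationScore <- function(ps, cloneX, i = 2L) {
  stopifnot(i >= 1L, i <= 6L)
  n <- nrow(ps@points)
  isX <- ps@clone == cloneX
  if (!any(isX)) stop("clone absent: ", cloneX)
  D <- pairwiseDistances(ps@points)
  rmax <- max(D)
  ri <- i * rmax / 6
  rx <- mean(isX)
  focals <- which(isX)
  lc <- rep(NA_real_, length(focals))
  for (k in seq_along(focals)) {
    f <- focals[k]
    nb <- which(D[f, ] <= ri)
    nb <- nb[nb != f]
    if (!length(nb)) {
      warning("cell ", f, " has no neighbour within r_", i, "; skipped")
      next
    }
    lc[k] <- mean(isX[nb]) / rx
  }
  if (all(is.na(lc))) stop("no cell has neighbours within r_", i)
  list(
    clone = cloneX, i = i, radius = ri, Lo = mean(lc, na.rm = TRUE),
    Lc = lc, n = sum(!is.na(lc))
  )
}

#' Permutation null for the localization score
#'
#' Shuffles clone labels over the fixed cell geometry and recomputes Lo;
#' one-sided p = (1 + #(Lo_perm >= Lo_obs)) / (1 + nPerm).
#'
#' @param ps a \linkS4class{CellPointSet}.
#' @param cloneX clone label to score.
#' @param K window size.
#' @param nPerm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return list with `observed`, `null` (vector of permuted Lo) and `p`.
#' @export
permutationNull <- function(ps, cloneX, K, nPerm = 1000L, seed = 1L) {
  stopifnot(nPerm >= 100L)
  obs <- localizationScore(ps, cloneX, K)$Lo
  set.seed(seed)
  null <- vapply(seq_len(nPerm), function(b) {
    shuffled <- new("CellPointSet",
      points = ps@points,
      clone = sample(ps@clone), organoidLabel = ps@organoidLabel
    )
    localizationScore(shuffled, cloneX, K)$Lo
  }, numeric(1))
  list(observed = obs, null = null,
    p = (1 + sum(null >= obs)) / (1 + nPerm))
}

#' Bin per-organoid scores by clone fraction
#'
#' Bins organoids into clone-fraction intervals \[0, w), \[w, 2w), ... and
#' summarises the score distribution per bin; empty bins are omitted.
#'
#' @param df data.frame with columns `fraction` and `score` (one row per
#'   organoid).
#' @param binWidth bin width, default 0.2.
#' @return data.frame with bin bounds, n, mean and median score per bin.
#' @export
stratifyByFraction <- function(df, binWidth = 0.2) {
  edges <- seq(0, 1, by = binWidth)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  bin <- findInterval(df$fraction, edges, rightmost.closed = TRUE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    s <- df$score[bin == b]
    data.frame(
      bin_lo = edges[b], bin_hi = edges[b + 1], n = length(s),
      mean = mean(s), median = stats::median(s)
    )
  }))
  rownames(out) <- NULL
  out
}

#' Restrict to organoids with comparable clone fractions
#'
#' Keeps organoids whose clone fraction lies in \[lo, hi\] (default 0.4-0.6),
#' the filter used when contrasting homogeneously vs heterogeneously mixed
#' organoids so clonal fraction does not confound the score.
#'
#' @param df data.frame with a `fraction` column.
#' @param lo,hi inclusive bounds.
#' @return the filtered data.frame.
#' @export
filterComparableFractions <- function(df, lo = 0.4, hi = 0.6) {
  df[df$fraction >= lo & df$fraction <= hi, , drop = FALSE]
}
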