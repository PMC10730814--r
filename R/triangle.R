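#' Triangle histogram threshold
#'
#' Geometric threshold selection: build a histogram, draw the line from the
#' histogram peak to the farthest non-empty bin, and return the bin whose
#' (index, scaled count) point lies at maximum perpendicular distance below
#' that line. Counts are scaled so the peak height equals `nbins - 1`, making
#' the geometry invariant to the absolute number of pixels. Designed for
#' strongly skewed fluorescence histograms where the background forms the
#' dominant peak and the signal a long thin tail.
#'
#' @param image numeric array of any dimension (values, not a histogram).
#' @param nbins number of histogram bins, default 256.
#' @return threshold in intensity units (centre of the selected bin); pixels
#'   strictly above it are foreground.
#' @seealso [triangleThresholdBin()] for the bin-level computation.
#' @export
triangleThreshold <- function(image, nbins = 256L) {
  v <- as.numeric(image)
  rng <- range(v)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    stop("degenerate histogram: image is constant")
  }
  bin <- pmin(floor((v - rng[1]) / diff(rng) * nbins) + 1L, nbins)
  counts <- tabulate(bin, nbins)
  b <- triangleThresholdBin(counts)
  rng[1] + (b - 0.5) / nbins * diff(rng)
}

#' @rdname triangleThreshold
#' @param counts integer histogram counts.
#' @return `triangleThresholdBin`: the selected 1-based bin index.
#' @export
triangleThresholdBin <- function(counts) {
  nbins <- length(counts)
  if (nbins < 2L || all(counts == 0) || sum(counts > 0) == 1L) {
    stop("degenerate histogram")
  }
  peak <- which.max(counts)
  nz <- which(counts > 0)
  tail <- nz[which.max(abs(nz - peak))]
  if (tail == peak) stop("degenerate histogram")
  # scale counts so the peak has height nbins - 1
  ys <- counts * (nbins - 1) / counts[peak]
  x1 <- peak
  y1 <- ys[peak]
  x2 <- tail
  y2 <- ys[tail]
  # implicit line A x + B y + C = 0 through peak and tail
  a <- y2 - y1
  b <- -(x2 - x1)
  cc <- -(a * x1 + b * y1)
  bs <- if (x2 > x1) seq(x1, x2) else seq(x1, x2, by = -1)
  d <- abs(a * bs + b * ys[bs] + cc) / sqrt(a * a + b * b)
  bs[which.max(d)]
}
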