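#' @useDynLib organoid3d, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Plate layout metadata
#'
#' Describes how a multi-well plate was imaged: the well grid, the grid of
#' fields tiled inside each well, the number of z planes, the ordered channel
#' names, the per-field image shape and the physical voxel size.
#'
#' @slot rows,cols number of well rows / columns on the plate.
#' @slot fieldGrid integer length-2, fields tiled per well as
#'   (rows of fields, cols of fields); fields are laid out edge-to-edge with
#'   zero overlap, in row-major order.
#' @slot planesPerField number of z slices per field.
#' @slot channels ordered character vector of channel names.
#' @slot fieldShapePx integer length-2 (height, width) of one field in pixels.
#' @slot voxelSizeUm numeric length-3 (dz, dy, dx) in micrometres.
#'
#' @examples
#' layout <- PlateLayout(fieldGrid = c(2, 2), planesPerField = 5,
#'                       channels = c("EGFP", "mCherry"),
#'                       fieldShapePx = c(64, 64),
#'                       voxelSizeUm = c(5, 1, 1))
#' fieldsPerWell(layout)
#' @export
setClass("PlateLayout",
  representation(
    rows = "integer", cols = "integer",
    fieldGrid = "integer", planesPerField = "integer",
    channels = "character", fieldShapePx = "integer",
    voxelSizeUm = "numeric"
  )
)

setValidity("PlateLayout", function(object) {
  msg <- character()
  if (length(object@fieldGrid) != 2L || any(object@fieldGrid < 1L))
    msg <- c(msg, "fieldGrid must be two positive integers")
  if (length(object@planesPerField) != 1L || object@planesPerField < 1L)
    msg <- c(msg, "planesPerField must be >= 1")
  if (length(object@channels) < 1L)
    msg <- c(msg, "at least one channel is required")
  if (length(object@fieldShapePx) != 2L || any(object@fieldShapePx < 1L))
    msg <- c(msg, "fieldShapePx must be two positive integers")
  if (length(object@voxelSizeUm) != 3L || any(object@voxelSizeUm <= 0))
    msg <- c(msg, "voxelSizeUm components must all be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname PlateLayout-class
#' @param rows,cols well grid dimensions (default 1).
#' @param fieldGrid,planesPerField,channels,fieldShapePx,voxelSizeUm see slots.
#' @return a validated \code{PlateLayout}.
#' @export
PlateLayout <- function(rows = 1L, cols = 1L, fieldGrid = c(1L, 1L),
                        planesPerField = 1L, channels = "ch1",
                        fieldShapePx = c(64L, 64L),
                        voxelSizeUm = c(1, 1, 1)) {
  new("PlateLayout",
    rows = as.integer(rows), cols = as.integer(cols),
    fieldGrid = as.integer(fieldGrid),
    planesPerField = as.integer(planesPerField),
    channels = as.character(channels),
    fieldShapePx = as.integer(fieldShapePx),
    voxelSizeUm = as.numeric(voxelSizeUm)
  )
}

#' One assembled well volume
#'
#' Holds the 4D intensity array of one well in the fixed axis order
#' (channel, z, y, x), together with its layout, well id, and the maximum
#' representable intensity of the storage dtype (65535 for unsigned 16-bit,
#' the default acquisition depth).
#'
#' @slot data 4D numeric/integer array ordered (channel, z, y, x).
#' @slot layout the \linkS4class{PlateLayout} the well was imaged with.
#' @slot wellId integer length-2 (row, col), 1-based.
#' @slot dtypeMax maximum representable intensity of the storage type.
#' @export
setClass("WellVolume",
  representation(
    data = "array", layout = "PlateLayout",
    wellId = "integer", dtypeMax = "numeric"
  )
)

setValidity("WellVolume", function(object) {
  lay <- object@layout
  expect <- c(
    length(lay@channels), lay@planesPerField,
    lay@fieldGrid[1] * lay@fieldShapePx[1],
    lay@fieldGrid[2] * lay@fieldShapePx[2]
  )
  d <- dim(object@data)
  if (length(d) != 4L)
    return("data must be a 4D array (channel, z, y, x)")
  if (!all(d == expect))
    return(sprintf(
      "data shape (%s) does not match layout (%s)",
      paste(d, collapse = "x"), paste(expect, collapse = "x")
    ))
  if (length(object@wellId) != 2L) return("wellId must be (row, col)")
  TRUE
})

#' @rdname WellVolume-class
#' @param data,layout,wellId,dtypeMax see slots.
#' @return a validated \code{WellVolume}.
#' @export
WellVolume <- function(data, layout, wellId = c(1L, 1L), dtypeMax = 65535) {
  new("WellVolume",
    data = data, layout = layout,
    wellId = as.integer(wellId), dtypeMax = as.numeric(dtypeMax)
  )
}

#' Labeled 3D volume
#'
#' Integer label image over (z, y, x): 0 is background, k > 0 is object k.
#' Carries the physical voxel size so downstream measurements are in
#' micrometres.
#'
#' @slot labels 3D integer array (z, y, x).
#' @slot voxelSizeUm numeric length-3 (dz, dy, dx) in micrometres.
#' @export
setClass("LabeledVolume",
  representation(labels = "array", voxelSizeUm = "numeric")
)

setValidity("LabeledVolume", function(object) {
  if (length(dim(object@labels)) != 3L)
    return("labels must be a 3D array (z, y, x)")
  if (length(object@voxelSizeUm) != 3L || any(object@voxelSizeUm <= 0))
    return("voxelSizeUm components must all be > 0")
  if (any(object@labels < 0)) return("labels must be non-negative")
  TRUE
})

#' @rdname LabeledVolume-class
#' @param labels,voxelSizeUm see slots.
#' @return a validated \code{LabeledVolume}.
#' @export
LabeledVolume <- function(labels, voxelSizeUm) {
  storage.mode(labels) <- "integer"
  new("LabeledVolume", labels = labels, voxelSizeUm = as.numeric(voxelSizeUm))
}

#' Fitted n-parameter logistic dose-response curve
#'
#' Parameters of \eqn{f(x) = B + (T - B) / (1 + 10^{b (x_{mid} - x)})^s} on
#' x = log10(dose), with the relative IC50 (dose at the curve midpoint
#' between the fitted asymptotes) and a bootstrap confidence interval.
#'
#' @slot parameters named numeric: bottom, top, xmid (log10 uM, centred
#'   parameterisation resolved to the data scale), slope, asym.
#' @slot nParams 4 or 5 (asym fixed at 1 for the 4-parameter model).
#' @slot ic50 relative IC50 in uM.
#' @slot ic50Absolute dose at which the fitted curve crosses 0.5 (absolute
#'   IC50), NA if never crossed inside the asymptotes.
#' @slot ic50CI95 numeric length-2 bootstrap 95% CI for the relative IC50.
#' @slot rss residual sum of squares.
#' @slot data data.frame of the fitted (dose, response) observations.
#' @slot extrapolated TRUE if ic50 lies outside the observed dose range.
#' @export
setClass("DoseResponseFit",
  representation(
    parameters = "numeric", nParams = "integer",
    ic50 = "numeric", ic50Absolute = "numeric", ic50CI95 = "numeric",
    rss = "numeric", data = "data.frame", extrapolated = "logical"
  )
)

#' Synthetic plate simulation settings
#'
#' All knobs of the ground-truthed synthetic plate generator. Defaults emulate
#' a high-content confocal screen of fluorescently labelled two-clone
#' organoids: a 2x2 field grid of 256x256 px fields, 40 z planes at 5 um
#' spacing with 1 um xy pixels, ~20 organoids per well of radius ~45 um each
#' packed with ~75 nuclei of radius ~5 um, nuclear label intensities rendered
#' as anisotropy-aware Gaussian blobs over a weak cytoplasmic organoid body,
#' plus Gaussian read noise, an optional dead-cell dye channel and point
#' debris.
#'
#' @slot layout \linkS4class{PlateLayout} of the simulated plate.
#' @slot nOrganoids organoids per well.
#' @slot organoidRadiusUm numeric (mean, sd, min, max) of organoid radii.
#' @slot nucleiPerOrganoid Poisson mean of nuclei per organoid.
#' @slot nucleusRadiusUm numeric (mean, sd) of nucleus radii.
#' @slot nucleusMinSepUm minimum centre-to-centre nucleus distance.
#' @slot cloneFraction seeding fraction of clone A (first fluorescence
#'   channel).
#' @slot affinity spatial affinity alpha in \[0,1\]: 0 = labels assigned
#'   uniformly at random, 1 = the two clones form contiguous blocks
#'   (nearest-neighbour label contagion interpolates in between).
#' @slot deadFraction fraction of nuclei rendered in the dead-dye channel.
#' @slot background,noiseSd baseline intensity and Gaussian read noise (u16
#'   counts).
#' @slot bodyIntensity weak cytoplasmic intensity of the organoid body.
#' @slot nucleusIntensity numeric (mean, sd) peak amplitude of nucleus blobs.
#' @slot deadIntensity peak amplitude of dead-dye blobs.
#' @slot debrisRate expected count of bright point debris per field.
#' @slot debrisIntensity debris amplitude.
#' @slot deadChannel name of the dead-dye channel ("" = none).
#' @slot seed integer RNG seed; all output is deterministic given it.
#' @export
setClass("SimulationConfig",
  representation(
    layout = "PlateLayout",
    nOrganoids = "integer",
    organoidRadiusUm = "numeric",
    nucleiPerOrganoid = "numeric",
    nucleusRadiusUm = "numeric",
    nucleusMinSepUm = "numeric",
    cloneFraction = "numeric",
    affinity = "numeric",
    deadFraction = "numeric",
    background = "numeric",
    noiseSd = "numeric",
    bodyIntensity = "numeric",
    nucleusIntensity = "numeric",
    deadIntensity = "numeric",
    debrisRate = "numeric",
    debrisIntensity = "numeric",
    deadChannel = "character",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  frac <- c(object@cloneFraction, object@affinity, object@deadFraction)
  if (any(frac < 0 | frac > 1))
    msg <- c(msg, "cloneFraction, affinity and deadFraction must be in [0,1]")
  if (any(object@organoidRadiusUm[1:2] < 0) || object@organoidRadiusUm[1] <= 0)
    msg <- c(msg, "organoid radius parameters must be positive")
  if (object@nucleusRadiusUm[1] <= 0)
    msg <- c(msg, "nucleus radius must be positive")
  if (object@nucleusMinSepUm <= 0)
    msg <- c(msg, "nucleusMinSepUm must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param layout,nOrganoids,organoidRadiusUm,nucleiPerOrganoid see slots.
#' @param nucleusRadiusUm,nucleusMinSepUm,cloneFraction,affinity see slots.
#' @param deadFraction,background,noiseSd,bodyIntensity see slots.
#' @param nucleusIntensity,deadIntensity,debrisRate,debrisIntensity see slots.
#' @param deadChannel,seed see slots.
#' @return a validated \code{SimulationConfig}.
#' @export
SimulationConfig <- function(layout = simDefaultLayout(),
                             nOrganoids = 20L,
                             organoidRadiusUm = c(45, 8, 30, 60),
                             nucleiPerOrganoid = 75,
                             nucleusRadiusUm = c(5, 0.4),
                             nucleusMinSepUm = 9,
                             cloneFraction = 0.5,
                             affinity = 0,
                             deadFraction = 0.05,
                             background = 120,
                             noiseSd = 30,
                             bodyIntensity = 1500,
                             nucleusIntensity = c(12000, 1500),
                             deadIntensity = 10000,
                             debrisRate = 0,
                             debrisIntensity = 20000,
                             deadChannel = "DRAQ7",
                             seed = 1L) {
  new("SimulationConfig",
    layout = layout, nOrganoids = as.integer(nOrganoids),
    organoidRadiusUm = as.numeric(organoidRadiusUm),
    nucleiPerOrganoid = as.numeric(nucleiPerOrganoid),
    nucleusRadiusUm = as.numeric(nucleusRadiusUm),
    nucleusMinSepUm = as.numeric(nucleusMinSepUm),
    cloneFraction = as.numeric(cloneFraction),
    affinity = as.numeric(affinity),
    deadFraction = as.numeric(deadFraction),
    background = as.numeric(background), noiseSd = as.numeric(noiseSd),
    bodyIntensity = as.numeric(bodyIntensity),
    nucleusIntensity = as.numeric(nucleusIntensity),
    deadIntensity = as.numeric(deadIntensity),
    debrisRate = as.numeric(debrisRate),
    debrisIntensity = as.numeric(debrisIntensity),
    deadChannel = as.character(deadChannel), seed = as.integer(seed)
  )
}

#' Default simulated-plate layout
#'
#' 2x2 fields of 256x256 px, 40 z planes, voxel (5, 1, 1) um, two
#' fluorescence channels plus a dead-cell dye channel.
#' @return a \linkS4class{PlateLayout}.
#' @export
simDefaultLayout <- function() {
  PlateLayout(
    rows = 1L, cols = 1L, fieldGrid = c(2L, 2L), planesPerField = 40L,
    channels = c("EGFP", "mCherry", "DRAQ7"),
    fieldShapePx = c(256L, 256L), voxelSizeUm = c(5, 1, 1)
  )
}
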