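#' Accessors for the core classes
#'
#' Small read-only accessors so downstream code never touches slots directly.
#'
#' @param object a \linkS4class{PlateLayout}, \linkS4class{WellVolume} or
#'   \linkS4class{LabeledVolume}.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("fieldsPerWell", function(object) standardGeneric("fieldsPerWell"))
#' @rdname accessors
#' @export
setGeneric("wellData", function(object) standardGeneric("wellData"))
#' @rdname accessors
#' @export
setGeneric("wellId", function(object) standardGeneric("wellId"))
#' @rdname accessors
#' @export
setGeneric("labelData", function(object) standardGeneric("labelData"))
#' @rdname accessors
#' @export
setGeneric("nObjects", function(object) standardGeneric("nObjects"))
#' @rdname accessors
#' @export
setGeneric("ic50", function(object) standardGeneric("ic50"))

#' @rdname accessors
#' @export
setMethod("voxelSize", "PlateLayout", function(object) object@voxelSizeUm)
#' @rdname accessors
#' @export
setMethod("voxelSize", "WellVolume", function(object)
  object@layout@voxelSizeUm)
#' @rdname accessors
#' @export
setMethod("voxelSize", "LabeledVolume", function(object) object@voxelSizeUm)
#' @rdname accessors
#' @export
setMethod("channelNames", "PlateLayout", function(object) object@channels)
#' @rdname accessors
#' @export
setMethod("channelNames", "WellVolume", function(object)
  object@layout@channels)
#' @rdname accessors
#' @export
setMethod("fieldsPerWell", "PlateLayout", function(object)
  prod(object@fieldGrid))
#' @rdname accessors
#' @export
setMethod("wellData", "WellVolume", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("wellId", "WellVolume", function(object) object@wellId)
#' @rdname accessors
#' @export
setMethod("labelData", "LabeledVolume", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("nObjects", "LabeledVolume", function(object)
  length(setdiff(unique(as.vector(object@labels)), 0L)))
#' @rdname accessors
#' @export
setMethod("ic50", "DoseResponseFit", function(object) object@ic50)

setMethod("show", "PlateLayout", function(object) {
  cat(
    "PlateLayout:", object@rows, "x", object@cols, "wells;",
    object@fieldGrid[1], "x", object@fieldGrid[2], "fields of",
    object@fieldShapePx[1], "x", object@fieldShapePx[2], "px;",
    object@planesPerField, "z planes\n"
  )
  cat(
    " channels:", paste(object@channels, collapse = ", "),
    "| voxel (dz,dy,dx) um:", paste(object@voxelSizeUm, collapse = ", "), "\n"
  )
})

setMethod("show", "WellVolume", function(object) {
  d <- dim(object@data)
  cat(
    "WellVolume r", object@wellId[1], "c", object@wellId[2],
    ": (channel, z, y, x) = ", paste(d, collapse = " x "), "\n",
    sep = ""
  )
})

setMethod("show", "LabeledVolume", function(object) {
  cat(
    "LabeledVolume: ", paste(dim(object@labels), collapse = " x "),
    " (z, y, x), ", nObjects(object), " objects\n",
    sep = ""
  )
})

setMethod("show", "DoseResponseFit", function(object) {
  cat(sprintf(
    "%d-parameter logistic fit: IC50 = %.4g uM (95%% CI %.4g-%.4g)%s\n",
    object@nParams, object@ic50, object@ic50CI95[1], object@ic50CI95[2],
    if (object@extrapolated) " [extrapolated]" else ""
  ))
  p <- object@parameters
  cat(sprintf(
    "  bottom %.3g, top %.3g, xmid %.3g, slope %.3g, asym %.3g; RSS %.3g\n",
    p["bottom"], p["top"], p["xmid"], p["slope"], p["asym"], object@rss
  ))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(
    "SimulationConfig:", object@nOrganoids, "organoids/well, ~",
    object@nucleiPerOrganoid, "nuclei each; clone fraction",
    object@cloneFraction, "; affinity", object@affinity,
    "; dead fraction", object@deadFraction, "; seed", object@seed, "\n"
  )
})
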