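# Minimal Zarr v2 directory store for well volumes.
#
# One well is one 4D (channel, z, y, x) array chunked as (1, 1, H, W), i.e.
# one chunk per z-plane per channel, so reading a single plane touches a
# single chunk file. Chunks are raw little-endian values in C order with no
# compression; metadata lives in `.zarray` / `.zattrs` JSON files as the
# Zarr v2 layout prescribes.

zarrDtype <- function(dtypeMax) if (dtypeMax <= 65535) "<u2" else "<f8"

#' Persist a well volume to a chunked array store
#'
#' Writes a Zarr v2 layout directory: a 4D (channel, z, y, x) array chunked
#' one z-plane per chunk, uncompressed, with the plate metadata stored as
#' array attributes. The round-trip through [readWellStore()] is lossless.
#'
#' @param vol a \linkS4class{WellVolume}.
#' @param path store directory, conventionally named `r{row}c{col}`; it is
#'   created (or emptied of stale chunks) as needed.
#' @return `path`, invisibly.
#' @export
writeWellStore <- function(vol, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(vol@data)
  dtype <- zarrDtype(vol@dtypeMax)
  meta <- list(
    zarr_format = 2L,
    shape = as.list(d),
    chunks = as.list(c(1L, 1L, d[3], d[4])),
    dtype = dtype,
    compressor = NULL,
    fill_value = 0L,
    order = "C",
    filters = NULL,
    dimension_separator = "."
  )
  jsonlite::write_json(meta, file.path(path, ".zarray"),
    auto_unbox = TRUE, null = "null", digits = NA)
  lay <- vol@layout
  attrs <- list(
    well_id = vol@wellId, dtype_max = vol@dtypeMax,
    rows = lay@rows, cols = lay@cols, field_grid = lay@fieldGrid,
    planes_per_field = lay@planesPerField, channels = lay@channels,
    field_shape_px = lay@fieldShapePx, voxel_size_um = lay@voxelSizeUm
  )
  jsonlite::write_json(attrs, file.path(path, ".zattrs"), digits = NA)
  for (ch in seq_len(d[1])) {
    for (pl in seq_len(d[2])) {
      plane <- vol@data[ch, pl, , ]
      con <- file(file.path(path, sprintf("%d.%d.0.0", ch - 1L, pl - 1L)),
        "wb")
      # C order: x fastest within the chunk
      if (dtype == "<u2") {
        v <- as.integer(t(plane))
        # writeBin size=2 needs values in signed 16-bit range
        v <- ifelse(v > 32767L, v - 65536L, v)
        writeBin(v, con, size = 2L, endian = "little")
      } else {
        writeBin(as.double(t(plane)), con, size = 8L, endian = "little")
      }
      close(con)
    }
  }
  invisible(path)
}

readZarrMeta <- function(path) {
  za <- file.path(path, ".zarray")
  if (!file.exists(za)) stop("not a well store (no .zarray): ", path)
  meta <- jsonlite::read_json(za, simplifyVector = TRUE)
  if (!identical(as.integer(meta$zarr_format), 2L)) {
    stop("unsupported store format version")
  }
  meta
}

readStoreChunk <- function(path, meta, ch, pl) {
  fn <- file.path(path, sprintf("%d.%d.0.0", ch - 1L, pl - 1L))
  h <- meta$chunks[3]
  w <- meta$chunks[4]
  if (!file.exists(fn)) {
    return(matrix(meta$fill_value, nrow = h, ncol = w))
  }
  con <- file(fn, "rb")
  on.exit(close(con))
  if (meta$dtype == "<u2") {
    v <- readBin(con, "integer", n = h * w, size = 2L, signed = FALSE,
      endian = "little")
  } else {
    v <- readBin(con, "double", n = h * w, size = 8L, endian = "little")
  }
  if (length(v) != h * w) stop("corrupt chunk: ", fn)
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}

#' Read one z-plane from a well store
#'
#' Touches only the single chunk file holding that plane (plus metadata),
#' never the full volume.
#'
#' @param path store directory.
#' @param channel,plane 1-based indices.
#' @return a 2D (y, x) matrix.
#' @export
readStorePlane <- function(path, channel, plane) {
  meta <- readZarrMeta(path)
  if (channel < 1 || channel > meta$shape[1]) {
    stop("channel index out of range")
  }
  if (plane < 1 || plane > meta$shape[2]) stop("plane index out of range")
  readStoreChunk(path, meta, channel, plane)
}

#' Read a full well volume from a chunked store
#'
#' @param path store directory written by [writeWellStore()].
#' @return a \linkS4class{WellVolume}.
#' @export
readWellStore <- function(path) {
  meta <- readZarrMeta(path)
  attrs <- jsonlite::read_json(file.path(path, ".zattrs"),
    simplifyVector = TRUE)
  layout <- PlateLayout(
    rows = attrs$rows, cols = attrs$cols, fieldGrid = attrs$field_grid,
    planesPerField = attrs$planes_per_field, channels = attrs$channels,
    fieldShapePx = attrs$field_shape_px, voxelSizeUm = attrs$voxel_size_um
  )
  d <- meta$shape
  vol <- array(0, dim = d)
  for (ch in seq_len(d[1])) {
    for (pl in seq_len(d[2])) {
      vol[ch, pl, , ] <- readStoreChunk(path, meta, ch, pl)
    }
  }
  WellVolume(vol, layout, wellId = attrs$well_id, dtypeMax = attrs$dtype_max)
}
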