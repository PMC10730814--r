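#' Parse a plate-layout configuration file
#'
#' Reads a neutral YAML description of how the plate was imaged. Required
#' keys: `rows`, `cols`, `field_grid` (two integers), `planes_per_field`,
#' `channels`, `field_shape_px` (height, width), `voxel_size_um` (dz, dy, dx).
#' Unknown keys are ignored with a warning. Vendor export dialects are not
#' parsed; users translate their instrument metadata into this file once.
#'
#' @param path path to the YAML file.
#' @return a \linkS4class{PlateLayout}.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c(
#'   "rows: 1", "cols: 1", "field_grid: [2, 2]", "planes_per_field: 5",
#'   "channels: [EGFP, mCherry]", "field_shape_px: [64, 64]",
#'   "voxel_size_um: [5, 1, 1]"
#' ), f)
#' parsePlateLayout(f)
#' @export
parsePlateLayout <- function(path) {
  if (!file.exists(path)) {
    stop("plate layout config not found: ", path)
  }
  cfg <- yaml::read_yaml(path)
  required <- c(
    "rows", "cols", "field_grid", "planes_per_field", "channels",
    "field_shape_px", "voxel_size_um"
  )
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop(
      "plate layout config is missing required key(s): ",
      paste(missing, collapse = ", ")
    )
  }
  unknown <- setdiff(names(cfg), required)
  if (length(unknown)) {
    warning(
      "ignoring unknown plate layout key(s): ",
      paste(unknown, collapse = ", ")
    )
  }
  PlateLayout(
    rows = cfg$rows, cols = cfg$cols,
    fieldGrid = unlist(cfg$field_grid),
    planesPerField = cfg$planes_per_field,
    channels = unlist(cfg$channels),
    fieldShapePx = unlist(cfg$field_shape_px),
    voxelSizeUm = unlist(cfg$voxel_size_um)
  )
}

#' Write a plate layout back to YAML
#' @param layout a \linkS4class{PlateLayout}.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePlateLayout <- function(layout, path) {
  yaml::write_yaml(list(
    rows = layout@rows, cols = layout@cols,
    field_grid = layout@fieldGrid,
    planes_per_field = layout@planesPerField,
    channels = as.list(layout@channels),
    field_shape_px = layout@fieldShapePx,
    voxel_size_um = layout@voxelSizeUm
  ), path)
  invisible(path)
}

# Top-left (y, x) pixel offset (0-based) of a field in row-major tiling.
fieldOffset <- function(layout, field) {
  gr <- layout@fieldGrid
  fr <- (field - 1L) %/% gr[2]
  fc <- (field - 1L) %% gr[2]
  c(fr * layout@fieldShapePx[1], fc * layout@fieldShapePx[2])
}

#' Assemble per-field tiles into one well volume
#'
#' Places 2D tiles edge-to-edge (no overlap) in row-major field order into the
#' 4D (channel, z, y, x) array. Every (field, plane, channel) combination must
#' be present exactly once; pixel values are copied unmodified.
#'
#' @param tiles a list; each element a list with `field`, `plane`, `channel`
#'   (1-based integers) and `image` (a height x width matrix).
#' @param layout a \linkS4class{PlateLayout}.
#' @param wellId integer (row, col) of the well.
#' @param dtypeMax storage dtype ceiling, default unsigned 16-bit.
#' @return a \linkS4class{WellVolume}.
#' @seealso [disassembleWell()] for the inverse operation.
#' @export
assembleWell <- function(tiles, layout, wellId = c(1L, 1L), dtypeMax = 65535) {
  nf <- fieldsPerWell(layout)
  np <- layout@planesPerField
  nc <- length(layout@channels)
  fs <- layout@fieldShapePx
  key <- vapply(tiles, function(t) {
    paste(t$field, t$plane, t$channel, sep = "/")
  }, character(1))
  expected <- as.vector(outer(
    outer(seq_len(nf), seq_len(np), paste, sep = "/"),
    seq_len(nc), paste,
    sep = "/"
  ))
  dup <- key[duplicated(key)]
  if (length(dup)) {
    stop("duplicate tile(s): ", paste(unique(dup), collapse = ", "))
  }
  miss <- setdiff(expected, key)
  if (length(miss)) {
    stop(
      "missing tile(s) (field/plane/channel): ",
      paste(utils::head(miss, 10), collapse = ", "),
      if (length(miss) > 10) sprintf(" ... and %d more", length(miss) - 10)
    )
  }
  vol <- array(0L, dim = c(
    nc, np, layout@fieldGrid[1] * fs[1],
    layout@fieldGrid[2] * fs[2]
  ))
  for (t in tiles) {
    img <- t$image
    if (!all(dim(img) == fs)) {
      stop(sprintf(
        "tile field %d plane %d channel %d has shape %s, expected %s",
        t$field, t$plane, t$channel, paste(dim(img), collapse = "x"),
        paste(fs, collapse = "x")
      ))
    }
    off <- fieldOffset(layout, t$field)
    vol[
      t$channel, t$plane, off[1] + seq_len(fs[1]),
      off[2] + seq_len(fs[2])
    ] <- img
  }
  WellVolume(vol, layout, wellId = wellId, dtypeMax = dtypeMax)
}

#' Split a well volume back into per-field tiles
#'
#' Inverse of [assembleWell()]: assembly followed by disassembly recovers
#' every tile bit-exactly.
#'
#' @param vol a \linkS4class{WellVolume}.
#' @return list of tiles as accepted by [assembleWell()].
#' @export
disassembleWell <- function(vol) {
  layout <- vol@layout
  fs <- layout@fieldShapePx
  tiles <- vector("list",
    fieldsPerWell(layout) * layout@planesPerField * length(layout@channels))
  i <- 0L
  for (ch in seq_along(layout@channels)) {
    for (pl in seq_len(layout@planesPerField)) {
      for (f in seq_len(fieldsPerWell(layout))) {
        off <- fieldOffset(layout, f)
        i <- i + 1L
        tiles[[i]] <- list(
          field = f, plane = pl, channel = ch,
          image = vol@data[ch, pl, off[1] + seq_len(fs[1]),
            off[2] + seq_len(fs[2])]
        )
      }
    }
  }
  tiles
}

#' Maximum intensity projection along z
#'
#' @param vol a \linkS4class{WellVolume}.
#' @param channel channel name or 1-based index.
#' @return a 2D (y, x) matrix of per-pixel maxima over z.
#' @export
maxProjection <- function(vol, channel) {
  ch <- resolveChannel(vol@layout, channel)
  sub <- vol@data[ch, , , , drop = FALSE]
  apply(array(sub, dim = dim(sub)[2:4]), c(2, 3), max)
}

resolveChannel <- function(layout, channel) {
  if (is.character(channel)) {
    ch <- match(channel, layout@channels)
    if (is.na(ch)) {
      stop(
        "unknown channel '", channel, "'; available: ",
        paste(layout@channels, collapse = ", ")
      )
    }
    ch
  } else {
    ch <- as.integer(channel)
    if (ch < 1L || ch > length(layout@channels)) {
      stop("channel index out of range: ", channel)
    }
    ch
  }
}

#' Write per-field TIFF tiles for a well
#'
#' One 16-bit grayscale TIFF per (field, plane, channel), named
#' `r{row}c{col}f{field}p{plane}ch{channel}.tiff`, plus a `layout.yaml`.
#'
#' @param vol a \linkS4class{WellVolume}.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeWellTiles <- function(vol, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tiles <- disassembleWell(vol)
  for (t in tiles) {
    fn <- file.path(dir, sprintf(
      "r%dc%df%dp%dch%d.tiff", vol@wellId[1], vol@wellId[2],
      t$field, t$plane, t$channel
    ))
    tiff::writeTIFF(t$image / vol@dtypeMax, fn, bits.per.sample = 16L,
      compression = "none")
  }
  writePlateLayout(vol@layout, file.path(dir, "layout.yaml"))
  invisible(dir)
}

#' Read per-field TIFF tiles and assemble a well
#'
#' @param dir directory written by [writeWellTiles()] (or following the same
#'   naming pattern).
#' @param wellId integer (row, col) selecting the well.
#' @param layout optional \linkS4class{PlateLayout}; defaults to
#'   `layout.yaml` in `dir`.
#' @return a \linkS4class{WellVolume}.
#' @export
readWellTiles <- function(dir, wellId = c(1L, 1L), layout = NULL) {
  if (is.null(layout)) layout <- parsePlateLayout(file.path(dir, "layout.yaml"))
  pat <- sprintf("^r%dc%df([0-9]+)p([0-9]+)ch([0-9]+)\\.tiff?$",
    wellId[1], wellId[2])
  files <- list.files(dir, pattern = pat)
  if (!length(files)) stop("no tiles for well r", wellId[1], "c", wellId[2],
    " in ", dir)
  m <- regmatches(files, regexec(pat, files))
  tiles <- lapply(seq_along(files), function(i) {
    img <- tiff::readTIFF(file.path(dir, files[i]))
    list(
      field = as.integer(m[[i]][2]), plane = as.integer(m[[i]][3]),
      channel = as.integer(m[[i]][4]),
      image = round(img * 65535)
    )
  })
  assembleWell(tiles, layout, wellId = wellId)
}
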