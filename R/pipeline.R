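# Per-well orchestration: assemble -> organoid stage -> nuclei stage ->
# dead-cell filter -> well summary, with per-well parallelism. Wells share
# no mutable state, so outputs are identical for any worker count.

#' Pipeline run configuration
#'
#' @param organoidParams [organoidSegParams()].
#' @param nucleiConfig [nucleiBackendConfig()].
#' @param areaParams [imagedAreaParams()].
#' @param deadChannel dead-dye channel name ("" disables the filter).
#' @param deadThreshold dead cutoff, see [classifyDead()].
#' @param fluorChannels fluorescence channels (default: all but the dead
#'   channel and brightfield).
#' @param padVoxels organoid crop padding.
#' @return named list.
#' @export
runConfig <- function(organoidParams = organoidSegParams(),
                      nucleiConfig = nucleiBackendConfig(),
                      areaParams = imagedAreaParams(),
                      deadChannel = "DRAQ7", deadThreshold = 0.1,
                      fluorChannels = NULL,
                      padVoxels = c(1L, 3L, 3L)) {
  list(
    organoidParams = organoidParams, nucleiConfig = nucleiConfig,
    areaParams = areaParams, deadChannel = deadChannel,
    deadThreshold = deadThreshold, fluorChannels = fluorChannels,
    padVoxels = padVoxels
  )
}

atomicWriteCsv <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  path
}

#' Run the full pipeline on one well
#'
#' Executes organoid segmentation, nuclei segmentation, dead-cell filtering
#' and well summary, writing one CSV per stage named by the well's row and
#' column (`organoids_r{row}c{col}.csv`, `nuclei_r{row}c{col}.csv`,
#' `summary_r{row}c{col}.csv`). Writes are atomic (temp file + rename), so
#' reruns overwrite cleanly.
#'
#' @param well a \linkS4class{WellVolume}, a tile directory (read with
#'   [readWellTiles()]) or a chunked store path ([readWellStore()]).
#' @param outDir output directory.
#' @param cfg [runConfig()].
#' @param dose,treatment metadata passed into the summary.
#' @param tilesWellId (row, col); used when `well` is a tile directory.
#' @return list with the stage tables, the imaged area and `paths`.
#' @export
runWell <- function(well, outDir, cfg = runConfig(), dose = NA_real_,
                    treatment = "", tilesWellId = c(1L, 1L)) {
  if (is.character(well)) {
    well <- if (file.exists(file.path(well, ".zarray"))) {
      readWellStore(well)
    } else {
      readWellTiles(well, wellId = tilesWellId)
    }
  }
  stopifnot(is(well, "WellVolume"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  id <- wellId(well)
  seg <- segmentOrganoids(well, cfg$organoidParams,
    fluorChannels = cfg$fluorChannels)
  nuclei <- segmentWellNuclei(well, seg$features, cfg$nucleiConfig,
    fluorChannels = cfg$fluorChannels, padVoxels = cfg$padVoxels)
  if (nzchar(cfg$deadChannel) &&
    cfg$deadChannel %in% channelNames(well) && nrow(nuclei)) {
    nuclei <- classifyDeadWell(well, seg$features, nuclei,
      deadChannel = cfg$deadChannel, padVoxels = cfg$padVoxels,
      threshold = cfg$deadThreshold)
  }
  area <- imagedArea(seg$labels, cfg$areaParams)
  ws <- wellSummary(seg$features, nuclei, area,
    wellId = id, dose = dose, treatment = treatment)
  tagged <- sprintf("r%dc%d", id[1], id[2])
  paths <- c(
    organoids = atomicWriteCsv(seg$features,
      file.path(outDir, paste0("organoids_", tagged, ".csv"))),
    nuclei = atomicWriteCsv(nuclei,
      file.path(outDir, paste0("nuclei_", tagged, ".csv"))),
    summary = atomicWriteCsv(ws$summary,
      file.path(outDir, paste0("summary_", tagged, ".csv")))
  )
  list(
    organoids = seg$features, nuclei = nuclei, labels = seg$labels,
    summary = ws$summary, organoidClones = ws$organoidClones,
    imagedAreaMm2 = area, paths = paths
  )
}

#' Run the pipeline over a plate of wells
#'
#' Fan-out of [runWell()] with optional per-well parallelism (forked
#' workers); a failing well is recorded and does not affect the others.
#'
#' @param wells named list of inputs accepted by [runWell()]; names are
#'   carried into the report.
#' @param outDir output directory.
#' @param cfg [runConfig()].
#' @param doses optional numeric vector (one per well).
#' @param workers parallel workers (default 1 = sequential).
#' @param resume skip wells whose summary CSV already exists.
#' @return list with `summaries` (row-bound summary table of successful
#'   wells) and `errors` (named character of failures).
#' @export
runPlate <- function(wells, outDir, cfg = runConfig(), doses = NULL,
                     workers = 1L, resume = FALSE) {
  if (is.null(names(wells))) names(wells) <- paste0("well", seq_along(wells))
  worker <- function(i) {
    w <- wells[[i]]
    d <- if (is.null(doses)) NA_real_ else doses[i]
    id <- if (is(w, "WellVolume")) wellId(w) else c(1L, 1L)
    outCsv <- file.path(outDir, sprintf("summary_r%dc%d.csv", id[1], id[2]))
    if (resume && file.exists(outCsv)) {
      return(list(ok = TRUE, summary = utils::read.csv(outCsv),
        skipped = TRUE))
    }
    tryCatch(
      {
        res <- runWell(w, outDir, cfg, dose = d)
        list(ok = TRUE, summary = res$summary, skipped = FALSE)
      },
      error = function(e) list(ok = FALSE, error = conditionMessage(e))
    )
  }
  results <- if (workers > 1L) {
    parallel::mclapply(seq_along(wells), worker, mc.cores = workers)
  } else {
    lapply(seq_along(wells), worker)
  }
  ok <- vapply(results, function(r) isTRUE(r$ok), logical(1))
  summaries <- do.call(rbind, lapply(results[ok], `[[`, "summary"))
  errors <- vapply(results[!ok], function(r) {
    if (is.null(r$error)) "unknown error" else r$error
  }, character(1))
  names(errors) <- names(wells)[!ok]
  if (length(errors)) {
    warning("failed wells: ", paste(names(errors), collapse = ", "))
  }
  list(summaries = summaries, errors = errors)
}
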