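#' Write and read calibrated image stacks
#'
#' Stacks are stored as multi-page 32-bit float TIFF in `(time, channel)`
#' page order with a JSON sidecar (`<path>.json`) carrying the pixel size,
#' channel tags, timepoints, time unit and the intensity scale used to map
#' raw intensities into the TIFF's `[0, 1]` storage range. Reading
#' normalises the axes back to a list of [Frame-class] objects ordered by
#' `(time, channel)`; a single-plane TIFF promotes to a one-timepoint,
#' one-channel stack. If the sidecar is missing, `pixelSize` must be
#' supplied as an override or a calibration error is raised.
#'
#' Storage is single precision, so round-trips are exact to about 1e-7
#' relative; the package asserts 1e-6.
#'
#' @param frames list of [Frame-class] (time-major, channel-minor order)
#' @param path TIFF file path
#' @param pixelSize calibration override in um/px (read)
#' @return `writeImageStack` returns `path` invisibly; `readImageStack`
#'   returns a list of [Frame-class]
#' @export
writeImageStack <- function(frames, path) {
  if (is(frames, "Frame")) frames <- list(frames)
  stopifnot(length(frames) > 0L)
  scale <- max(1, vapply(frames, function(f) max(f@data), numeric(1)))
  pages <- lapply(frames, function(f) f@data / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = "deflate")
  meta <- list(pixelSize = frames[[1]]@pixelSize, scale = scale,
               channels = vapply(frames, channelName, character(1)),
               timepoints = vapply(frames, timePoint, numeric(1)),
               timeUnit = frames[[1]]@timeUnit)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeImageStack
#' @export
readImageStack <- function(path, pixelSize = NULL) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("corrupt or unreadable TIFF: ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  metaPath <- paste0(path, ".json")
  if (file.exists(metaPath)) {
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  } else {
    if (is.null(pixelSize))
      stop("calibration error: no pixel-size metadata and no override")
    meta <- list(pixelSize = pixelSize, scale = 1,
                 channels = rep("unknown", length(pages)),
                 timepoints = rep(0, length(pages)), timeUnit = "day")
  }
  if (!is.null(pixelSize)) meta$pixelSize <- pixelSize
  lapply(seq_along(pages), function(i) {
    Frame(pages[[i]] * meta$scale, channel = meta$channels[i],
          timepoint = meta$timepoints[i], timeUnit = meta$timeUnit,
          pixelSize = meta$pixelSize)
  })
}

#' Write and read tabular records
#'
#' All pipeline tables travel as headered CSV with a stable column order
#' and floats serialised at 15 significant digits, so a round-trip
#' reproduces every numeric field to better than 1e-9 relative.
#'
#' @param records a data.frame (all rows share the schema by construction)
#' @param path CSV path
#' @return `writeRecords` returns `path` invisibly; `readRecords` the
#'   data.frame
#' @export
writeRecords <- function(records, path) {
  if (!is.data.frame(records)) stop("records must share one tabular schema")
  fmt <- records
  for (j in seq_along(fmt))
    if (is.double(fmt[[j]])) fmt[[j]] <- sprintf("%.15g", fmt[[j]])
  utils::write.csv(fmt, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeRecords
#' @export
readRecords <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# stage registry -------------------------------------------------------------

.stageRegistry <- new.env(parent = emptyenv())

#' Run a registered pipeline stage with logging
#'
#' `registerStage()` binds a name to a function of signature
#' `function(config, inputs)` returning a named list of outputs (tables are
#' written to `config$outDir` when set). `runStage()` validates the name,
#' executes the stage, and appends a machine-readable JSON-lines log entry
#' (stage, config hash, seed, row counts, timestamp) to
#' `config$logFile` when configured. Identical config + seed yields
#' identical outputs because all package randomness is seed-scoped.
#'
#' @param name stage name
#' @param fun stage function `function(config, inputs)`
#' @param config named list; recognised fields include `seed`, `outDir`,
#'   `logFile`; loaded from YAML via [loadRunConfig()]
#' @param inputs named list handed to the stage
#' @return the stage's output list, invisibly augmented with the log entry
#'   as attribute `"log"`
#' @export
registerStage <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .stageRegistry)
  invisible(name)
}

#' @rdname registerStage
#' @export
runStage <- function(name, config = list(), inputs = list()) {
  if (!exists(name, envir = .stageRegistry))
    stop("unknown stage '", name, "'; registered: ",
         paste(ls(.stageRegistry), collapse = ", "))
  fun <- get(name, envir = .stageRegistry)
  out <- fun(config, inputs)
  counts <- vapply(out, function(x)
    if (is.data.frame(x)) nrow(x) else length(x), numeric(1))
  entry <- list(stage = name, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                seed = config$seed,
                configHash = digestConfig(config), counts = as.list(counts))
  if (!is.null(config$logFile))
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
        file = config$logFile, append = TRUE)
  attr(out, "log") <- entry
  invisible(out)
}

#' @rdname registerStage
#' @param path YAML config path
#' @export
loadRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    pixelSizes = list(`10x` = 0.69, `20x` = 0.345, `40x` = 0.1725),
    motilityThreshold = 12.5, motilityDuration = 10,
    schedule = c(12, 46, 2), seed = 1L)
  utils::modifyList(defaults, cfg)
}

digestConfig <- function(config) {
  if (length(config)) config <- config[order(names(config))]
  s <- jsonlite::toJSON(config, auto_unbox = TRUE)
  # small rolling hash; enough to detect config drift in logs
  v <- utf8ToInt(as.character(s))
  h <- Reduce(function(h, c) (h * 31 + c) %% 2147483647, v, 17)
  sprintf("%08x", as.integer(h))
}
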