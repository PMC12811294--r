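#' Calibrated 2-D fluorescence image
#'
#' A `Frame` holds one 2-D intensity grid together with its acquisition
#' calibration: the channel tag (e.g. `"cytoplasm"`, `"nucleus"`,
#' `"mitochondria"`, `"antibody"`), the timepoint, the unit of that
#' timepoint (`"day"` for longitudinal imaging, `"min"` or `"s"` for acute
#' imaging) and the pixel size in micrometres per pixel. The three standard
#' magnifications of the imaging platform correspond to 0.69 (10x),
#' 0.345 (20x) and 0.1725 (40x) um/px.
#'
#' All pixel coordinates in this package are 0-based `(row, col)` and
#' bounding boxes are half-open `[y0, y1) x [x0, x1)`.
#'
#' @slot data numeric matrix of intensities (finite, non-negative)
#' @slot channel single character channel tag
#' @slot timepoint single numeric timepoint
#' @slot timeUnit one of `"day"`, `"min"`, `"s"`
#' @slot pixelSize micrometres per pixel (> 0)
#' @export
setClass("Frame",
  representation(data = "matrix", channel = "character",
                 timepoint = "numeric", timeUnit = "character",
                 pixelSize = "numeric"))

setValidity("Frame", function(object) {
  msg <- character()
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be a numeric matrix")
  else if (any(!is.finite(object@data)) || any(object@data < 0))
    msg <- c(msg, "intensities must be finite and >= 0")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single value > 0")
  if (length(object@channel) != 1L)
    msg <- c(msg, "channel must be a single tag")
  if (!object@timeUnit %in% c("day", "min", "s"))
    msg <- c(msg, "timeUnit must be one of 'day', 'min', 's'")
  if (length(msg)) msg else TRUE
})

#' Construct a Frame
#'
#' @param data numeric intensity matrix
#' @param channel channel tag
#' @param timepoint acquisition time
#' @param timeUnit `"day"`, `"min"` or `"s"`
#' @param pixelSize micrometres per pixel
#' @return a [Frame-class] object
#' @examples
#' f <- Frame(matrix(0, 10, 10), channel = "cytoplasm", pixelSize = 0.69)
#' pixelSize(f)
#' @export
Frame <- function(data, channel = "unknown", timepoint = 0,
                  timeUnit = "day", pixelSize = 0.69) {
  new("Frame", data = data, channel = channel, timepoint = timepoint,
      timeUnit = timeUnit, pixelSize = pixelSize)
}

#' Integer label mask aligned to a Frame
#'
#' Background is 0 and objects are labelled with consecutive integers
#' `1..K` in top-left scan order (column-major over 0-based `(row, col)`).
#'
#' @slot data integer matrix of labels
#' @slot pixelSize micrometres per pixel
#' @export
setClass("LabelMask",
  representation(data = "matrix", pixelSize = "numeric"))

setValidity("LabelMask", function(object) {
  msg <- character()
  lab <- object@data
  if (any(lab < 0) || any(lab != round(lab)))
    msg <- c(msg, "labels must be non-negative integers")
  k <- max(lab)
  present <- sort(unique(lab[lab > 0]))
  if (k > 0 && !identical(as.integer(present), seq_len(k)))
    msg <- c(msg, "labels must be consecutive 1..K")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelMask
#' @param data integer matrix (0 = background)
#' @param pixelSize micrometres per pixel
#' @return a [LabelMask-class] object
#' @export
LabelMask <- function(data, pixelSize = 0.69) {
  storage.mode(data) <- "integer"
  new("LabelMask", data = data, pixelSize = pixelSize)
}

#' Synthetic culture scene specification
#'
#' A `SceneSpec` pins down everything the synthetic-microscopy generator
#' needs to render one multichannel field of a directly converted culture:
#' field geometry, how many cells of each morphology class to place, the
#' archetype parameter ranges, the mitochondrial content of each cell, the
#' TDP-43 painting, and the noise model. The same spec with the same seed
#' always renders bit-identical images.
#'
#' The three morphology archetypes encode the criteria the classification
#' stage relies on: an iMN is a small bright round soma (radius 5-10 um)
#' with 1-5 neurites of ~1 um width; a non-iMN is a large flat dim
#' ellipse (major axis >= 30 um, eccentricity >= 0.7); a dead cell is 2-4
#' small bright fragments (<= 4 um across).
#'
#' @slot fieldSize numeric length-2, field extent in um (height, width)
#' @slot pixelSize um per pixel
#' @slot nIMN,nNonIMN,nDead per-class cell counts
#' @slot somaRadius iMN soma radius range (um)
#' @slot somaIntensity iMN soma intensity range (a.u.)
#' @slot neuriteCount integer range of neurites per iMN
#' @slot neuriteLength neurite length range (um)
#' @slot mitoCount integer range of mitochondria per iMN
#' @slot mitoArea per-mitochondrion area range (um^2)
#' @slot mitoIntensity per-mitochondrion peak intensity range (a.u.)
#' @slot tdpNuclear nuclear TDP-43 mean intensity painted per cell (a.u.)
#' @slot tdpRatio range of true cytoplasm/nucleus TDP-43 ratios
#' @slot background constant background level (a.u.)
#' @slot noiseSigma additive Gaussian noise sd (a.u.)
#' @slot maxOverlap max allowed soma-overlap fraction when placing cells
#' @slot seed RNG seed
#' @export
setClass("SceneSpec",
  representation(fieldSize = "numeric", pixelSize = "numeric",
    nIMN = "integer", nNonIMN = "integer", nDead = "integer",
    somaRadius = "numeric", somaIntensity = "numeric",
    neuriteCount = "integer", neuriteLength = "numeric",
    mitoCount = "integer", mitoArea = "numeric", mitoIntensity = "numeric",
    tdpNuclear = "numeric", tdpRatio = "numeric",
    background = "numeric", noiseSigma = "numeric",
    maxOverlap = "numeric", seed = "integer"))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (object@nIMN < 0 || object@nNonIMN < 0 || object@nDead < 0)
    msg <- c(msg, "cell counts must be >= 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (any(object@fieldSize <= 0)) msg <- c(msg, "fieldSize must be > 0")
  if (object@maxOverlap < 0 || object@maxOverlap > 1)
    msg <- c(msg, "maxOverlap must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn SceneSpec-class constructor with the default study
#'   conditions: a 706.5 x 706.5 um tile imaged at 10x (0.69 um/px).
#' @param fieldSize,pixelSize,nIMN,nNonIMN,nDead,somaRadius,somaIntensity
#'   see slots
#' @param neuriteCount,neuriteLength,mitoCount,mitoArea,mitoIntensity
#'   see slots
#' @param tdpNuclear,tdpRatio,background,noiseSigma,maxOverlap,seed see slots
#' @return a `SceneSpec`
#' @export
sceneSpec <- function(fieldSize = c(706.5, 706.5), pixelSize = 0.69,
    nIMN = 25L, nNonIMN = 10L, nDead = 10L,
    somaRadius = c(5, 10), somaIntensity = c(120, 200),
    neuriteCount = c(1L, 5L), neuriteLength = c(20, 80),
    mitoCount = c(5L, 15L), mitoArea = c(0.3, 0.8),
    mitoIntensity = c(80, 150), tdpNuclear = 200, tdpRatio = c(0.2, 1.2),
    background = 10, noiseSigma = 8, maxOverlap = 0.1, seed = 1L) {
  new("SceneSpec", fieldSize = fieldSize, pixelSize = pixelSize,
      nIMN = as.integer(nIMN), nNonIMN = as.integer(nNonIMN),
      nDead = as.integer(nDead), somaRadius = somaRadius,
      somaIntensity = somaIntensity, neuriteCount = as.integer(neuriteCount),
      neuriteLength = neuriteLength, mitoCount = as.integer(mitoCount),
      mitoArea = mitoArea, mitoIntensity = mitoIntensity,
      tdpNuclear = tdpNuclear, tdpRatio = tdpRatio,
      background = background, noiseSigma = noiseSigma,
      maxOverlap = maxOverlap, seed = as.integer(seed))
}

#' Synthetic survival cohort specification
#'
#' Defines the groups of a longitudinal viability experiment: each group
#' has a name, a number of cells and a true log hazard ratio relative to
#' the control group (whose log HR is 0 by construction). Death times are
#' exponential with rate `baselineHazard * exp(logHR)`; cells enter the
#' risk set on their recognition day and are administratively censored at
#' `finalDay`.
#'
#' @slot groups data.frame with columns `name`, `logHR`, `n`
#' @slot control name of the control group (log HR 0)
#' @slot baselineHazard events/day in the control group (> 0)
#' @slot entryDays candidate iMN-recognition days (uniformly sampled)
#' @slot finalDay last observation day
#' @slot seed RNG seed
#' @export
setClass("CohortSpec",
  representation(groups = "data.frame", control = "character",
    baselineHazard = "numeric", entryDays = "numeric",
    finalDay = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  g <- object@groups
  if (!all(c("name", "logHR", "n") %in% names(g)))
    msg <- c(msg, "groups needs columns name, logHR, n")
  if (object@baselineHazard < 0)
    msg <- c(msg, "baselineHazard must be >= 0 (0 = no deaths)")
  if (any(object@entryDays >= object@finalDay))
    msg <- c(msg, "finalDay must exceed all entry days")
  if (!object@control %in% g$name)
    msg <- c(msg, "control group missing from groups")
  else if (abs(g$logHR[g$name == object@control]) > 1e-12)
    msg <- c(msg, "control group must have log HR = 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn CohortSpec-class constructor. Defaults model the standard
#'   viability experiment: imaging D12-D46, entry at D12, 500 cells per
#'   group, baseline hazard 0.04 events/day.
#' @param groups data.frame(name, logHR, n)
#' @param control,baselineHazard,entryDays,finalDay,seed see slots
#' @return a `CohortSpec`
#' @export
cohortSpec <- function(
    groups = data.frame(name = c("control", "mutant"),
                        logHR = c(0, 0.69), n = c(500L, 500L)),
    control = "control", baselineHazard = 0.04,
    entryDays = 12, finalDay = 46, seed = 1L) {
  new("CohortSpec", groups = groups, control = control,
      baselineHazard = baselineHazard, entryDays = entryDays,
      finalDay = finalDay, seed = as.integer(seed))
}

# show methods ---------------------------------------------------------------

setMethod("show", "Frame", function(object) {
  cat(sprintf("Frame: %d x %d px, channel '%s', t = %g %s, %.4f um/px\n",
              nrow(object@data), ncol(object@data), object@channel,
              object@timepoint, object@timeUnit, object@pixelSize))
})

setMethod("show", "LabelMask", function(object) {
  cat(sprintf("LabelMask: %d x %d px, %d objects, %.4f um/px\n",
              nrow(object@data), ncol(object@data), max(object@data),
              object@pixelSize))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(paste0("SceneSpec: %.1f x %.1f um at %.4f um/px; ",
                     "%d iMN, %d non-iMN, %d dead; noise sd %.1f; seed %d\n"),
              object@fieldSize[1], object@fieldSize[2], object@pixelSize,
              object@nIMN, object@nNonIMN, object@nDead,
              object@noiseSigma, object@seed))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d groups, baseline hazard %.3f/day, D%g-D%g\n",
              nrow(object@groups), object@baselineHazard,
              min(object@entryDays), object@finalDay))
  print(object@groups)
})
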