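#' Simulate an extracellular-flux (mito stress test) plate
#'
#' Builds per-well OCR/ECAR measurement sequences following the standard
#' injection protocol: baseline, oligomycin, FCCP, then antimycin A +
#' rotenone + 2-deoxy-D-glucose. Raw OCR in each phase is the true
#' mitochondrial term plus the non-mitochondrial term (and raw ECAR the
#' glycolytic plus non-glycolytic term), so with zero noise the per-phase
#' plateau means equal the true construction exactly:
#' baseline = basal + nonMito, post-oligomycin = basal - atpLinked +
#' nonMito, post-FCCP = maximal + nonMito, post-inhibitors = nonMito.
#'
#' @param lines data.frame with one row per cell line and columns `line`,
#'   `basal`, `maximal`, `atpLinked` (oligomycin-sensitive OCR), `ecar`
#'   (glycolytic ECAR), `nonMitoOCR`, `nonGlycECAR` — all in raw
#'   (per-well) rate units
#' @param cellsPerWell cells per well (> 0), recycled across wells
#' @param noiseSigma additive Gaussian noise sd on each measurement
#' @param wellsPerLine technical replicate wells per line
#' @param cyclesPerPhase measurement cycles per injection phase (>= 2)
#' @param seed RNG seed
#' @return list with `wells` (long data.frame: `well`, `line`, `cycle`,
#'   `phase`, `OCR`, `ECAR`, `cell_count`) and `truth` (the input `lines`)
#' @export
generateFluxPlate <- function(lines, cellsPerWell = 2000,
    noiseSigma = 0, wellsPerLine = 6L, cyclesPerPhase = 3L, seed = 1L) {
  need <- c("line", "basal", "maximal", "atpLinked", "ecar",
            "nonMitoOCR", "nonGlycECAR")
  if (!all(need %in% names(lines)))
    stop("lines must have columns: ", paste(need, collapse = ", "))
  if (any(cellsPerWell <= 0)) stop("cell count must be positive")
  if (cyclesPerPhase < 2L) stop("need >= 2 measurements per phase")
  phases <- c("baseline", "post-oligomycin", "post-FCCP",
              "post-inhibitors")
  withSeed(seed, {
    rows <- list(); w <- 0L
    for (i in seq_len(nrow(lines))) {
      L <- lines[i, ]
      ocrPhase <- c(L$basal + L$nonMitoOCR,
                    L$basal - L$atpLinked + L$nonMitoOCR,
                    L$maximal + L$nonMitoOCR,
                    L$nonMitoOCR)
      ecarPhase <- c(L$ecar + L$nonGlycECAR, L$ecar + L$nonGlycECAR,
                     L$ecar + L$nonGlycECAR, L$nonGlycECAR)
      for (j in seq_len(wellsPerLine)) {
        w <- w + 1L
        nm <- length(phases) * cyclesPerPhase
        rows[[w]] <- data.frame(
          well = sprintf("W%03d", w), line = L$line,
          cycle = seq_len(nm),
          phase = rep(phases, each = cyclesPerPhase),
          OCR = rep(ocrPhase, each = cyclesPerPhase) +
            rnorm(nm, 0, noiseSigma),
          ECAR = rep(ecarPhase, each = cyclesPerPhase) +
            rnorm(nm, 0, noiseSigma),
          cell_count = rep_len(cellsPerWell, wellsPerLine)[j])
      }
    }
    list(wells = do.call(rbind, rows), truth = lines)
  })
}

#' Simulate per-cell biosensor intensity time series
#'
#' Two kinds are supported. `"mitosox"` produces one-channel series that
#' rise linearly (mitochondrial superoxide accumulation): intensity =
#' baseline + slope * t + noise, sampled every `timestep` minutes for
#' `duration` minutes (slope in intensity units per hour). `"perceval"`
#' produces two-channel (490 nm / 405 nm excitation) ATP/ADP biosensor
#' series whose true 490/405 ratio is piecewise constant with transitions
#' at the oligomycin (5 min) and 2-deoxy-D-glucose (15 min) injections.
#'
#' @param kind `"mitosox"` or `"perceval"`
#' @param slope true MitoSOX slope (intensity/h); recycled over cells
#' @param phaseRatios length-3 true 490/405 ratios (steady-state,
#'   post-oligomycin, post-2DG)
#' @param injections injection times (min) for the perceval kind
#' @param timestep sampling interval (min)
#' @param duration total duration (min); must cover all injections for
#'   the perceval kind
#' @param noiseSigma additive noise sd per sample
#' @param nCells number of cells
#' @param baseline MitoSOX intensity at t = 0 / Perceval 405-channel level
#' @param seed RNG seed
#' @return list with `series` (long data.frame: `cell`, `time` min, and
#'   `intensity` for mitosox or `ch490`/`ch405` for perceval) and `truth`
#'   (per-cell true slope, or the phase ratios)
#' @export
generateIntensitySeries <- function(kind = c("mitosox", "perceval"),
    slope = 2, phaseRatios = c(1.0, 0.7, 0.4), injections = c(5, 15),
    timestep = 10, duration = 180, noiseSigma = 0, nCells = 1L,
    baseline = 100, seed = 1L) {
  kind <- match.arg(kind)
  if (duration <= 0) stop("duration must be positive")
  withSeed(seed, {
    times <- seq(0, duration, by = timestep)
    if (kind == "mitosox") {
      slopes <- rep_len(slope, nCells)
      series <- do.call(rbind, lapply(seq_len(nCells), function(i) {
        data.frame(cell = i, time = times,
          intensity = baseline + slopes[i] * times / 60 +
            rnorm(length(times), 0, noiseSigma))
      }))
      list(series = series, truth = data.frame(cell = seq_len(nCells),
                                               slope = slopes))
    } else {
      if (duration < max(injections))
        stop("duration must cover all injection times")
      ratio <- stepRatio(times, injections, phaseRatios)
      series <- do.call(rbind, lapply(seq_len(nCells), function(i) {
        ch405 <- baseline + rnorm(length(times), 0, noiseSigma)
        ch490 <- ratio * baseline + rnorm(length(times), 0, noiseSigma)
        data.frame(cell = i, time = times, ch490 = ch490, ch405 = ch405)
      }))
      list(series = series,
           truth = data.frame(phase = c("steady-state", "post-oligomycin",
                                        "post-2DG"),
                              ratio = phaseRatios))
    }
  })
}

# piecewise-constant ratio: phases are [0, i1), [i1, i2), [i2, end]
stepRatio <- function(times, injections, ratios) {
  idx <- findInterval(times, injections, left.open = FALSE) + 1L
  ratios[idx]
}
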