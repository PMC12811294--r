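#' Simulate a long-term viability imaging experiment
#'
#' Renders an eGFP-like time-lapse of one field: each simulated iMN appears
#' at its entry (recognition) day and disappears at its death day, with
#' non-iMN and dead-debris clutter static across the whole series. Death
#' times are exponential under the cohort's group hazards; a cell that dies
#' on day `d` is present in frames with day `< d` (half-open presence), so
#' the observed duration is `d - entry`. Cells alive past the last imaging
#' day persist to the final frame and their true record is censored there.
#'
#' The imaging schedule defaults to the standard viability protocol:
#' every second day from D12 to D46, i.e. 18 timepoints.
#'
#' @param spec a [SceneSpec-class]; its iMN archetype parameters, field
#'   geometry, noise and clutter counts are used. The number of iMN comes
#'   from the cohort, not from `spec@nIMN`.
#' @param cohort a [CohortSpec-class]; one cell is simulated per unit of
#'   each group's `n`
#' @param schedule numeric `c(first, last, interval)` in days
#' @return list with elements
#'   \item{stack}{list of [Frame-class] (channel `"cytoplasm"`, one per
#'     scheduled day)}
#'   \item{tracks}{ground-truth per-frame boxes: data.frame `cellId`,
#'     `day`, `y0`,`x0`,`y1`,`x1` (0-based half-open px)}
#'   \item{records}{true survival records: `cellId`, `group`, `start`,
#'     `end`, `time`, `event`}
#'   \item{days}{the scheduled imaging days}
#' @export
generateTimelapse <- function(spec, cohort,
                              schedule = c(first = 12, last = 46,
                                           interval = 2)) {
  validObject(spec)
  validObject(cohort)
  days <- seq(schedule[[1]], schedule[[2]], by = schedule[[3]])
  if (any(cohort@entryDays < schedule[[1]] |
          cohort@entryDays > schedule[[2]]))
    stop("entry days must lie within the imaging schedule")
  withSeed(spec@seed + 1000L * cohort@seed, {
    px <- spec@pixelSize
    dim <- c(max(1L, round(spec@fieldSize[1] / px)),
             max(1L, round(spec@fieldSize[2] / px)))
    g <- cohort@groups
    nCells <- sum(g$n)

    # per-cell geometry: rejection-sampled static iMN somata
    occupied <- matrix(FALSE, dim[1], dim[2])
    cells <- vector("list", nCells)
    grp <- rep(g$name, g$n)
    for (i in seq_len(nCells)) {
      placed <- FALSE
      for (try in seq_len(.PLACEMENT_RETRIES)) {
        geom <- sampleCellGeometry("iMN", spec, dim)
        if (sum(geom$core & occupied) <=
            spec@maxOverlap * sum(geom$core)) { placed <- TRUE; break }
      }
      if (!placed)
        stop(sprintf(paste0("field too small to place cell %d without ",
                            "exceeding the %.0f%% overlap bound"),
                     i, 100 * spec@maxOverlap))
      occupied <- occupied | geom$core
      body <- geom$core | geom$neurites
      cells[[i]] <- list(
        idx = which(body),
        val = ifelse(geom$core[body], geom$amplitude,
                     .NEURITE_INTENSITY * geom$amplitude),
        bbox = maskBBox(geom$core))
    }

    # entry / death times per cell
    entry <- if (length(cohort@entryDays) == 1L)
      rep(cohort@entryDays, nCells)
    else snapToSchedule(sample(cohort@entryDays, nCells, TRUE), days)
    rate <- cohort@baselineHazard * exp(rep(g$logHR, g$n))
    rawDeath <- entry + ifelse(rate > 0, rexp(nCells, pmax(rate, 1e-300)),
                               Inf)
    # death observed at the first scheduled day >= the true death time
    deathDay <- vapply(rawDeath, function(d) {
      later <- days[days >= d]
      if (length(later)) later[1] else Inf
    }, numeric(1))
    event <- as.integer(is.finite(deathDay))
    end <- ifelse(event == 1L, deathDay, days[length(days)])

    records <- data.frame(cellId = seq_len(nCells), group = grp,
                          start = entry, end = end, time = end - entry,
                          event = event)

    tracks <- do.call(rbind, lapply(seq_len(nCells), function(i) {
      present <- days[days >= entry[i] & days < deathDay[i]]
      if (!length(present)) return(NULL)
      bb <- cells[[i]]$bbox
      data.frame(cellId = i, day = present, y0 = bb[1], x0 = bb[2],
                 y1 = bb[3], x1 = bb[4])
    }))
    if (is.null(tracks))
      tracks <- data.frame(cellId = integer(), day = numeric(),
                           y0 = numeric(), x0 = numeric(),
                           y1 = numeric(), x1 = numeric())

    # static clutter rendered once
    clutter <- matrix(0, dim[1], dim[2])
    for (cls in c(rep("non-iMN", spec@nNonIMN), rep("dead", spec@nDead))) {
      geom <- sampleCellGeometry(cls, spec, dim)
      clutter[geom$core] <- clutter[geom$core] + geom$amplitude
    }

    stack <- lapply(days, function(d) {
      img <- clutter + spec@background
      for (i in seq_len(nCells))
        if (d >= entry[i] && d < deathDay[i]) {
          ci <- cells[[i]]
          img[ci$idx] <- img[ci$idx] + ci$val
        }
      if (spec@noiseSigma > 0)
        img <- img + matrix(rnorm(length(img), 0, spec@noiseSigma),
                            dim[1], dim[2])
      Frame(pmax(img, 0), channel = "cytoplasm", timepoint = d,
            timeUnit = "day", pixelSize = px)
    })
    list(stack = stack, tracks = tracks, records = records, days = days)
  })
}

# smallest scheduled day >= each value
snapToSchedule <- function(x, days) {
  vapply(x, function(v) {
    later <- days[days >= v]
    if (length(later)) later[1] else days[length(days)]
  }, numeric(1))
}
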