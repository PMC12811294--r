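#' Simulate a neurite time-lapse for kymograph motility analysis
#'
#' Generates a short live-imaging stack of one straight neurite populated
#' with `nMito` punctate mitochondria, a fraction of which move. The frame
#' count follows the package's rounding rule `floor(duration_s * rate) + 1`
#' including t = 0, so the default 10 min at 0.33 Hz gives 199 frames.
#'
#' Motile mitochondria move with a constant speed magnitude drawn from
#' `speedRange` and may reverse direction (probability `reversalProb` per
#' frame), so their true cumulative movement is exactly
#' `speed * duration`; the generator refuses speed ranges whose maximum
#' cannot exceed the motility threshold within the duration. Stationary
#' mitochondria jitter with sub-pixel Gaussian steps far below the
#' threshold. Positions reflect at the path ends.
#'
#' @param nMito number of mitochondria
#' @param motileFraction fraction in `[0, 1]` that move
#' @param speedRange motile speed magnitude range (um/min)
#' @param duration experiment duration (min)
#' @param frameRate acquisition rate (Hz)
#' @param pathLength neurite path length (um); soma at position 0
#' @param pixelSize um/px (40x default)
#' @param threshold motility threshold (um) used only for the feasibility
#'   check of `speedRange`
#' @param reversalProb per-frame probability that a motile mitochondrion
#'   reverses direction
#' @param noiseSigma additive image noise sd (a.u.)
#' @param seed RNG seed
#' @return list with elements
#'   \item{stack}{list of [Frame-class] (channel `"mitochondria"`,
#'     `timeUnit` `"s"`)}
#'   \item{path}{data.frame `x`, `y` (um): the neurite polyline from the
#'     soma end outward}
#'   \item{truth}{per-mitochondrion table: `mitoId`, `motile`, `totalMovement`,
#'     `anterograde`, `retrograde`, `meanSpeed`, `maxSpeed` (um, um/min)}
#'   \item{positions}{matrix of true positions (um), mitochondria x frames}
#'   \item{frameInterval}{seconds between frames}
#' @export
generateKymoStack <- function(nMito = 50L, motileFraction = 0.4,
    speedRange = c(1.5, 3), duration = 10, frameRate = 0.33,
    pathLength = 250, pixelSize = 0.1725, threshold = 12.5,
    reversalProb = 0.05, noiseSigma = 2, seed = 1L) {
  if (motileFraction < 0 || motileFraction > 1)
    stop("motileFraction must be in [0, 1]")
  if (duration <= 0) stop("duration must be > 0")
  if (motileFraction > 0 && max(speedRange) * duration < threshold)
    stop(sprintf(paste0("speed range incompatible with exceeding the ",
                        "%.1f um threshold within %.0f min"),
                 threshold, duration))
  withSeed(seed, {
    nFrames <- floor(duration * 60 * frameRate) + 1L
    dt <- 1 / frameRate                     # seconds
    nMotile <- round(nMito * motileFraction)
    motile <- c(rep(TRUE, nMotile), rep(FALSE, nMito - nMotile))

    pos <- matrix(0, nMito, nFrames)
    pos[, 1] <- runif(nMito, 0.1 * pathLength, 0.9 * pathLength)
    speed <- ifelse(motile, runif(nMito, speedRange[1], speedRange[2]), 0)
    dir <- sample(c(-1, 1), nMito, replace = TRUE)
    jitterSd <- 0.03                        # um per frame, sub-pixel
    for (t in 2:nFrames) {
      flip <- runif(nMito) < reversalProb
      dir <- ifelse(flip, -dir, dir)
      step <- ifelse(motile, dir * speed * dt / 60,
                     rnorm(nMito, 0, jitterSd))
      p <- pos[, t - 1] + step
      # reflect at the path ends (and flip direction of travel)
      over <- p > pathLength; under <- p < 0
      p[over] <- 2 * pathLength - p[over]
      p[under] <- -p[under]
      dir[over | under] <- -dir[over | under]
      pos[, t] <- p
    }

    d <- pos[, -1, drop = FALSE] - pos[, -nFrames, drop = FALSE]
    total <- rowSums(abs(d))
    antero <- rowSums(pmax(d, 0))
    retro <- rowSums(pmax(-d, 0))
    truth <- data.frame(mitoId = seq_len(nMito), motile = motile,
      totalMovement = total, anterograde = antero, retrograde = retro,
      meanSpeed = total / duration,
      maxSpeed = apply(abs(d), 1, max) / (dt / 60))

    width <- 31L
    len <- floor(pathLength / pixelSize) + 2L
    midRow <- (width - 1) / 2
    amp <- runif(nMito, 100, 180)
    stack <- lapply(seq_len(nFrames), function(t) {
      img <- matrix(5, width, len)
      for (i in seq_len(nMito))
        img <- addSpot(img, midRow, pos[i, t] / pixelSize,
                       sigma = 0.35 / pixelSize, amplitude = amp[i])
      if (noiseSigma > 0)
        img <- img + matrix(rnorm(length(img), 0, noiseSigma),
                            width, len)
      Frame(pmax(img, 0), channel = "mitochondria",
            timepoint = (t - 1L) * dt, timeUnit = "s",
            pixelSize = pixelSize)
    })
    path <- data.frame(x = c(0, pathLength),
                       y = rep(midRow * pixelSize, 2))
    list(stack = stack, path = path, truth = truth, positions = pos,
         frameInterval = dt)
  })
}
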