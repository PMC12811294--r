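#' Build a kymograph from a time stack and a neurite path
#'
#' Samples the neurite polyline (soma end first) at pixel-size arc-length
#' steps; at each sample the intensity is the maximum across a short
#' segment normal to the path (`lineWidth`, default 3 px), interpolated
#' bilinearly. Columns are timepoints, row 0 is the soma end, so a
#' mitochondrion moving anterograde traces a ridge of positive slope.
#'
#' @param stack list of [Frame-class] at a constant frame interval
#' @param path data.frame `x`, `y` in um, starting at the soma
#' @param lineWidth width of the max-projection normal to the path, px
#' @return a [Frame-class] kymograph (rows = positions along the path at
#'   `pixelSize` steps, cols = frames), with attributes `frameInterval`
#'   (s) and `pixelSize`
#' @export
buildKymograph <- function(stack, path, lineWidth = 3L) {
  px <- stack[[1]]@pixelSize
  d <- dim(stack[[1]]@data)
  # arc-length parameterisation of the polyline, sampled at px steps
  pts <- as.matrix(path[, c("y", "x")]) / px   # px coords, 0-based
  if (any(pts < -0.5) || any(pts[, 1] > d[1] - 0.5) ||
      any(pts[, 2] > d[2] - 0.5))
    stop("path outside image bounds")
  seg <- diff(pts)
  segLen <- sqrt(rowSums(seg^2))
  total <- sum(segLen)
  nPos <- floor(total) + 1L
  s <- seq(0, by = 1, length.out = nPos)
  cum <- c(0, cumsum(segLen))
  segIdx <- pmin(findInterval(s, cum, rightmost.closed = TRUE),
                 nrow(seg))
  frac <- (s - cum[segIdx]) / pmax(segLen[segIdx], 1e-12)
  base <- pts[segIdx, , drop = FALSE] + seg[segIdx, , drop = FALSE] * frac
  # unit normals per sample
  tangent <- seg[segIdx, , drop = FALSE] / pmax(segLen[segIdx], 1e-12)
  normal <- cbind(-tangent[, 2], tangent[, 1])
  offs <- seq(-(lineWidth - 1) / 2, (lineWidth - 1) / 2)

  nT <- length(stack)
  ky <- matrix(0, nPos, nT)
  for (t in seq_len(nT)) {
    img <- stack[[t]]@data
    prof <- matrix(-Inf, nPos, length(offs))
    for (j in seq_along(offs)) {
      yy <- base[, 1] + offs[j] * normal[, 1]
      xx <- base[, 2] + offs[j] * normal[, 2]
      prof[, j] <- bilinear(img, yy, xx)
    }
    ky[, t] <- apply(prof, 1, max)
  }
  out <- Frame(pmax(ky, 0), channel = "kymograph",
               timepoint = stack[[1]]@timepoint,
               timeUnit = stack[[1]]@timeUnit, pixelSize = px)
  attr(out, "frameInterval") <-
    if (nT > 1) stack[[2]]@timepoint - stack[[1]]@timepoint else NA_real_
  out
}

#' Track mitochondria ridges across a kymograph
#'
#' Per column (timepoint), ridge positions are local intensity maxima
#' above `minIntensity`; ridges are linked across consecutive columns by
#' nearest-neighbour association within a `maxStep` gate (um per frame),
#' and tracks shorter than `minDuration` frames are discarded. Positions
#' are reported in um from the soma end.
#'
#' @param kymo a [buildKymograph()] result
#' @param maxStep association gate, um per frame
#' @param minIntensity ridge detection floor (a.u.); defaults to an Otsu
#'   cut over the kymograph, which lands between background and the
#'   dimmest ridges
#' @param minDuration minimum track length in frames
#' @param maxGap tolerated missed frames before a track is closed
#' @return list of `KymoTrack` data.frames (`frame`, `time` s,
#'   `position` um)
#' @export
trackKymograph <- function(kymo, maxStep = 1, minIntensity = NULL,
                           minDuration = 10L, maxGap = 5L) {
  ky <- kymo@data
  px <- kymo@pixelSize
  dt <- attr(kymo, "frameInterval")
  if (is.null(dim(ky)) || ncol(ky) == 0L || !any(ky > 0)) return(list())
  if (is.null(minIntensity)) {
    rg <- range(ky)
    minIntensity <- if (diff(rg) < 1e-9) Inf
      else EBImage::otsu(ky, range = rg)
  }
  peaksAt <- function(v) {
    n <- length(v)
    if (n < 3L) return(numeric())
    j <- which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n] &
                 v[2:(n - 1)] >= minIntensity) + 1L
    if (!length(j)) return(numeric())
    # parabolic sub-pixel refinement; quantized ridge positions otherwise
    # accumulate spurious movement over hundreds of frames
    den <- v[j - 1] - 2 * v[j] + v[j + 1]
    off <- ifelse(abs(den) > 1e-12, 0.5 * (v[j - 1] - v[j + 1]) / den, 0)
    j + pmin(pmax(off, -0.5), 0.5)
  }
  gatePx <- maxStep / px
  tracks <- list(); active <- list()
  for (t in seq_len(ncol(ky))) {
    pk <- peaksAt(ky[, t])
    usedPk <- logical(length(pk))
    nextActive <- list()
    if (length(active)) {
      lastPos <- vapply(active, function(a) a$pos[length(a$pos)],
                        numeric(1))
      usedTr <- logical(length(active))
      # greedy nearest-neighbour by increasing distance; the gate widens
      # with the number of frames a track has been unseen
      if (length(pk)) {
        gapN <- vapply(active, function(a) t - a$frame[length(a$frame)],
                       numeric(1))
        # constant-velocity prediction over the recent past, so a moving
        # ridge is matched ahead of itself rather than to a stationary
        # ridge it is crossing
        predPos <- vapply(seq_along(active), function(i) {
          a <- active[[i]]
          k <- length(a$pos)
          if (k < 2L) return(a$pos[k])
          j <- max(1L, k - 5L)
          vel <- (a$pos[k] - a$pos[j]) / (a$frame[k] - a$frame[j])
          a$pos[k] + vel * gapN[i]
        }, numeric(1))
        dm <- abs(outer(predPos, pk, function(a, b) a - b))
        ord <- order(dm)
        for (o in ord) {
          i <- (o - 1) %% length(active) + 1
          j <- (o - 1) %/% length(active) + 1
          if (usedTr[i] || usedPk[j] || dm[i, j] > gatePx * gapN[i]) next
          usedTr[i] <- TRUE; usedPk[j] <- TRUE
          active[[i]]$pos <- c(active[[i]]$pos, pk[j])
          active[[i]]$frame <- c(active[[i]]$frame, t)
        }
        # occlusion handling: two ridges crossing merge into one peak for
        # a few frames; let an unmatched track share the nearest peak
        # within a tight gate so both survive the crossing
        for (i in which(!usedTr)) {
          j <- which.min(dm[i, ])
          if (dm[i, j] <= gatePx) {
            usedTr[i] <- TRUE
            active[[i]]$pos <- c(active[[i]]$pos, pk[j])
            active[[i]]$frame <- c(active[[i]]$frame, t)
          }
        }
      }
      for (i in seq_along(active)) {
        if (usedTr[i] ||
            t - active[[i]]$frame[length(active[[i]]$frame)] <= maxGap)
          nextActive[[length(nextActive) + 1L]] <- active[[i]]
        else tracks[[length(tracks) + 1L]] <- active[[i]]
      }
    }
    for (j in which(!usedPk))
      nextActive[[length(nextActive) + 1L]] <-
        list(pos = pk[j], frame = t)
    active <- nextActive
  }
  tracks <- c(tracks, active)
  tracks <- Filter(function(a) length(a$pos) >= minDuration, tracks)
  lapply(seq_along(tracks), function(i) {
    a <- tracks[[i]]
    data.frame(mitoId = i, frame = a$frame,
               time = (a$frame - 1) * dt,
               position = runMean((a$pos - 1) * px, 5L))
  })
}

# centred running mean (window w, odd), edges shrink symmetrically
runMean <- function(x, w) {
  n <- length(x)
  if (n < 3L || w < 3L) return(x)
  h <- w %/% 2
  vapply(seq_len(n), function(i) {
    r <- min(h, i - 1L, n - i)
    mean(x[(i - r):(i + r)])
  }, numeric(1))
}

#' Score the motility of one kymograph track
#'
#' Total movement is the cumulative path length `sum(|dPosition|)` (not
#' net displacement — a mitochondrion shuttling back and forth is
#' motile); a track is motile when total movement meets the threshold
#' (inclusive: exactly 12.5 um counts as motile). Anterograde distance
#' sums the positive steps (soma at 0, increasing = anterograde) and
#' retrograde the negative ones, so anterograde + retrograde equals total
#' movement exactly. Average speed is total movement over the track
#' duration and maximum speed the largest per-frame step rate.
#'
#' Tracks spanning less than `duration` are scored on their own span and
#' flagged `shortTrack`; by default [motileFraction()] excludes them.
#'
#' @param track data.frame with `position` (um) and `time` (s), >= 2 rows
#' @param threshold motility threshold in um (default 12.5)
#' @param duration nominal experiment duration in min (default 10)
#' @param mode `"cumulative"` (default) or `"net"` total-movement rule
#' @return one-row data.frame: `totalMovement`, `motile`, `anterograde`,
#'   `retrograde`, `averageSpeed`, `maxSpeed` (um/min), `trackDuration`
#'   (min), `shortTrack`
#' @export
scoreMotility <- function(track, threshold = 12.5, duration = 10,
                          mode = c("cumulative", "net")) {
  mode <- match.arg(mode)
  if (nrow(track) < 2L) stop("track needs >= 2 positions")
  d <- diff(track$position)
  dtMin <- diff(track$time) / 60
  total <- if (mode == "cumulative") sum(abs(d))
    else abs(track$position[nrow(track)] - track$position[1])
  antero <- sum(pmax(d, 0)); retro <- sum(pmax(-d, 0))
  span <- (track$time[nrow(track)] - track$time[1]) / 60
  data.frame(totalMovement = total, motile = total >= threshold,
             anterograde = antero, retrograde = retro,
             averageSpeed = total / span,
             maxSpeed = max(abs(d) / dtMin),
             trackDuration = span,
             shortTrack = span < 0.95 * duration)
}

#' Fraction of motile mitochondria
#'
#' @param metrics data.frame of [scoreMotility()] rows (one per track)
#' @param includeShort include tracks flagged `shortTrack`?
#' @return the motile fraction in `[0, 1]`; `NA` (with a warning) when no
#'   eligible tracks remain
#' @export
motileFraction <- function(metrics, includeShort = FALSE) {
  if (nrow(metrics) == 0L) stop("no tracks: motile fraction undefined")
  if (!includeShort)
    metrics <- metrics[!metrics$shortTrack, , drop = FALSE]
  if (nrow(metrics) == 0L) {
    warning("no full-duration tracks; motile fraction undefined")
    return(NA_real_)
  }
  mean(metrics$motile)
}
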