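#' Tracker parameters
#'
#' @param iouMin minimum IoU for frame-to-frame association, in (0, 1]
#' @param maxGap tolerated missed frames inside a track (>= 0)
#' @param minLength minimum detections per track
#' @param scoreCutoff detection score floor
#' @return a `TrackerParams` list
#' @export
trackerParams <- function(iouMin = 0.3, maxGap = 1L, minLength = 2L,
                          scoreCutoff = 0.5) {
  if (iouMin <= 0 || iouMin > 1) stop("iouMin must be in (0, 1]")
  if (maxGap < 0) stop("maxGap must be >= 0")
  structure(list(iouMin = iouMin, maxGap = as.integer(maxGap),
                 minLength = as.integer(minLength),
                 scoreCutoff = scoreCutoff), class = "TrackerParams")
}

#' Detect iMN in one time-lapse frame
#'
#' Classical stand-in for the learned detector: blob detection on the
#' eGFP-like channel (cell-body presets), feature extraction per blob,
#' three-class classification, and a bounding box for every object
#' classified iMN. The detection score is the classifier's iMN posterior
#' (1 for the rules engine).
#'
#' @param frame eGFP-like [Frame-class]
#' @param model a fitted `ClassifierModel`
#' @param params [detectionParams()] for the cell-body pass; the default
#'   uses a 1 um blur, fine enough to keep touching somata separable
#' @param tile tile id carried into the detections
#' @return data.frame: `day`, `y0`,`x0`,`y1`,`x1` (0-based half-open px),
#'   `score`, `tile`
#' @export
detectImn <- function(frame, model, params = detectionParams(sigma = 1),
                      tile = 1L) {
  empty <- data.frame(day = numeric(), y0 = numeric(), x0 = numeric(),
                      y1 = numeric(), x1 = numeric(), score = numeric(),
                      tile = integer())
  bg <- subtractBackground(frame, radius = 40)
  px <- frame@pixelSize
  blur <- EBImage::gblur(bg@data, sigma = params$sigma / px)
  rg <- range(blur)
  if (diff(rg) < 1e-9) return(empty)
  bw <- blur > EBImage::otsu(blur, range = rg)
  if (!any(bw)) return(empty)
  # touching somata: intensity watershed first, then the bright core of
  # each region (neurite shoulders are much dimmer after the blur), then
  # a distance-map watershed of the cores to split dumbbell-shaped merges
  lab <- as.matrix(EBImage::watershed(blur * bw, tolerance = 5))
  coreAll <- matrix(FALSE, nrow(bw), ncol(bw))
  for (i in seq_len(max(lab))) {
    comp <- lab == i
    coreAll <- coreAll | (comp & blur >= 0.5 * max(blur[comp]))
  }
  if (!any(coreAll)) return(empty)
  lab2 <- as.matrix(EBImage::watershed(EBImage::distmap(coreAll),
                                       tolerance = 1))
  k <- max(lab2)
  rows <- lapply(seq_len(k), function(i) {
    core <- lab2 == i
    cl <- EBImage::bwlabel(core)
    core <- cl == which.max(tabulate(cl[cl > 0]))
    comp <- lab == max(lab[core])   # parent foreground component
    comp <- comp | core
    areaCore <- sum(core) * px^2
    if (areaCore < params$minArea || areaCore > params$maxArea)
      return(NULL)
    f <- extractCellFeatures(core, comp, bg)
    if (classifyFeatures(f, model) != "iMN") return(NULL)
    score <- if (model$engine == "rules") 1 else {
      p <- multinomPosterior(f, model)
      p[1, match("iMN", model$levels)]
    }
    bb <- maskBBox(core)
    data.frame(day = frame@timepoint, y0 = bb[1], x0 = bb[2],
               y1 = bb[3], x1 = bb[4], score = score,
               tile = tile)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

#' Link detections into tracks by greedy IoU association
#'
#' Frames are processed in day order (reversed for `direction =
#' "backward"`). At each frame, candidate (track, detection) pairs with
#' IoU >= `iouMin` are accepted greedily by descending IoU (ties: larger
#' IoU, then smaller track id); unmatched detections start new tracks;
#' a track ends once it has missed more than `maxGap` consecutive frames;
#' tracks with fewer than `minLength` detections are dropped. Detections
#' below `scoreCutoff` are ignored.
#'
#' @param detections data.frame as produced by [detectImn()] (several
#'   frames together)
#' @param params a [trackerParams()] list
#' @param direction `"forward"` or `"backward"`
#' @return data.frame of track points: `trackId`, `day`, boxes, `score`,
#'   `tile`, `direction`
#' @export
linkTracks <- function(detections, params = trackerParams(),
                       direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (!inherits(params, "TrackerParams")) stop("invalid tracker params")
  det <- detections[detections$score >= params$scoreCutoff, ,
                    drop = FALSE]
  days <- sort(unique(det$day), decreasing = direction == "backward")
  active <- list()   # each: list(rows = df, missed = n)
  done <- list()
  nextId <- 1L
  for (d in days) {
    cur <- det[det$day == d, , drop = FALSE]
    matchedTr <- integer(0)
    matchedDet <- integer(0)
    if (length(active) && nrow(cur)) {
      lastBox <- do.call(rbind, lapply(active, function(a)
        a$rows[nrow(a$rows), c("y0", "x0", "y1", "x1")]))
      M <- iouMatrix(lastBox, cur)
      cand <- which(M >= params$iouMin, arr.ind = TRUE)
      if (nrow(cand)) {
        # descending IoU; ties by smaller track id
        ord <- order(-M[cand], cand[, 1])
        usedT <- logical(length(active)); usedD <- logical(nrow(cur))
        for (o in ord) {
          i <- cand[o, 1]; j <- cand[o, 2]
          if (usedT[i] || usedD[j]) next
          usedT[i] <- TRUE; usedD[j] <- TRUE
          active[[i]]$rows <- rbind(active[[i]]$rows, cur[j, ])
          active[[i]]$missed <- 0L
        }
        matchedTr <- which(usedT); matchedDet <- which(usedD)
      }
    }
    # age unmatched tracks
    if (length(active)) {
      keep <- logical(length(active))
      for (i in seq_along(active)) {
        if (i %in% matchedTr) { keep[i] <- TRUE; next }
        active[[i]]$missed <- active[[i]]$missed + 1L
        if (active[[i]]$missed > params$maxGap)
          done[[length(done) + 1L]] <- active[[i]]
        else keep[i] <- TRUE
      }
      active <- active[keep]
    }
    # new tracks from unmatched detections
    newIdx <- setdiff(seq_len(nrow(cur)), matchedDet)
    for (j in newIdx) {
      active[[length(active) + 1L]] <-
        list(rows = cur[j, , drop = FALSE], missed = 0L)
    }
  }
  done <- c(done, active)
  done <- Filter(function(a) nrow(a$rows) >= params$minLength, done)
  if (!length(done))
    return(data.frame(trackId = integer(), day = numeric(),
                      y0 = numeric(), x0 = numeric(), y1 = numeric(),
                      x1 = numeric(), score = numeric(), tile = integer(),
                      direction = character()))
  out <- do.call(rbind, lapply(seq_along(done), function(i) {
    r <- done[[i]]$rows
    r <- r[order(r$day), , drop = FALSE]
    cbind(data.frame(trackId = i), r)
  }))
  out$direction <- direction
  rownames(out) <- NULL
  out
}

#' Merge forward/backward and cross-tile tracks
#'
#' Tracks are first mapped into the global frame using each tile's offset
#' (um), then any two tracks sharing at least one day with mean IoU over
#' the shared days >= `mergeIoU` are merged; merging is transitive
#' (connected components via union-find). A merged track's box on a day
#' is the highest-score source box for that day.
#'
#' @param ... track data.frames from [linkTracks()] (any mix of
#'   directions/tiles); may also be a single combined data.frame
#' @param tileLayout data.frame `tile`, `dy`, `dx` (offsets in um) or
#'   NULL when all tracks share one tile/frame
#' @param mergeIoU merge threshold on mean shared-day IoU
#' @param pixelSize um/px, used to convert tile offsets to px
#' @return merged track data.frame: `trackId`, `day`, boxes (global px),
#'   `score`
#' @export
mergeTracks <- function(..., tileLayout = NULL, mergeIoU = 0.5,
                        pixelSize = 0.69) {
  parts <- Filter(function(x) is.data.frame(x) && nrow(x) > 0, list(...))
  if (!length(parts))
    return(data.frame(trackId = integer(), day = numeric(),
                      y0 = numeric(), x0 = numeric(), y1 = numeric(),
                      x1 = numeric(), score = numeric()))
  for (i in seq_along(parts)) parts[[i]]$src <- i
  all <- do.call(rbind, parts)
  if (!is.null(tileLayout)) {
    m <- match(all$tile, tileLayout$tile)
    if (any(is.na(m))) stop("inconsistent tile offsets: unknown tile id")
    all$y0 <- all$y0 + tileLayout$dy[m] / pixelSize
    all$y1 <- all$y1 + tileLayout$dy[m] / pixelSize
    all$x0 <- all$x0 + tileLayout$dx[m] / pixelSize
    all$x1 <- all$x1 + tileLayout$dx[m] / pixelSize
  }
  key <- interaction(all$src, all$trackId, drop = TRUE)
  tracks <- split(all, key)
  n <- length(tracks)
  parent <- seq_len(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      A <- tracks[[i]]; B <- tracks[[j]]
      shared <- intersect(A$day, B$day)
      if (!length(shared)) next
      ious <- vapply(shared, function(d) {
        a <- A[A$day == d, ][1, ]; b <- B[B$day == d, ][1, ]
        boxIoU(c(a$y0, a$x0, a$y1, a$x1), c(b$y0, b$x0, b$y1, b$x1))
      }, numeric(1))
      if (mean(ious) >= mergeIoU) {
        ri <- ufFind(parent, i); rj <- ufFind(parent, j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), function(i) ufFind(parent, i), integer(1))
  comp <- match(root, unique(root))
  out <- do.call(rbind, lapply(seq_along(unique(root)), function(c) {
    members <- do.call(rbind, tracks[comp == c])
    # per-day best-score box
    best <- do.call(rbind, lapply(split(members, members$day),
      function(m) m[which.max(m$score), , drop = FALSE]))
    best <- best[order(best$day), ]
    data.frame(trackId = c, day = best$day, y0 = best$y0, x0 = best$x0,
               y1 = best$y1, x1 = best$x1, score = best$score)
  }))
  rownames(out) <- NULL
  out
}

#' Convert merged tracks to start-end-censor survival records
#'
#' The start is the first day the cell was recognised as an iMN; a track
#' that ends before the final imaging day dies at its first missed
#' scheduled timepoint (`last detection day + interval`, event = 1);
#' tracks still present at the final day are censored there (end =
#' `finalDay`, event = 0).
#'
#' @param tracks merged track data.frame
#' @param finalDay last scheduled imaging day
#' @param interval scheduled imaging interval (days)
#' @param group group label (single value or per-track named vector by
#'   trackId)
#' @return data.frame of `SurvivalRecord`: `cellId`, `group`, `start`,
#'   `end`, `time`, `event`
#' @export
tracksToSurvival <- function(tracks, finalDay = 46, interval = 2,
                             group = "all") {
  ids <- unique(tracks$trackId)
  if (nrow(tracks) == 0L)
    return(data.frame(cellId = integer(), group = character(),
                      start = numeric(), end = numeric(),
                      time = numeric(), event = integer()))
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$trackId == id, ]
    if (nrow(tr) == 0L) stop("track with no detections")
    start <- min(tr$day); last <- max(tr$day)
    if (last >= finalDay) { end <- finalDay; event <- 0L }
    else { end <- last + interval; event <- 1L }
    g <- if (length(group) == 1L) group else group[[as.character(id)]]
    data.frame(cellId = id, group = g, start = start, end = end,
               time = end - start, event = event)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multi-object tracking accuracy (MOTA)
#'
#' Per-frame matching at an IoU threshold with persistent identities:
#' matches from the previous frame are kept while still above the
#' threshold, remaining objects are matched greedily by descending IoU.
#' MOTA = 1 - (FN + FP + IDSW) / total ground-truth objects, with the
#' three components reported.
#'
#' @param pred predicted track data.frame (`trackId`, `day`, boxes)
#' @param gt ground-truth track data.frame (`cellId` or `trackId`, `day`,
#'   boxes)
#' @param iouThreshold match threshold in (0, 1]
#' @return list: `mota`, `fn`, `fp`, `idsw`, `nGT`
#' @export
mota <- function(pred, gt, iouThreshold = 0.5) {
  if (iouThreshold <= 0 || iouThreshold > 1)
    stop("iouThreshold must be in (0, 1]")
  gid <- if ("cellId" %in% names(gt)) gt$cellId else gt$trackId
  gt$gid <- gid
  days <- sort(unique(gt$day))
  fn <- 0L; fp <- 0L; idsw <- 0L; nGT <- 0L
  lastMatch <- list()   # gid -> trackId
  for (d in days) {
    G <- gt[gt$day == d, , drop = FALSE]
    P <- pred[pred$day == d, , drop = FALSE]
    nGT <- nGT + nrow(G)
    M <- iouMatrix(G[, c("y0", "x0", "y1", "x1")],
                   P[, c("y0", "x0", "y1", "x1")])
    usedG <- logical(nrow(G)); usedP <- logical(nrow(P))
    matches <- list()
    # keep persistent matches first
    for (i in seq_len(nrow(G))) {
      prev <- lastMatch[[as.character(G$gid[i])]]
      if (is.null(prev)) next
      j <- which(P$trackId == prev)
      if (length(j) == 1L && !usedP[j] && M[i, j] >= iouThreshold) {
        usedG[i] <- TRUE; usedP[j] <- TRUE
        matches[[length(matches) + 1L]] <- c(i, j)
      }
    }
    if (nrow(G) && nrow(P)) {
      cand <- which(M >= iouThreshold, arr.ind = TRUE)
      if (nrow(cand)) {
        for (o in order(-M[cand])) {
          i <- cand[o, 1]; j <- cand[o, 2]
          if (usedG[i] || usedP[j]) next
          usedG[i] <- TRUE; usedP[j] <- TRUE
          matches[[length(matches) + 1L]] <- c(i, j)
        }
      }
    }
    for (m in matches) {
      g <- as.character(G$gid[m[1]]); tid <- P$trackId[m[2]]
      prev <- lastMatch[[g]]
      if (!is.null(prev) && prev != tid) idsw <- idsw + 1L
      lastMatch[[g]] <- tid
    }
    fn <- fn + sum(!usedG)
    fp <- fp + sum(!usedP)
  }
  # predictions on days with no ground truth at all are false positives
  extraDays <- setdiff(unique(pred$day), days)
  fp <- fp + sum(pred$day %in% extraDays)
  list(mota = if (nGT > 0) 1 - (fn + fp + idsw) / nGT else NA_real_,
       fn = fn, fp = fp, idsw = idsw, nGT = nGT)
}

#' Seeded random search over tracker parameters
#'
#' Samples `budget` parameter sets uniformly from the given ranges,
#' evaluates each by mean MOTA over the supplied ground-truth movies and
#' returns the best (with the full evaluation log attached). Random
#' search stands in for fancier optimizers; the target (MOTA) and space
#' are what matter, and the result is deterministic under the seed.
#'
#' @param space list of ranges: `iouMin = c(lo, hi)`, `maxGap = c(lo,
#'   hi)`, `minLength = c(lo, hi)`, `scoreCutoff = c(lo, hi)`; fixed
#'   scalars allowed
#' @param movies list of movies, each a list with `detections` (all-frame
#'   detection table) and `gt` (ground-truth tracks)
#' @param budget evaluations (>= 1)
#' @param seed RNG seed
#' @return the winning [trackerParams()], with attribute `"log"` (the
#'   evaluated sets and their mean MOTA)
#' @export
tuneTracker <- function(space, movies, budget = 20L, seed = 1L) {
  if (!length(space)) stop("empty parameter space")
  if (budget < 1L) stop("budget must be >= 1")
  withSeed(seed, {
    draw <- function(rng, integer = FALSE) {
      if (length(rng) == 1L) return(rng)
      v <- runif(1, rng[1], rng[2])
      if (integer) round(v) else v
    }
    evalLog <- data.frame()
    best <- NULL; bestScore <- -Inf
    for (b in seq_len(budget)) {
      p <- trackerParams(
        iouMin = draw(space$iouMin %||% 0.3),
        maxGap = draw(space$maxGap %||% 1L, integer = TRUE),
        minLength = draw(space$minLength %||% 2L, integer = TRUE),
        scoreCutoff = draw(space$scoreCutoff %||% 0.5))
      scores <- vapply(movies, function(mv) {
        tr <- linkTracks(mv$detections, p)
        mota(tr, mv$gt)$mota
      }, numeric(1))
      s <- mean(scores)
      evalLog <- rbind(evalLog, data.frame(iouMin = p$iouMin,
        maxGap = p$maxGap, minLength = p$minLength,
        scoreCutoff = p$scoreCutoff, meanMOTA = s))
      if (s > bestScore) { bestScore <- s; best <- p }
    }
    attr(best, "log") <- evalLog
    best
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subsample survival records per group
#'
#' Uniform sampling without replacement of `n` records per group (the
#' standard 500-cell subsample of tracked iMN); groups smaller than `n`
#' are returned whole and flagged.
#'
#' @param records SurvivalRecord data.frame with a `group` column
#' @param n records per group
#' @param seed RNG seed
#' @return the subsample, with attribute `"undersized"` naming groups
#'   returned whole
#' @export
sampleCells <- function(records, n = 500L, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  withSeed(seed, {
    undersized <- character()
    out <- do.call(rbind, lapply(split(records, records$group),
      function(g) {
        if (nrow(g) <= n) {
          if (nrow(g) < n)
            undersized <<- c(undersized, as.character(g$group[1]))
          g
        } else g[sample.int(nrow(g), n), , drop = FALSE]
      }))
    rownames(out) <- NULL
    attr(out, "undersized") <- undersized
    out
  })
}
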