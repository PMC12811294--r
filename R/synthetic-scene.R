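#' Render a synthetic multichannel culture field with ground truth
#'
#' Draws a co-registered four-channel fluorescence field (cytoplasm /
#' eGFP-like, nucleus / Hoechst-like, mitochondria / TMRM-like, antibody /
#' TDP-43-like) populated with the three morphology archetypes of a
#' directly converted culture, plus per-object label masks and a ground
#' truth table. Cells are placed by rejection sampling so that no new cell
#' core overlaps already placed cells by more than `spec@maxOverlap` of its
#' own area; if the field cannot accommodate the requested counts under
#' that bound a placement error is raised naming the constraint.
#'
#' Mitochondria are painted only inside iMN (as crisp disks of the
#' requested area, so segmentation counts have a ground truth). The
#' antibody channel paints each cell's nucleus at `spec@tdpNuclear` and its
#' cytoplasm at `ratio * tdpNuclear` with a per-cell true ratio drawn from
#' `spec@tdpRatio`, giving the nuclear/cytoplasmic partitioning stage a
#' recoverable truth.
#'
#' @param spec a [SceneSpec-class]
#' @return a list with elements
#'   \item{frames}{named list of [Frame-class]: `cytoplasm`, `nucleus`,
#'     `mitochondria`, `antibody`}
#'   \item{masks}{named list of [LabelMask-class]: `cell` (soma +
#'     neurites), `soma` (core only), `nucleus`, `mito`}
#'   \item{truth}{data.frame, one row per cell: `id`, `class`, centroid
#'     `cy`/`cx` (0-based px), `coreArea` (um^2), `neuriteCount`,
#'     `mitoCount`, `tdpRatio`, core bounding box `y0,x0,y1,x1`}
#'   \item{mito}{data.frame, one row per painted mitochondrion: `cellId`,
#'     `mitoId`, `cy`, `cx`, `area` (um^2), `intensity`}
#' @examples
#' sc <- generateCultureImage(sceneSpec(nIMN = 3, nNonIMN = 1, nDead = 1,
#'   fieldSize = c(200, 200), seed = 7))
#' table(sc$truth$class)
#' @export
generateCultureImage <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, renderScene(spec))
}

# class archetype constants (um unless noted)
.NUCLEUS_FRACTION <- 0.55    # iMN nucleus radius as fraction of soma radius
.NEURITE_WIDTH <- 1          # um
.NEURITE_INTENSITY <- 0.7    # fraction of soma amplitude
.NUCLEUS_LEVEL <- 150        # Hoechst amplitude
.NONIMN_INTENSITY <- c(30, 60)
.NONIMN_MAJOR <- c(30, 50)   # full major axis, um
.NONIMN_ECC <- c(0.7, 0.9)
.DEAD_FRAG_RADIUS <- c(0.9, 2)   # fragment radius, um (diameter <= 4)
.DEAD_FRAG_COUNT <- c(2L, 4L)
.DEAD_INTENSITY <- c(80, 150)
.DEAD_SCATTER <- 5           # fragment scatter radius around centre, um
.PLACEMENT_RETRIES <- 200L

renderScene <- function(spec) {
  px <- spec@pixelSize
  dim <- c(max(1L, round(spec@fieldSize[1] / px)),
           max(1L, round(spec@fieldSize[2] / px)))
  chan <- list(cytoplasm = matrix(0, dim[1], dim[2]),
               nucleus = matrix(0, dim[1], dim[2]),
               mitochondria = matrix(0, dim[1], dim[2]),
               antibody = matrix(0, dim[1], dim[2]))
  lab <- list(cell = matrix(0L, dim[1], dim[2]),
              soma = matrix(0L, dim[1], dim[2]),
              nucleus = matrix(0L, dim[1], dim[2]),
              mito = matrix(0L, dim[1], dim[2]))
  occupied <- matrix(FALSE, dim[1], dim[2])

  classes <- c(rep("iMN", spec@nIMN), rep("non-iMN", spec@nNonIMN),
               rep("dead", spec@nDead))
  n <- length(classes)
  truth <- data.frame(id = integer(), class = character(), cy = numeric(),
                      cx = numeric(), coreArea = numeric(),
                      neuriteCount = integer(), mitoCount = integer(),
                      tdpRatio = numeric(), y0 = numeric(), x0 = numeric(),
                      y1 = numeric(), x1 = numeric())
  mitoTruth <- data.frame(cellId = integer(), mitoId = integer(),
                          cy = numeric(), cx = numeric(), area = numeric(),
                          intensity = numeric())
  nextMito <- 1L

  for (i in seq_len(n)) {
    cls <- classes[i]
    placed <- FALSE
    for (try in seq_len(.PLACEMENT_RETRIES)) {
      geom <- sampleCellGeometry(cls, spec, dim)
      ov <- sum(geom$core & occupied)
      if (ov <= spec@maxOverlap * sum(geom$core)) { placed <- TRUE; break }
    }
    if (!placed)
      stop(sprintf(paste0("field too small to place cell %d (%s) without ",
                          "exceeding the %.0f%% overlap bound"),
                   i, cls, 100 * spec@maxOverlap))
    occupied <- occupied | geom$core

    paint <- function(m, mask, value) { m[mask] <- m[mask] + value; m }
    free <- function(mask) mask & lab$cell == 0L
    chan$cytoplasm <- paint(chan$cytoplasm, geom$core, geom$amplitude)
    if (!is.null(geom$neurites)) {
      nm <- geom$neurites & !geom$core
      chan$cytoplasm <- paint(chan$cytoplasm, nm,
                              .NEURITE_INTENSITY * geom$amplitude)
    }
    body <- geom$core | (if (is.null(geom$neurites))
      matrix(FALSE, dim[1], dim[2]) else geom$neurites)
    lab$cell[free(body)] <- i
    lab$soma[geom$core & lab$soma == 0L] <- i

    tdpRatio <- NA_real_
    if (!is.null(geom$nucleus)) {
      chan$nucleus <- paint(chan$nucleus, geom$nucleus, .NUCLEUS_LEVEL)
      lab$nucleus[geom$nucleus & lab$nucleus == 0L] <- i
      tdpRatio <- runif(1, spec@tdpRatio[1], spec@tdpRatio[2])
      cyto <- body & !geom$nucleus
      chan$antibody <- paint(chan$antibody, geom$nucleus, spec@tdpNuclear)
      chan$antibody <- paint(chan$antibody, cyto, tdpRatio * spec@tdpNuclear)
    }

    nm <- 0L
    if (cls == "iMN") {
      nm <- sample(spec@mitoCount[1]:spec@mitoCount[2], 1L)
      inside <- which(geom$core, arr.ind = TRUE)
      for (j in seq_len(nm)) {
        area <- runif(1, spec@mitoArea[1], spec@mitoArea[2])
        amp <- runif(1, spec@mitoIntensity[1], spec@mitoIntensity[2])
        pos <- inside[sample.int(nrow(inside), 1L), ]
        r <- sqrt(area / pi) / px
        mm <- maskDisk(dim, pos[1] - 1, pos[2] - 1, max(r, 0.6))
        chan$mitochondria[mm] <- pmax(chan$mitochondria[mm], amp)
        lab$mito[mm & lab$mito == 0L] <- nextMito
        mitoTruth <- rbind(mitoTruth, data.frame(cellId = i,
          mitoId = nextMito, cy = pos[1] - 1, cx = pos[2] - 1,
          area = area, intensity = amp))
        nextMito <- nextMito + 1L
      }
    }

    bb <- maskBBox(geom$core)
    ctr <- which(geom$core, arr.ind = TRUE)
    truth <- rbind(truth, data.frame(id = i, class = cls,
      cy = mean(ctr[, 1]) - 1, cx = mean(ctr[, 2]) - 1,
      coreArea = sum(geom$core) * px^2,
      neuriteCount = geom$nNeurites, mitoCount = nm, tdpRatio = tdpRatio,
      y0 = bb[1], x0 = bb[2], y1 = bb[3], x1 = bb[4]))
  }

  # relabel masks to consecutive 1..K in case a cell lost all pixels
  relabel <- function(m) {
    present <- sort(unique(m[m > 0L]))
    if (length(present)) m[] <- match(m, c(0L, present), nomatch = 1L) - 1L
    m
  }
  frames <- lapply(names(chan), function(nm) {
    img <- chan[[nm]] + spec@background
    if (spec@noiseSigma > 0)
      img <- img + matrix(rnorm(length(img), 0, spec@noiseSigma),
                          dim[1], dim[2])
    Frame(pmax(img, 0), channel = nm, timepoint = 0, timeUnit = "day",
          pixelSize = px)
  })
  names(frames) <- names(chan)
  masks <- lapply(lab, function(m) LabelMask(relabel(m), pixelSize = px))
  list(frames = frames, masks = masks, truth = truth, mito = mitoTruth,
       spec = spec)
}

# sample one cell's geometry; masks are full-field logicals
sampleCellGeometry <- function(cls, spec, dim) {
  px <- spec@pixelSize
  margin <- 12 / px
  cy <- runif(1, margin, dim[1] - 1 - margin)
  cx <- runif(1, margin, dim[2] - 1 - margin)
  if (cls == "iMN") {
    r <- runif(1, spec@somaRadius[1], spec@somaRadius[2])
    core <- maskDisk(dim, cy, cx, r / px)
    nucleus <- maskDisk(dim, cy, cx, .NUCLEUS_FRACTION * r / px)
    k <- sample(spec@neuriteCount[1]:spec@neuriteCount[2], 1L)
    neurites <- matrix(FALSE, dim[1], dim[2])
    for (j in seq_len(k)) {
      len <- runif(1, spec@neuriteLength[1], spec@neuriteLength[2])
      neurites <- neurites |
        neuriteMask(dim, cy, cx, r / px, len / px, px)
    }
    list(core = core, nucleus = nucleus, neurites = neurites,
         amplitude = runif(1, spec@somaIntensity[1], spec@somaIntensity[2]),
         nNeurites = k)
  } else if (cls == "non-iMN") {
    a <- runif(1, .NONIMN_MAJOR[1], .NONIMN_MAJOR[2]) / 2
    e <- runif(1, .NONIMN_ECC[1], .NONIMN_ECC[2])
    b <- a * sqrt(1 - e^2)
    th <- runif(1, 0, pi)
    core <- maskEllipse(dim, cy, cx, a / px, b / px, th)
    nucleus <- maskDisk(dim, cy, cx, min(5, b * 0.8) / px)
    list(core = core, nucleus = nucleus, neurites = NULL,
         amplitude = runif(1, .NONIMN_INTENSITY[1], .NONIMN_INTENSITY[2]),
         nNeurites = 0L)
  } else {
    k <- sample(.DEAD_FRAG_COUNT[1]:.DEAD_FRAG_COUNT[2], 1L)
    core <- matrix(FALSE, dim[1], dim[2])
    placedFrag <- matrix(numeric(0), 0, 3)   # cy, cx, r (um)
    for (j in seq_len(k)) {
      # keep fragments disjoint so debris really is fragmented
      for (try in 1:20) {
        fr <- runif(1, .DEAD_FRAG_RADIUS[1], .DEAD_FRAG_RADIUS[2])
        ang <- runif(1, 0, 2 * pi)
        d <- runif(1, 2, .DEAD_SCATTER)
        fy <- cy + d * sin(ang) / px; fx <- cx + d * cos(ang) / px
        if (nrow(placedFrag) == 0L ||
            all(sqrt((placedFrag[, 1] - fy)^2 +
                       (placedFrag[, 2] - fx)^2) * px >
                  placedFrag[, 3] + fr + 2 * px)) break
      }
      placedFrag <- rbind(placedFrag, c(fy, fx, fr))
      core <- core | maskDisk(dim, fy, fx, fr / px)
    }
    list(core = core, nucleus = NULL, neurites = NULL,
         amplitude = runif(1, .DEAD_INTENSITY[1], .DEAD_INTENSITY[2]),
         nNeurites = 0L)
  }
}

# random-walk neurite leaving the soma edge
neuriteMask <- function(dim, cy, cx, rPx, lenPx, px) {
  ang <- runif(1, 0, 2 * pi)
  stepPx <- 2 / px
  nstep <- max(2L, ceiling(lenPx / stepPx))
  pts <- matrix(0, nstep + 1L, 2L)
  pts[1L, ] <- c(cy + rPx * sin(ang), cx + rPx * cos(ang))
  for (s in seq_len(nstep)) {
    ang <- ang + rnorm(1, 0, 0.25)
    pts[s + 1L, ] <- pts[s, ] + stepPx * c(sin(ang), cos(ang))
  }
  pts[, 1] <- pmin(pmax(pts[, 1], 0), dim[1] - 1)
  pts[, 2] <- pmin(pmax(pts[, 2], 0), dim[2] - 1)
  maskPolyline(dim, pts, halfWidth = (.NEURITE_WIDTH / 2) / px)
}
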