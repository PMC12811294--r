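#' Detection parameters for blob (cell body / nucleus) detection
#'
#' @param sigma Gaussian blur sd in um
#' @param method threshold method: `"otsu"` or `"fixed"`
#' @param fixedThreshold intensity cutoff when `method = "fixed"`
#' @param minArea,maxArea object area bounds in um^2
#' @param minRoundness minimum roundness `4*pi*area/perimeter^2`; `NA`
#'   disables the bound (nuclei presets disable it)
#' @return a `DetectionParams` list
#' @export
detectionParams <- function(sigma = 2, method = c("otsu", "fixed"),
    fixedThreshold = NA_real_, minArea = 30, maxArea = 400,
    minRoundness = 0.5) {
  method <- match.arg(method)
  if (sigma <= 0) stop("sigma must be > 0")
  if (!(minArea > 0 && minArea < maxArea))
    stop("need 0 < minArea < maxArea")
  structure(list(sigma = sigma, method = method,
                 fixedThreshold = fixedThreshold, minArea = minArea,
                 maxArea = maxArea, minRoundness = minRoundness),
            class = "DetectionParams")
}

#' Remove large-scale background from a frame
#'
#' Rolling-ball-style background subtraction: the background is estimated
#' by grayscale morphological opening with a disc of the given radius
#' (computed on a downsampled image when the disc would be large, then
#' resampled back), subtracted, and the result clipped at zero. Objects
#' smaller than about half the radius survive with their peak amplitudes
#' intact; a flat image maps to zero everywhere, and re-applying the
#' operator to its own output changes little (the background is already
#' flat).
#'
#' @param frame a [Frame-class]
#' @param radius ball radius in um; must exceed the largest foreground
#'   object's radius
#' @return background-subtracted [Frame-class]
#' @export
subtractBackground <- function(frame, radius = 50) {
  if (radius <= 0) stop("radius must be > 0")
  img <- frame@data
  rPx <- radius / frame@pixelSize
  # shrink so the structuring element stays small (ImageJ-style)
  shrink <- max(1L, ceiling(rPx / 12))
  small <- if (shrink > 1L)
    as.matrix(EBImage::resize(img, w = max(2L, ceiling(nrow(img) / shrink)),
                              h = max(2L, ceiling(ncol(img) / shrink))))
  else img
  r <- max(1L, round(rPx / shrink))
  bg <- grayDilate(grayErode(small, r), r)
  if (shrink > 1L)
    bg <- as.matrix(EBImage::resize(bg, w = nrow(img), h = ncol(img)))
  out <- pmax(img - bg, 0)
  Frame(out, channel = frame@channel, timepoint = frame@timepoint,
        timeUnit = frame@timeUnit, pixelSize = frame@pixelSize)
}

# grayscale erosion/dilation with a (2r+1) square window and replicated
# borders (EBImage pads with zeros, which wrecks background estimates at
# the image edge)
grayErode <- function(m, r) runFilt(runFilt(m, r, pmin, 1), r, pmin, 2)
grayDilate <- function(m, r) runFilt(runFilt(m, r, pmax, 1), r, pmax, 2)

runFilt <- function(m, r, op, margin) {
  out <- m
  n <- dim(m)[margin]
  for (k in seq_len(min(r, n - 1L))) {
    if (margin == 1L) {
      up <- m[c(rep(1L, k), seq_len(n - k)), , drop = FALSE]
      dn <- m[c(seq_len(n - k) + k, rep(n, k)), , drop = FALSE]
    } else {
      up <- m[, c(rep(1L, k), seq_len(n - k)), drop = FALSE]
      dn <- m[, c(seq_len(n - k) + k, rep(n, k)), drop = FALSE]
    }
    out <- op(out, up, dn)
  }
  out
}

#' Detect blobs by blurring, thresholding and size/roundness exclusion
#'
#' The standard cell-body / nucleus detector: Gaussian blur at
#' `params$sigma`, a global threshold (Otsu on the blurred image by
#' default, or a fixed value), connected-component labelling, then
#' exclusion of components outside the `[minArea, maxArea]` bound or below
#' `minRoundness` (roundness = `4*pi*area/perimeter^2` on the pixel
#' boundary). Surviving objects are relabelled `1..K` in top-left scan
#' order.
#'
#' @param frame a background-subtracted [Frame-class]
#' @param params a [detectionParams()] list
#' @return a [LabelMask-class]
#' @export
detectBlobs <- function(frame, params = detectionParams()) {
  px <- frame@pixelSize
  img <- frame@data
  blur <- EBImage::gblur(img, sigma = params$sigma / px)
  thr <- switch(params$method,
    otsu = {
      rg <- range(blur)
      if (diff(rg) < 1e-12) Inf else EBImage::otsu(blur, range = rg)
    },
    fixed = {
      if (is.na(params$fixedThreshold))
        stop("fixed threshold method needs fixedThreshold")
      params$fixedThreshold
    },
    stop("unknown threshold method '", params$method, "'"))
  bw <- blur > thr
  if (!any(bw)) return(LabelMask(matrix(0L, nrow(img), ncol(img)), px))
  lab <- EBImage::bwlabel(bw)
  filterLabelMask(lab, px, params)
}

# apply area/roundness bounds and relabel in top-left scan order
filterLabelMask <- function(lab, px, params) {
  lab <- as.matrix(lab)
  storage.mode(lab) <- "integer"
  if (max(lab) == 0L) return(LabelMask(lab, px))
  ids <- seq_len(max(lab))
  area <- vapply(ids, function(k) sum(lab == k), numeric(1)) * px^2
  perim <- vapply(ids, function(k) maskPerimeter(lab == k),
                  numeric(1)) * px
  roundness <- pmin(4 * pi * area / pmax(perim, 1e-9)^2, 1)
  keep <- area >= params$minArea & area <= params$maxArea
  if (!is.na(params$minRoundness))
    keep <- keep & roundness >= params$minRoundness
  keepIds <- which(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (length(keepIds)) {
    # scan-order relabelling: order of first pixel in column-major scan
    first <- vapply(keepIds, function(k) which(lab == k)[1], numeric(1))
    ord <- keepIds[order(first)]
    for (i in seq_along(ord)) out[lab == ord[i]] <- i
  }
  LabelMask(out, px)
}

#' Histogram-equalized composite of two channels
#'
#' Each channel is exactly rank-equalized — pixel value replaced by
#' `(rank - 1)/(n - 1)` with average ranks on ties, so a strictly
#' monotone image maps onto a uniform histogram in `[0, 1]` — and the two
#' equalized images are summed pixelwise. The composite (range `[0, 2]`)
#' enhances dim cytoplasm and neurites relative to either raw channel and
#' is the substrate for seeded single-cell segmentation.
#'
#' Intensities are first quantized to `nBins` grey levels (as on the 8/16
#' bit data the method was designed for); pixels sharing a level share
#' their average rank, which keeps a flat noisy background collapsed at
#' its histogram mass midpoint instead of being spread over the range.
#' `nBins = NULL` gives exact continuous equalization.
#'
#' @param chanA,chanB co-registered [Frame-class] objects of equal shape
#'   (typically the antibody and nuclear channels)
#' @param nBins grey-level quantization before ranking (default 256)
#' @return a [Frame-class] with channel tag `"EQ"`
#' @export
equalizeAndSum <- function(chanA, chanB, nBins = 256L) {
  if (!all(dim(chanA@data) == dim(chanB@data)))
    stop("channel shapes differ")
  eq <- function(m) {
    n <- length(m)
    if (n == 1L) return(matrix(0.5, 1, 1))
    v <- m
    if (!is.null(nBins)) {
      rg <- range(m)
      if (diff(rg) > 0)
        v <- floor((m - rg[1]) / diff(rg) * (nBins - 1L) + 0.5)
    }
    r <- rank(v, ties.method = "average")
    matrix((r - 1) / (n - 1), nrow(m), ncol(m))
  }
  Frame(eq(chanA@data) + eq(chanB@data), channel = "EQ",
        timepoint = chanA@timepoint, timeUnit = chanA@timeUnit,
        pixelSize = chanA@pixelSize)
}

#' Seeded watershed single-cell segmentation
#'
#' Partitions the foreground among the seed objects by seeded region
#' growing on the (inverted) EQ composite — the propagate algorithm of the
#' CellProfiler lineage, which is the seeded-watershed step of the
#' pipeline. Every seed must lie inside the foreground; each output region
#' carries its seed's label and contains that seed, and the regions are
#' disjoint with union equal to the foreground reachable from any seed.
#'
#' @param eq the EQ composite [Frame-class] (bright cells)
#' @param seeds a [LabelMask-class] of seed objects (typically nuclei)
#' @param foreground logical matrix marking cell-covered pixels (defaults
#'   to an Otsu threshold of the composite)
#' @return a [LabelMask-class] of single-cell regions
#' @export
watershedCells <- function(eq, seeds, foreground = NULL) {
  img <- eq@data
  if (is.null(foreground)) {
    # the composite has a flat histogram by construction; a light blur
    # restores bimodality before the Otsu cut
    b <- EBImage::gblur(img, sigma = 1)
    foreground <- b > EBImage::otsu(b, range = range(b))
  }
  sd <- seeds@data
  # seeds must sit in foreground; tolerate partial overhang, reject only
  # seeds entirely outside
  wholly <- vapply(sort(unique(sd[sd > 0])), function(k)
    !any(foreground[sd == k]), logical(1))
  if (any(wholly))
    stop("seed(s) outside foreground: ",
         paste(sort(unique(sd[sd > 0]))[wholly], collapse = ", "))
  out <- EBImage::propagate(max(img) - img, seeds = sd,
                            mask = foreground, lambda = 1e-4)
  out <- as.matrix(out)
  storage.mode(out) <- "integer"
  # preserve seed labelling; relabel consecutively if seeds were sparse
  present <- sort(unique(out[out > 0L]))
  out[] <- match(out, c(0L, present), nomatch = 1L) - 1L
  LabelMask(out, eq@pixelSize)
}

#' Square centre-crop of a stated physical size
#'
#' Crops a `side` x `side` um square centred on a pixel position,
#' zero-padding whatever falls outside the field, so the centre always
#' maps to the crop midpoint. At 0.69 um/px a 27.6 um side gives a
#' 40 px crop.
#'
#' @param frame a [Frame-class]
#' @param center 0-based `(row, col)` pixel position inside the frame
#' @param side crop side length in um
#' @return a [Frame-class] crop
#' @export
cropCentered <- function(frame, center, side) {
  if (side <= 0) stop("side must be > 0")
  d <- dim(frame@data)
  if (center[1] < 0 || center[1] > d[1] - 1 ||
      center[2] < 0 || center[2] > d[2] - 1)
    stop("center outside frame bounds")
  n <- max(1L, round(side / frame@pixelSize))
  out <- matrix(0, n, n)
  half <- floor((n - 1) / 2)
  ys <- round(center[1]) - half + 0:(n - 1)
  xs <- round(center[2]) - half + 0:(n - 1)
  okY <- ys >= 0 & ys < d[1]; okX <- xs >= 0 & xs < d[2]
  out[which(okY), which(okX)] <- frame@data[ys[okY] + 1L, xs[okX] + 1L]
  Frame(out, channel = frame@channel, timepoint = frame@timepoint,
        timeUnit = frame@timeUnit, pixelSize = frame@pixelSize)
}
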