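#' @import methods
#' @importFrom stats rnorm runif rexp lm coef sd aov pnorm qnorm setNames
#'   complete.cases
#' @importFrom utils head tail read.csv write.csv
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All generators route their randomness through this, which is
# what makes the spec+seed => identical-output contract hold.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# half-open boxes (y0, x0, y1, x1): intersection-over-union
boxIoU <- function(a, b) {
  iy <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ix <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iy * ix
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) return(0)
  inter / ua
}

# vectorised IoU matrix between two box data.frames with columns y0,x0,y1,x1
iouMatrix <- function(A, B) {
  if (nrow(A) == 0L || nrow(B) == 0L)
    return(matrix(0, nrow(A), nrow(B)))
  iy <- pmax(0, outer(A$y1, B$y1, pmin) - outer(A$y0, B$y0, pmax))
  ix <- pmax(0, outer(A$x1, B$x1, pmin) - outer(A$x0, B$x0, pmax))
  inter <- iy * ix
  areaA <- (A$y1 - A$y0) * (A$x1 - A$x0)
  areaB <- (B$y1 - B$y0) * (B$x1 - B$x0)
  un <- outer(areaA, areaB, "+") - inter
  out <- inter / un
  out[un <= 0] <- 0
  out
}

# minimal union-find for transitive track merging
ufFind <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# raster helpers -------------------------------------------------------------

# logical mask of a filled disk; centre in 0-based pixel coords
maskDisk <- function(dim, cy, cx, r) {
  yy <- matrix(seq_len(dim[1]) - 1, dim[1], dim[2])
  xx <- matrix(seq_len(dim[2]) - 1, dim[1], dim[2], byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

# filled rotated ellipse, semi-axes (a, b) px, angle radians
maskEllipse <- function(dim, cy, cx, a, b, theta) {
  yy <- matrix(seq_len(dim[1]) - 1, dim[1], dim[2]) - cy
  xx <- matrix(seq_len(dim[2]) - 1, dim[1], dim[2], byrow = TRUE) - cx
  u <- xx * cos(theta) + yy * sin(theta)
  v <- -xx * sin(theta) + yy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# rasterise a polyline (px coords, 0-based, matrix with columns y,x) with a
# given half-width in px; returns logical mask
maskPolyline <- function(dim, pts, halfWidth) {
  m <- matrix(FALSE, dim[1], dim[2])
  if (nrow(pts) < 2L) return(m)
  for (i in seq_len(nrow(pts) - 1L)) {
    p0 <- pts[i, ]; p1 <- pts[i + 1L, ]
    len <- sqrt(sum((p1 - p0)^2))
    nstep <- max(2L, ceiling(len * 2))
    t <- seq(0, 1, length.out = nstep)
    ys <- round(p0[1] + t * (p1[1] - p0[1]))
    xs <- round(p0[2] + t * (p1[2] - p0[2]))
    keep <- ys >= 0 & ys < dim[1] & xs >= 0 & xs < dim[2]
    m[cbind(ys[keep] + 1L, xs[keep] + 1L)] <- TRUE
  }
  if (halfWidth >= 1) {
    brush <- EBImage::makeBrush(2L * floor(halfWidth) + 1L, shape = "disc")
    m <- EBImage::dilate(m, brush) > 0
  }
  m
}

# additive Gaussian spot (for mitochondria / kymograph puncta)
addSpot <- function(img, cy, cx, sigma, amplitude) {
  r <- ceiling(3 * sigma)
  y0 <- max(0, floor(cy - r)); y1 <- min(nrow(img) - 1, ceiling(cy + r))
  x0 <- max(0, floor(cx - r)); x1 <- min(ncol(img) - 1, ceiling(cx + r))
  if (y1 < y0 || x1 < x0) return(img)
  ys <- y0:y1; xs <- x0:x1
  g <- outer(exp(-(ys - cy)^2 / (2 * sigma^2)),
             exp(-(xs - cx)^2 / (2 * sigma^2)))
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + amplitude * g
  img
}

# 0-based bounding box (y0, x0, y1, x1), half-open, of a logical mask
maskBBox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
  c(min(w[, 1]) - 1, min(w[, 2]) - 1, max(w[, 1]), max(w[, 2]))
}

# bilinear interpolation of matrix `img` at 0-based (y, x) positions
bilinear <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  y <- pmin(pmax(y, 0), ny - 1); x <- pmin(pmax(x, 0), nx - 1)
  y0 <- floor(y); x0 <- floor(x)
  y1 <- pmin(y0 + 1, ny - 1); x1 <- pmin(x0 + 1, nx - 1)
  fy <- y - y0; fx <- x - x0
  i00 <- img[cbind(y0 + 1, x0 + 1)]; i01 <- img[cbind(y0 + 1, x1 + 1)]
  i10 <- img[cbind(y1 + 1, x0 + 1)]; i11 <- img[cbind(y1 + 1, x1 + 1)]
  i00 * (1 - fy) * (1 - fx) + i01 * (1 - fy) * fx +
    i10 * fy * (1 - fx) + i11 * fy * fx
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

# perimeter of a logical mask in px: exposed 4-neighbour edge count with
# the pi/4 correction (exact for circles, adequate for blobs)
maskPerimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  up <- rbind(FALSE, mask[-nr, , drop = FALSE])
  down <- rbind(mask[-1, , drop = FALSE], FALSE)
  left <- cbind(FALSE, mask[, -nc, drop = FALSE])
  right <- cbind(mask[, -1, drop = FALSE], FALSE)
  exposed <- sum(mask & !up) + sum(mask & !down) +
    sum(mask & !left) + sum(mask & !right)
  exposed * pi / 4
}
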