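# shared fixtures, built once per test run

# a moderate training culture and fitted classifier, reused by the
# classification and tracking tests
trainingFeatures <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ft <- do.call(rbind, lapply(1:2, function(s) sceneFeatureTable(
        generateCultureImage(sceneSpec(nIMN = 20, nNonIMN = 10,
                                       nDead = 10,
                                       fieldSize = c(450, 450),
                                       seed = 100 + s)))))
      cache <<- ft
    }
    cache
  }
})

trainedModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fitClassifier(trainingFeatures(),
                                                seed = 1L)
    cache
  }
})

# draw a filled disk Frame
diskFrame <- function(dim = c(80, 80), cy = 40, cx = 40, r = 15,
                      amplitude = 100, background = 0, pixelSize = 0.345) {
  img <- matrix(background, dim[1], dim[2])
  img[imnpheno:::maskDisk(dim, cy, cx, r)] <- background + amplitude
  Frame(img, channel = "cytoplasm", pixelSize = pixelSize)
}

# simple straight-line synthetic kymograph track
lineTrack <- function(positions, dt = 3) {
  data.frame(mitoId = 1L, frame = seq_along(positions),
             time = (seq_along(positions) - 1) * dt,
             position = positions)
}

# brute-force optimal one-to-one assignment value (sum of IoU) for a
# small IoU matrix, by permutation enumeration
bruteBestAssignment <- function(M, iouMin) {
  n <- nrow(M); m <- ncol(M)
  k <- min(n, m)
  best <- list(value = -Inf, pairs = NULL)
  idx <- utils::combn(seq_len(n), k, simplify = FALSE)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  cols <- perms(seq_len(m))
  for (rows in idx) for (cp in cols) {
    csel <- cp[seq_len(k)]
    val <- 0; pairs <- NULL
    for (j in seq_len(k)) {
      if (M[rows[j], csel[j]] >= iouMin) {
        val <- val + M[rows[j], csel[j]]
        pairs <- rbind(pairs, c(rows[j], csel[j]))
      }
    }
    if (val > best$value) best <- list(value = val, pairs = pairs)
  }
  best
}
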