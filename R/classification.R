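#' Extract morphological features for one segmented cell
#'
#' The seven-feature vector the three-class morphology classifier
#' consumes: soma area (um^2), soma roundness, fragment count within a
#' centre crop, neurite count, total neurite skeleton length (um), and the
#' mean and maximum intensity over the cell region. The fragment count is
#' the number of connected components of the cell's mask inside a
#' `cropSide` square around its centroid — dead debris fragments into
#' several pieces, intact cells do not. Neurite count approximates the
#' number of processes leaving the soma: connected components of the cell
#' region minus the (dilated) soma that touch the soma boundary.
#'
#' @param somaMask logical matrix for the cell's soma/core
#' @param cellMask logical matrix for the full cell (soma + neurites)
#' @param frame intensity [Frame-class]
#' @param cropSide side of the fragment-count crop (um)
#' @return one-row data.frame of the 7 features
#' @export
extractCellFeatures <- function(somaMask, cellMask, frame,
                                cropSide = 27.6) {
  if (!any(somaMask)) stop("empty mask")
  px <- frame@pixelSize
  # everything below is local to the cell: crop to its bounding box
  bb <- maskBBox(somaMask | cellMask)
  pad <- 3L
  ys <- max(1, bb[1] + 1 - pad):min(nrow(somaMask), bb[3] + pad)
  xs <- max(1, bb[2] + 1 - pad):min(ncol(somaMask), bb[4] + pad)
  somaMask <- somaMask[ys, xs, drop = FALSE]
  cellMask <- cellMask[ys, xs, drop = FALSE]
  frame <- Frame(frame@data[ys, xs, drop = FALSE],
                 channel = frame@channel, timepoint = frame@timepoint,
                 timeUnit = frame@timeUnit, pixelSize = px)
  area <- sum(somaMask) * px^2
  perim <- max(maskPerimeter(somaMask), 1) * px
  roundness <- min(4 * pi * area / perim^2, 1)

  ctr <- colMeans(which(somaMask, arr.ind = TRUE)) - 1
  half <- max(1L, round(cropSide / px / 2))
  ys <- max(1, round(ctr[1]) + 1 - half):min(nrow(somaMask),
                                             round(ctr[1]) + 1 + half)
  xs <- max(1, round(ctr[2]) + 1 - half):min(ncol(somaMask),
                                             round(ctr[2]) + 1 + half)
  fragments <- max(EBImage::bwlabel(somaMask[ys, xs, drop = FALSE]))

  dil <- EBImage::dilate(somaMask, EBImage::makeBrush(5L, "disc")) > 0
  procs <- cellMask & !somaMask
  neuriteCount <- 0L
  skelLength <- 0
  if (any(procs)) {
    plab <- EBImage::bwlabel(procs)
    touching <- unique(plab[plab > 0 & dil])
    neuriteCount <- length(touching)
    if (neuriteCount > 0) {
      nm <- matrix(plab %in% touching, nrow(plab), ncol(plab))
      sk <- tryCatch(
        skeletonizeCell(nm | somaMask, px, somaMask = somaMask),
        error = function(e) NULL)
      if (!is.null(sk)) skelLength <- sk$totalLength
    }
  }
  vals <- frame@data[cellMask]
  data.frame(somaArea = area, roundness = roundness,
             fragmentCount = fragments, neuriteCount = neuriteCount,
             skeletonLength = skelLength,
             meanIntensity = mean(vals), maxIntensity = max(vals))
}

#' Features + true labels for every cell of a generated scene
#'
#' Runs [extractCellFeatures()] over the ground-truth masks of a
#' [generateCultureImage()] scene, which is how labelled training tables
#' for the classifier are produced.
#'
#' @param scene a [generateCultureImage()] result
#' @return data.frame of features plus `class`
#' @export
sceneFeatureTable <- function(scene) {
  cellLab <- scene$masks$cell@data
  somaLab <- scene$masks$soma@data
  rows <- lapply(seq_len(nrow(scene$truth)), function(i) {
    id <- scene$truth$id[i]
    soma <- somaLab == id
    if (!any(soma)) return(NULL)
    cell <- cellLab == id | soma
    f <- extractCellFeatures(soma, cell, scene$frames$cytoplasm)
    cbind(f, data.frame(class = scene$truth$class[i]))
  })
  do.call(rbind, rows)
}

.CLASS_LEVELS <- c("iMN", "non-iMN", "dead")
.FEATURES <- c("somaArea", "roundness", "fragmentCount", "neuriteCount",
               "skeletonLength", "meanIntensity", "maxIntensity")

#' Fit the three-class morphology classifier
#'
#' Default engine is multinomial logistic regression on the 7
#' standardized features (`nnet::multinom`), trained on a seeded split
#' with validation accuracy reported. A thresholds-only fallback
#' (`engine = "rules"`) encodes the archetype criteria directly —
#' fragmentation => dead, large flat dim => non-iMN, otherwise iMN — and
#' needs no fitting. Both are deterministic given the seed and serialise
#' to JSON.
#'
#' @param features data.frame with the 7 feature columns and a `class`
#'   column
#' @param seed RNG seed for the train/validation split
#' @param engine `"multinom"` or `"rules"`
#' @param validationFraction held-out fraction for the reported accuracy
#' @return a `ClassifierModel` list with elements `engine`, `scale`
#'   (centers/sds), `coef`, `validationAccuracy`, `nTrain`,
#'   `nValidation`, `seed`
#' @export
fitClassifier <- function(features, seed = 1L,
                          engine = c("multinom", "rules"),
                          validationFraction = 0.2) {
  engine <- match.arg(engine)
  cls <- factor(features$class, levels = .CLASS_LEVELS)
  if (length(unique(cls[!is.na(cls)])) < 2L)
    stop("degenerate training set: need >= 2 classes")
  if (engine == "rules") {
    model <- list(engine = "rules", seed = as.integer(seed),
                  nTrain = nrow(features), nValidation = 0L,
                  validationAccuracy = NA_real_)
    class(model) <- "ClassifierModel"
    return(model)
  }
  withSeed(seed, {
    n <- nrow(features)
    vIdx <- sample.int(n, max(1L, round(validationFraction * n)))
    train <- features[-vIdx, , drop = FALSE]
    valid <- features[vIdx, , drop = FALSE]
    X <- as.matrix(train[, .FEATURES])
    mu <- colMeans(X); sdv <- pmax(apply(X, 2, sd), 1e-9)
    Xs <- scale(X, mu, sdv)
    df <- data.frame(Xs, class = factor(train$class,
                                        levels = .CLASS_LEVELS))
    fit <- nnet::multinom(class ~ ., data = df, trace = FALSE,
                          maxit = 300)
    model <- list(engine = "multinom", scaleCenter = mu, scaleSd = sdv,
                  coef = coef(fit), levels = levels(df$class),
                  seed = as.integer(seed), nTrain = nrow(train),
                  nValidation = nrow(valid))
    class(model) <- "ClassifierModel"
    pred <- classifyFeatures(valid, model)
    model$validationAccuracy <- mean(pred == valid$class)
    model
  })
}

# posterior matrix for the multinom engine
multinomPosterior <- function(features, model) {
  X <- as.matrix(features[, .FEATURES])
  Xs <- scale(X, model$scaleCenter, model$scaleSd)
  cf <- model$coef
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
  eta <- cbind(0, Xs %*% t(cf[, -1, drop = FALSE]) +
                 matrix(cf[, 1], nrow(Xs), nrow(cf), byrow = TRUE))
  p <- exp(eta - apply(eta, 1, max))
  p / rowSums(p)
}

#' Classify cells from their feature table
#'
#' Every input row gets exactly one of the three labels, in input order.
#' For the multinomial engine the highest posterior wins; exact posterior
#' ties break by the priority dead > non-iMN > iMN, which biases against
#' inflating transformation efficiency.
#'
#' @param features feature data.frame (7 columns of
#'   [extractCellFeatures()])
#' @param model a fitted `ClassifierModel`
#' @return character vector of labels in `{"iMN", "non-iMN", "dead"}`
#' @export
classifyFeatures <- function(features, model) {
  if (nrow(features) == 0L) return(character(0))
  if (!all(.FEATURES %in% names(features)))
    stop("feature schema mismatch: need ",
         paste(.FEATURES, collapse = ", "))
  if (model$engine == "rules") {
    ifelse(features$fragmentCount >= 2 & features$somaArea <= 80, "dead",
      ifelse(features$somaArea >= 250 & features$roundness < 0.75,
             "non-iMN", "iMN"))
  } else {
    p <- multinomPosterior(features, model)
    colnames(p) <- model$levels
    prio <- c(dead = 3, `non-iMN` = 2, iMN = 1)
    apply(p, 1, function(r) {
      best <- which(r == max(r))
      names(r)[best][which.max(prio[names(r)[best]])]
    })
  }
}

#' Serialize / restore a classifier model
#' @param model a `ClassifierModel`
#' @param path JSON file path
#' @return `writeClassifier` returns `path`; `readClassifier` the model
#' @export
writeClassifier <- function(model, path) {
  out <- unclass(model)
  if (!is.null(out$coef)) out$coef <- as.data.frame(out$coef)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeClassifier
#' @export
readClassifier <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(m$coef)) m$coef <- as.matrix(m$coef)
  if (!is.null(m$scaleCenter)) {
    m$scaleCenter <- unlist(m$scaleCenter)
    m$scaleSd <- unlist(m$scaleSd)
  }
  class(m) <- "ClassifierModel"
  m
}

#' Transformation efficiency of a classified culture
#'
#' The fraction of detected cells exhibiting neuronal morphology:
#' iMN count over all detected cells (all three classes in the
#' denominator by default; `denominator = "alive"` excludes dead cells).
#' When a `batch` column is present, the per-batch efficiencies are
#' averaged and their SEM reported.
#'
#' @param records data.frame with a `class` column (and optionally
#'   `line`, `batch`)
#' @param denominator `"all"` or `"alive"`
#' @return list with `efficiency` (overall), and `perBatch` /`summary`
#'   (mean and SEM across batches, per line when a `line` column exists)
#' @export
transformationEfficiency <- function(records,
                                     denominator = c("all", "alive")) {
  denominator <- match.arg(denominator)
  if (nrow(records) == 0L) stop("undefined ratio: zero records")
  eff <- function(cl) {
    den <- if (denominator == "all") length(cl) else sum(cl != "dead")
    if (den == 0L) return(NA_real_)
    sum(cl == "iMN") / den
  }
  overall <- eff(records$class)
  out <- list(efficiency = overall)
  if (!is.null(records$batch)) {
    key <- if (!is.null(records$line))
      interaction(records$line, records$batch, drop = TRUE)
    else factor(records$batch)
    per <- tapply(records$class, key, eff)
    grp <- if (!is.null(records$line))
      sub("\\..*$", "", names(per)) else rep("all", length(per))
    out$perBatch <- data.frame(key = names(per), efficiency = as.numeric(per))
    out$summary <- do.call(rbind, lapply(split(as.numeric(per), grp),
      function(v) data.frame(mean = mean(v),
                             sem = if (length(v) > 1) sem(v) else NA_real_,
                             n = length(v))))
  }
  out
}
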