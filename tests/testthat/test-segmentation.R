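test_that("background subtraction flattens backgrounds, keeps peaks", {
  px <- 0.345
  # flat image maps to zero
  flat <- subtractBackground(Frame(matrix(77, 60, 60), pixelSize = px), 20)
  expect_equal(max(frameData(flat)), 0)

  # flat 100 + 6 um Gaussian spot of amplitude 50, ball radius 50 um:
  # the spot survives at its amplitude over a zeroed background
  img <- matrix(100, 200, 200)
  img <- imnpheno:::addSpot(img, 100, 100, sigma = 3 / px, amplitude = 50)
  out <- subtractBackground(Frame(img, pixelSize = px), radius = 50)
  expect_lt(abs(max(frameData(out)) - 50), 2.5)
  expect_lt(max(abs(frameData(out)[1:30, 1:30])), 1)

  # idempotence once the background is flat
  out2 <- subtractBackground(out, radius = 50)
  expect_lt(max(abs(frameData(out2) - frameData(out))) /
              max(frameData(out)), 0.01)
  expect_error(subtractBackground(out, radius = -1), "radius")
})

test_that("blob detection applies size and roundness exclusion", {
  blank <- detectBlobs(Frame(matrix(0, 50, 50), pixelSize = 0.69))
  expect_equal(objectCount(blank), 0L)

  # 8 somata within bounds plus 2 debris cells below the minimum area
  sc <- generateCultureImage(sceneSpec(nIMN = 8, nNonIMN = 0, nDead = 2,
                                       fieldSize = c(300, 300), seed = 2))
  m <- detectBlobs(subtractBackground(sc$frames$cytoplasm, 40),
                   detectionParams(sigma = 1, minArea = 40,
                                   maxArea = 400, minRoundness = 0.5))
  expect_equal(objectCount(m), 8L)

  # two somata merged into one oversized component are excluded
  img <- matrix(0, 120, 120)
  img[imnpheno:::maskDisk(c(120, 120), 60, 45, 16)] <- 150
  img[imnpheno:::maskDisk(c(120, 120), 60, 72, 16)] <- 150
  big <- detectBlobs(Frame(img, pixelSize = 0.69),
                     detectionParams(sigma = 1, minArea = 30,
                                     maxArea = 400, minRoundness = NA))
  expect_equal(objectCount(big), 0L)
  expect_error(detectBlobs(Frame(img, pixelSize = 0.69),
                           detectionParams(method = "fixed")),
               "fixedThreshold")
})

test_that("histogram-equalized composite has the contracted range and law", {
  a <- Frame(matrix(runif(2500) * 300, 50, 50), pixelSize = 0.1725)
  out <- equalizeAndSum(a, a)
  # symmetric inputs: exactly twice the equalization of either
  expect_true(min(frameData(out)) >= 0 && max(frameData(out)) <= 2)
  b <- Frame(matrix(runif(2500), 50, 50), pixelSize = 0.1725)
  expect_error(equalizeAndSum(a, Frame(matrix(1, 10, 10),
                                       pixelSize = 0.1725)), "shapes")

  # a strictly monotone ramp equalizes onto a uniform histogram
  n <- 1000L
  ramp <- Frame(matrix(seq_len(n * n) / (n * n), n, n),
                pixelSize = 0.1725)
  eq <- frameData(equalizeAndSum(ramp, ramp, nBins = NULL)) / 2
  ks <- suppressWarnings(stats::ks.test(as.vector(eq), "punif"))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("seeded watershed partitions the foreground around its seeds", {
  # one seed, connected foreground: the region is the whole foreground
  eq <- Frame(matrix(1, 30, 30), pixelSize = 0.345)
  fg <- imnpheno:::maskDisk(c(30, 30), 15, 15, 10)
  seeds <- matrix(0L, 30, 30); seeds[15, 15] <- 1L
  ws <- watershedCells(eq, LabelMask(seeds, 0.345), fg)
  expect_identical(frameData(ws) > 0, fg)

  # two seeds: two regions, disjoint, union = foreground
  seeds2 <- matrix(0L, 30, 30); seeds2[15, 10] <- 1L; seeds2[15, 20] <- 2L
  ws2 <- watershedCells(eq, LabelMask(seeds2, 0.345), fg)
  expect_equal(objectCount(ws2), 2L)
  expect_identical(frameData(ws2) > 0, fg)

  # seed outside the foreground is an error naming the label
  seeds3 <- matrix(0L, 30, 30); seeds3[1, 1] <- 1L
  expect_error(watershedCells(eq, LabelMask(seeds3, 0.345), fg),
               "outside foreground")
})

test_that("touching cells separate with high per-cell overlap", {
  hits <- 0L; total <- 0L
  for (sd in c(5, 11)) {
    sc <- generateCultureImage(sceneSpec(nIMN = 10, nNonIMN = 0,
      nDead = 0, fieldSize = c(110, 110), pixelSize = 0.345,
      somaRadius = c(6, 9), neuriteCount = c(0, 0), seed = sd))
    eq <- equalizeAndSum(sc$frames$antibody, sc$frames$nucleus)
    ws <- watershedCells(eq, sc$masks$nucleus)
    wd <- frameData(ws)
    cellLab <- frameData(sc$masks$cell)
    somaLab <- frameData(sc$masks$soma)
    for (i in 1:10) {
      gtm <- cellLab == i | somaLab == i
      pm <- wd == i
      iou <- sum(gtm & pm) / sum(gtm | pm)
      total <- total + 1L
      if (iou >= 0.8) hits <- hits + 1L
    }
    # partition property on the used foreground
    fg <- frameData(ws) > 0
    expect_identical(sort(unique(wd[fg])), 1:10)
  }
  expect_gte(hits / total, 0.9)
})

test_that("centre crops have the stated physical size and padding", {
  img <- matrix(runif(10000) * 10, 100, 100)
  f <- Frame(img, pixelSize = 0.69)
  # full-field crop centred at the midpoint reproduces the frame
  whole <- cropCentered(f, c(49, 49), 100 * 0.69)
  expect_equal(dim(frameData(whole)), c(100L, 100L))

  # 27.6 um at 0.69 um/px is a 40 px crop
  crop <- cropCentered(f, c(50, 50), 27.6)
  expect_equal(dim(frameData(crop)), c(40L, 40L))

  # corner crop zero-pads three quadrants
  corner <- cropCentered(f, c(0, 0), 27.6)
  expect_equal(sum(frameData(corner)[1:19, ] != 0), 0L)
  expect_equal(sum(frameData(corner)[, 1:19] != 0), 0L)
  expect_error(cropCentered(f, c(500, 0), 10), "bounds")
})

test_that("detection is pixel-size equivariant", {
  sc <- generateCultureImage(sceneSpec(nIMN = 6, nNonIMN = 0, nDead = 0,
                                       fieldSize = c(220, 220), seed = 8))
  f <- subtractBackground(sc$frames$cytoplasm, 40)
  n1 <- objectCount(detectBlobs(f, detectionParams(sigma = 1)))
  up <- EBImage::resize(frameData(f), w = 2 * nrow(frameData(f)),
                        h = 2 * ncol(frameData(f)))
  f2 <- Frame(pmax(as.matrix(up), 0), pixelSize = pixelSize(f) / 2)
  n2 <- objectCount(detectBlobs(f2, detectionParams(sigma = 1)))
  expect_equal(n1, n2)
})
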