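test_that("culture generator honours counts, determinism and empty case", {
  spec <- sceneSpec(nIMN = 5, nNonIMN = 3, nDead = 2,
                    fieldSize = c(250, 250), seed = 1)
  sc <- generateCultureImage(spec)
  expect_equal(nrow(sc$truth), 10L)
  expect_equal(as.integer(table(sc$truth$class)[c("iMN", "non-iMN",
                                                  "dead")]),
               c(5L, 3L, 2L))
  sc2 <- generateCultureImage(spec)
  for (ch in names(sc$frames))
    expect_identical(frameData(sc$frames[[ch]]),
                     frameData(sc2$frames[[ch]]))

  empty <- generateCultureImage(sceneSpec(nIMN = 0, nNonIMN = 0,
                                          nDead = 0,
                                          fieldSize = c(100, 100)))
  expect_equal(nrow(empty$truth), 0L)
  expect_lt(max(frameData(empty$frames$cytoplasm)), 60)
})

test_that("ground truth closes over rendered objects and placement can fail", {
  sc <- generateCultureImage(sceneSpec(nIMN = 4, nNonIMN = 2, nDead = 2,
                                       fieldSize = c(220, 220), seed = 3))
  # every mask label has exactly one truth row and vice versa
  lab <- frameData(sc$masks$soma)
  expect_setequal(sort(unique(lab[lab > 0])), sc$truth$id)
  expect_equal(anyDuplicated(sc$truth$id), 0L)
  expect_true(all(sc$truth$cy >= 0 & sc$truth$cx >= 0))

  expect_error(generateCultureImage(
    sceneSpec(nIMN = 60, fieldSize = c(60, 60), seed = 1)),
    "overlap bound")
})

test_that("time-lapse follows the imaging schedule with half-open presence", {
  spec <- sceneSpec(nIMN = 0, nNonIMN = 2, nDead = 2,
                    fieldSize = c(250, 250), seed = 4)
  cohort <- cohortSpec(groups = data.frame(name = c("control", "mut"),
                                           logHR = c(0, 0.5),
                                           n = c(4L, 4L)),
                       baselineHazard = 0.05, seed = 2)
  tl <- generateTimelapse(spec, cohort)
  expect_length(tl$stack, 18L)        # D12..D46 every second day
  expect_equal(tl$days, seq(12, 46, 2))

  # a cell that dies on day d is present for day < d only
  for (i in seq_len(nrow(tl$records))) {
    r <- tl$records[i, ]
    present <- tl$tracks$day[tl$tracks$cellId == r$cellId]
    if (r$event == 1) {
      expect_false(r$end %in% present)
      expect_true(all(present < r$end))
      expect_equal(max(present), r$end - 2)
    } else {
      expect_equal(max(present), 46)
    }
    expect_equal(min(present), r$start)
  }

  # zero hazard: every record censored at the final day
  noDeath <- generateTimelapse(spec,
    cohortSpec(groups = data.frame(name = "control", logHR = 0, n = 5L),
               baselineHazard = 0, seed = 2))
  expect_true(all(noDeath$records$event == 0))
  expect_true(all(noDeath$records$end == 46))
})

test_that("kymograph generator encodes motility ground truth", {
  # frame-count rule: floor(duration_s * rate) + 1
  kg <- generateKymoStack(nMito = 5, motileFraction = 0, duration = 10,
                          frameRate = 0.33, seed = 1)
  expect_equal(length(kg$stack), 199L)
  expect_true(all(!kg$truth$motile))
  expect_true(all(kg$truth$totalMovement < 12.5))

  kg2 <- generateKymoStack(nMito = 10, motileFraction = 1,
                           speedRange = c(2, 3), duration = 10, seed = 2)
  expect_true(all(kg2$truth$totalMovement >= 20))
  expect_equal(kg2$truth$anterograde + kg2$truth$retrograde,
               kg2$truth$totalMovement)

  expect_error(generateKymoStack(nMito = 5, motileFraction = 0.5,
                                 speedRange = c(0.1, 0.5), duration = 10),
               "speed range incompatible")
  expect_error(generateKymoStack(motileFraction = 1.5), "motileFraction")
})

test_that("flux plate is exact at zero noise and deterministic", {
  lines <- data.frame(line = "A", basal = 80, maximal = 130,
                      atpLinked = 60, ecar = 30, nonMitoOCR = 20,
                      nonGlycECAR = 10)
  pl <- generateFluxPlate(lines, noiseSigma = 0, seed = 1)
  w <- pl$wells[pl$wells$well == "W001", ]
  expect_equal(unique(w$OCR[w$phase == "baseline"]), 100)
  expect_equal(unique(w$OCR[w$phase == "post-inhibitors"]), 20)
  expect_equal(unique(w$ECAR[w$phase == "post-inhibitors"]), 10)

  pl2 <- generateFluxPlate(lines, noiseSigma = 3, seed = 9)
  pl3 <- generateFluxPlate(lines, noiseSigma = 3, seed = 9)
  expect_identical(pl2$wells, pl3$wells)
  expect_error(generateFluxPlate(lines, cellsPerWell = 0),
               "cell count")
})

test_that("intensity series generators match their construction", {
  ms <- generateIntensitySeries("mitosox", slope = 2, timestep = 10,
                                duration = 180, noiseSigma = 0)
  expect_equal(nrow(ms$series), 19L)
  expect_equal(ms$series$intensity[19] - ms$series$intensity[1], 6)

  pv <- generateIntensitySeries("perceval",
                                phaseRatios = c(1.0, 0.7, 0.4),
                                timestep = 1, duration = 25,
                                noiseSigma = 0)
  r <- pv$series$ch490 / pv$series$ch405
  expect_equal(unique(r[pv$series$time < 5]), 1.0)
  expect_equal(unique(r[pv$series$time >= 5 & pv$series$time < 15]), 0.7)
  expect_equal(unique(r[pv$series$time >= 15]), 0.4)
  expect_error(generateIntensitySeries("perceval", duration = 10),
               "cover all injection")
})

test_that("survival cohort construction matches its exponential law", {
  cohort <- cohortSpec(
    groups = data.frame(name = "control", logHR = 0, n = 1000L),
    baselineHazard = 0.05, entryDays = 12, finalDay = 46, seed = 5)
  rec <- generateSurvivalCohort(cohort)
  expect_true(all(rec$time <= 46 - rec$start))
  expect_true(all(rec$event[rec$end == 46] == 0))
  # exponential-rate MLE within 3 SE of the true hazard
  rate <- sum(rec$event) / sum(rec$time)
  se <- rate / sqrt(sum(rec$event))
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("noise never helps: segmentation F1 is monotone in noise sigma", {
  f1at <- function(noise, seed) {
    sc <- generateCultureImage(sceneSpec(nIMN = 8, nNonIMN = 0,
      nDead = 0, fieldSize = c(220, 220), noiseSigma = noise,
      seed = seed))
    m <- detectBlobs(subtractBackground(sc$frames$cytoplasm, 40),
                     detectionParams(sigma = 1))
    lab <- frameData(m)
    hits <- 0L
    for (i in sc$truth$id) {
      at <- lab[round(sc$truth$cy[i]) + 1, round(sc$truth$cx[i]) + 1]
      if (at > 0) hits <- hits + 1L
    }
    prec <- if (objectCount(m) > 0) hits / objectCount(m) else 0
    rec <- hits / nrow(sc$truth)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  seeds <- 1:10
  f1Low <- mean(vapply(seeds, function(s) f1at(4, s), numeric(1)))
  f1High <- mean(vapply(seeds, function(s) f1at(45, s), numeric(1)))
  expect_gte(f1Low, f1High)
})
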