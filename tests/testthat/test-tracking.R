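test_that("iMN detection is precise, sensitive and deterministic", {
  model <- trainedModel()
  blank <- Frame(matrix(5, 200, 200), channel = "cytoplasm",
                 pixelSize = 0.69)
  expect_equal(nrow(detectImn(blank, model)), 0L)

  sc <- generateCultureImage(sceneSpec(nIMN = 12, nNonIMN = 5, nDead = 0,
                                       fieldSize = c(500, 500),
                                       seed = 31))
  det <- detectImn(sc$frames$cytoplasm, model)
  det2 <- detectImn(sc$frames$cytoplasm, model)
  expect_identical(det, det2)

  truthIMN <- sc$truth[sc$truth$class == "iMN", ]
  gtBoxes <- truthIMN[, c("y0", "x0", "y1", "x1")]
  M <- imnpheno:::iouMatrix(gtBoxes, det[, c("y0", "x0", "y1", "x1")])
  recall <- mean(apply(M, 1, max) >= 0.5)
  precision <- mean(apply(M, 2, max) >= 0.5)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("greedy linking builds the obvious tracks", {
  days <- seq(12, 46, 2)
  one <- data.frame(day = days, y0 = 100, x0 = 100, y1 = 120, x1 = 120,
                    score = 0.9, tile = 1L)
  tr <- linkTracks(one, trackerParams())
  expect_equal(length(unique(tr$trackId)), 1L)
  expect_equal(nrow(tr), 18L)

  two <- rbind(one, transform(one, y0 = 400, y1 = 420))
  tr2 <- linkTracks(two, trackerParams())
  expect_equal(length(unique(tr2$trackId)), 2L)
  # each track keeps one spatial identity throughout
  for (id in unique(tr2$trackId))
    expect_equal(length(unique(tr2$y0[tr2$trackId == id])), 1L)

  expect_error(linkTracks(one, list(iouMin = 2)), "invalid tracker")
})

test_that("greedy association agrees with the brute-force optimum", {
  # small jittered instances solved exactly by permutation enumeration
  withr::with_seed(21, {
    agree <- 0L; total <- 0L
    for (rep in 1:6) {
      n <- 6L
      base <- data.frame(y0 = runif(n, 0, 500), x0 = runif(n, 0, 500))
      base$y1 <- base$y0 + 20; base$x1 <- base$x0 + 20
      jit <- base
      jit$y0 <- jit$y0 + runif(n, -4, 4); jit$y1 <- jit$y0 + 20
      jit$x0 <- jit$x0 + runif(n, -4, 4); jit$x1 <- jit$x0 + 20
      M <- imnpheno:::iouMatrix(base, jit)
      best <- bruteBestAssignment(M, 0.3)
      det <- rbind(cbind(day = 12, base, score = 0.9, tile = 1L),
                   cbind(day = 14, jit, score = 0.9, tile = 1L))
      tr <- linkTracks(det, trackerParams(minLength = 1L))
      links <- tr[order(tr$trackId, tr$day), ]
      for (id in unique(links$trackId)) {
        sub <- links[links$trackId == id, ]
        if (nrow(sub) == 2L) {
          i <- which(base$y0 == sub$y0[1] & base$x0 == sub$x0[1])
          j <- which(jit$y0 == sub$y0[2] & jit$x0 == sub$x0[2])
          total <- total + 1L
          if (any(best$pairs[, 1] == i & best$pairs[, 2] == j))
            agree <- agree + 1L
        }
      }
    }
    expect_gte(agree / total, 0.95)
  })
})

test_that("track merging unions time spans transitively and idempotently", {
  mk <- function(days, id, dir, y = 10) {
    data.frame(trackId = id, day = days, y0 = y, x0 = 10, y1 = y + 20,
               x1 = 30, score = 0.9, tile = 1L, direction = dir)
  }
  fw <- mk(seq(12, 20, 2), 1, "forward")
  bw <- mk(seq(16, 28, 2), 1, "backward")
  mg <- mergeTracks(fw, bw)
  expect_equal(length(unique(mg$trackId)), 1L)
  expect_equal(range(mg$day), c(12, 28))

  # identical forward and backward tracks collapse to one
  expect_equal(length(unique(mergeTracks(fw, fw)$trackId)), 1L)

  # zero temporal overlap: stays two tracks
  mg2 <- mergeTracks(mk(c(12, 14), 1, "forward"),
                     mk(c(20, 22), 1, "backward"))
  expect_equal(length(unique(mg2$trackId)), 2L)

  # merging an already-merged set changes nothing
  mg3 <- mergeTracks(mg)
  expect_equal(mg3[order(mg3$day), c("day", "y0", "x0")],
               mg[order(mg$day), c("day", "y0", "x0")])

  # tile offsets move tracks into the global frame
  lay <- data.frame(tile = 1L, dy = 69, dx = 0)
  mgt <- mergeTracks(fw, tileLayout = lay, pixelSize = 0.69)
  expect_equal(unique(mgt$y0), 10 + 100)
  expect_error(mergeTracks(mk(12, 1, "forward", y = 5),
                           tileLayout = data.frame(tile = 9L, dy = 0,
                                                   dx = 0)),
               "unknown tile")
})

test_that("survival conversion applies the first-missed-timepoint rule", {
  mk <- function(days, id) data.frame(trackId = id, day = days, y0 = 0,
                                      x0 = 0, y1 = 10, x1 = 10,
                                      score = 1)
  # seen D14-D28, step 2: dies at D30
  r <- tracksToSurvival(mk(seq(14, 28, 2), 1), finalDay = 46,
                        interval = 2)
  expect_equal(r$start, 14)
  expect_equal(r$end, 30)
  expect_equal(r$event, 1L)

  # present at the final day: censored there
  r2 <- tracksToSurvival(mk(seq(30, 46, 2), 2), finalDay = 46,
                         interval = 2)
  expect_equal(r2$end, 46)
  expect_equal(r2$event, 0L)

  emptyTracks <- mk(12, 1)[0, ]
  expect_equal(nrow(tracksToSurvival(emptyTracks)), 0L)

  # record validity on a batch of random tracks
  withr::with_seed(3, {
    trs <- do.call(rbind, lapply(1:30, function(id) {
      days <- seq(sample(seq(12, 40, 2), 1), by = 2,
                  length.out = sample(1:10, 1))
      mk(days[days <= 46], id)
    }))
  })
  recs <- tracksToSurvival(trs, finalDay = 46, interval = 2)
  expect_true(all(recs$end >= recs$start))
  expect_true(all(recs$end <= 46))
  lastSeen <- tapply(trs$day, trs$trackId, max)
  seenAtFinal <- names(lastSeen)[lastSeen == 46]
  expect_true(all(recs$event[recs$cellId %in% seenAtFinal] == 0))
})

test_that("MOTA scores its canonical fixtures exactly", {
  gt <- do.call(rbind, lapply(1:10, function(i)
    data.frame(cellId = i, day = 1:10, y0 = i * 50, x0 = i * 50,
               y1 = i * 50 + 20, x1 = i * 50 + 20)))

  # perfect predictions: MOTA 1, all components 0
  perfect <- transform(gt, trackId = cellId)
  m <- mota(perfect, gt, 0.5)
  expect_equal(m$mota, 1)
  expect_equal(m$fn + m$fp + m$idsw, 0L)

  # no predictions: MOTA 0 with FN = number of ground-truth objects
  none <- perfect[0, c("trackId", "day", "y0", "x0", "y1", "x1")]
  m0 <- mota(none, gt, 0.5)
  expect_equal(m0$mota, 0)
  expect_equal(m0$fn, 100L)

  # exactly one identity handover: object 1 is covered by track 1 then
  # track 11; no FP/FN anywhere, so MOTA = 1 - 1/100
  oneSwap <- perfect
  oneSwap$trackId[oneSwap$cellId == 1 & oneSwap$day >= 6] <- 11L
  m1 <- mota(oneSwap, gt, 0.5)
  expect_equal(m1$idsw, 1L)
  expect_equal(m1$mota, 0.99)
  expect_error(mota(perfect, gt, 2), "iouThreshold")
})

test_that("random-search tuning is seeded and prefers working settings", {
  days <- seq(12, 30, 2)
  gt <- do.call(rbind, lapply(1:5, function(i)
    data.frame(cellId = i, day = days, y0 = i * 60, x0 = i * 60,
               y1 = i * 60 + 20, x1 = i * 60 + 20)))
  withr::with_seed(4, {
    det <- do.call(rbind, lapply(1:5, function(i)
      data.frame(day = days, y0 = i * 60 + runif(10, -2, 2),
                 x0 = i * 60 + runif(10, -2, 2), score = 0.9,
                 tile = 1L)))
  })
  det$y1 <- det$y0 + 20; det$x1 <- det$x0 + 20
  movie <- list(detections = det, gt = gt)

  single <- tuneTracker(list(iouMin = 0.3), list(movie), budget = 1,
                        seed = 1)
  expect_equal(single$iouMin, 0.3)

  # a degenerate association gate loses to a sane one
  best <- tuneTracker(list(iouMin = c(0.2, 0.99)), list(movie),
                      budget = 12, seed = 2)
  best2 <- tuneTracker(list(iouMin = c(0.2, 0.99)), list(movie),
                       budget = 12, seed = 2)
  expect_identical(attr(best, "log"), attr(best2, "log"))
  expect_lt(best$iouMin, 0.9)
  log <- attr(best, "log")
  expect_gte(max(log$meanMOTA), log$meanMOTA[which.max(log$iouMin)])
  expect_error(tuneTracker(list(), list(movie)), "empty")
})

test_that("per-group subsampling honours n, seeds and undersized groups", {
  rec <- generateSurvivalCohort(cohortSpec(
    groups = data.frame(name = c("control", "mut"), logHR = c(0, 0.7),
                        n = c(700L, 300L)), seed = 6))
  sub <- sampleCells(rec, n = 500, seed = 1)
  expect_equal(sum(sub$group == "control"), 500L)
  expect_equal(sum(sub$group == "mut"), 300L)
  expect_equal(attr(sub, "undersized"), "mut")

  sub2 <- sampleCells(rec, n = 500, seed = 1)
  expect_identical(sub$cellId, sub2$cellId)
  sub3 <- sampleCells(rec, n = 500, seed = 2)
  expect_false(identical(sort(sub$cellId[sub$group == "control"]),
                         sort(sub3$cellId[sub3$group == "control"])))
})
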