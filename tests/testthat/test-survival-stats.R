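test_that("Kaplan-Meier reproduces hand product-limit values", {
  km <- kaplanMeier(data.frame(time = c(2, 4, 6), event = 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$time, c(2, 4, 6))

  # censoring shrinks the risk set without a step
  km2 <- kaplanMeier(data.frame(time = c(2, 3, 4), event = c(1, 0, 1)))
  expect_equal(km2$surv, c(2 / 3, 0))
  expect_equal(km2$nRisk, c(3, 1))

  # no events: S(t) = 1 throughout
  km3 <- kaplanMeier(data.frame(time = c(5, 8), event = 0))
  expect_true(all(km3$surv == 1) || nrow(km3) == 0L)

  expect_error(kaplanMeier(data.frame(time = -1, event = 1)), "negative")
})

test_that("KM equals the empirical survival when nothing is censored", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      t <- round(rexp(40, 0.1), 1)
      km <- kaplanMeier(data.frame(time = t, event = 1))
      emp <- vapply(km$time, function(u) mean(t > u), numeric(1))
      expect_equal(km$surv, emp)
    }
  })
})

test_that("pairwise logrank matches the observed-minus-expected oracle", {
  # identical groups: statistic 0, p 1
  a <- data.frame(time = c(3, 5, 7), event = 1, group = "A")
  b <- transform(a, group = "B")
  same <- pairwiseLogrank(rbind(a, b))
  expect_equal(same$chisq, 0, tolerance = 1e-9)
  expect_equal(same$p, 1, tolerance = 1e-9)

  # two-group toy vs the hand 2x2-table computation
  toy <- data.frame(time = c(1, 2, 3, 4), event = 1,
                    group = c("A", "A", "B", "B"))
  lr <- pairwiseLogrank(toy)
  # event times 1,2,3,4; O_A = 2; E_A = 2/4 + 1/3 + 0 + 0; V summed
  # V_t = d(n-d) nA nB / (n^2 (n-1)) summed over event times
  eA <- 2 / 4 + 1 / 3
  vA <- (1 * 3 * 2 * 2) / (16 * 3) + (1 * 2 * 1 * 2) / (9 * 2)
  expect_equal(lr$chisq, (2 - eA)^2 / vA, tolerance = 1e-6)

  expect_error(pairwiseLogrank(a), "2 groups")

  # invariance under a common monotone transform of all times
  withr::with_seed(17, {
    rec <- data.frame(time = rexp(60, 0.1) + 0.1,
                      event = rbinom(60, 1, 0.8),
                      group = rep(c("A", "B"), 30))
  })
  l1 <- pairwiseLogrank(rec)
  rec2 <- rec; rec2$time <- log1p(rec$time)
  l2 <- pairwiseLogrank(rec2)
  expect_equal(l1$chisq, l2$chisq, tolerance = 1e-9)
})

test_that("Cox fits match a directly maximised partial likelihood", {
  # symmetric groups: log HR 0
  a <- data.frame(time = c(3, 5, 7, 9), event = 1, group = "A")
  sym <- rbind(a, transform(a, group = "B"))
  f <- coxPH(sym, reference = "A")
  expect_lt(abs(f$logHR), 1e-6)

  # 4-subject alternating case: maximise the Breslow partial likelihood
  # by brute force and compare
  rec <- data.frame(time = 1:4, event = 1,
                    group = c("B", "A", "B", "A"))
  negpl <- function(b) {
    # risk sets at t=1..4 (group B coded x=1)
    x <- c(1, 0, 1, 0)
    val <- 0
    for (i in 1:4) {
      atRisk <- i:4
      val <- val + x[i] * b - log(sum(exp(b * x[atRisk])))
    }
    -val
  }
  bhat <- stats::optimize(negpl, c(-5, 5))$minimum
  fit <- coxPH(rec, reference = "A")
  expect_equal(fit$logHR, bhat, tolerance = 1e-4)
  expect_equal(fit$ciLow, fit$logHR - 1.96 * fit$se)
  expect_equal(fit$ciHigh, fit$logHR + 1.96 * fit$se)

  # reference relabelling flips the sign of the log hazard ratio
  flip <- coxPH(rec, reference = "B")
  expect_equal(flip$logHR, -fit$logHR, tolerance = 1e-6)

  expect_error(coxPH(data.frame(time = 1:3, event = 0, group = "A")),
               "1 event")
})

test_that("Cox CI width shrinks like 1/sqrt(n)", {
  widths <- vapply(c(125L, 500L, 2000L), function(n) {
    rec <- generateSurvivalCohort(cohortSpec(
      groups = data.frame(name = c("control", "mut"),
                          logHR = c(0, 0.693), n = c(n, n)),
      seed = 40 + n))
    f <- coxPH(rec, reference = "control")
    f$ciHigh - f$ciLow
  }, numeric(1))
  slope <- coef(lm(log(widths) ~ log(c(125, 500, 2000))))[2]
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("Dunnett comparisons reduce to a t-test at two groups", {
  withr::with_seed(19, {
    v <- c(rnorm(30), rnorm(30, 0.8))
  })
  g <- rep(c("control", "mut"), each = 30)
  ad <- anovaDunnett(v, g, "control", seed = 2)
  tt <- t.test(v[g == "mut"], v[g == "control"], var.equal = TRUE)
  expect_lt(abs(ad$comparisons$pAdj - tt$p.value), 0.005)
  expect_equal(ad$comparisons$estimate,
               mean(v[g == "mut"]) - mean(v[g == "control"]),
               tolerance = 1e-9)

  # a 2-SD shift at n = 100/group is overwhelmingly significant
  withr::with_seed(23, {
    v2 <- c(rnorm(100, 0, 1), rnorm(100, 2, 1), rnorm(100, 0, 1))
  })
  g2 <- rep(c("control", "shifted", "null"), each = 100)
  ad2 <- anovaDunnett(v2, g2, "control", seed = 3)
  pShift <- ad2$comparisons$pAdj[ad2$comparisons$group == "shifted"]
  expect_lt(pShift, 0.001)
  expect_gt(ad2$F, 10)

  expect_error(anovaDunnett(v, g, "absent"), "not present")
  expect_error(anovaDunnett(c(1, 2, 3), c("a", "a", "b"), "a"),
               "n >= 2")
})

test_that("Dunnett-adjusted tests hold their size under the null", {
  withr::with_seed(29, {
    rejections <- vapply(1:400, function(i) {
      v <- rnorm(60)
      g <- rep(c("control", "m1", "m2"), each = 20)
      ad <- anovaDunnett(v, g, "control", seed = i)
      any(ad$comparisons$pAdj < 0.05)
    }, logical(1))
  })
  # familywise rejection rate about alpha (allowing Monte-Carlo spread)
  expect_lte(mean(rejections), 0.08)
  expect_gte(mean(rejections), 0.02)
})
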