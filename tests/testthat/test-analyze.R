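test_that("heatmap aggregation over (group, correctness) cells", {
  H <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
  # identical heatmaps, all correct
  rel <- relevanceSetFromArray(array(rep(H, 3), c(2, 2, 2, 3)),
                               labels = rep("patient", 3))
  a <- aggregateHeatmaps(rel, predicted = c(1, 1, 1), "patient", TRUE)
  expect_equal(a$n, 3L)
  expect_equal(a$mean, H)

  # H and -H average to zero
  rel2 <- relevanceSetFromArray(array(c(H, -H), c(2, 2, 2, 2)),
                                labels = rep("patient", 2))
  a2 <- aggregateHeatmaps(rel2, c(1, 1), "patient", TRUE)
  expect_equal(max(abs(a2$mean)), 0)

  # mixed 6-sample fixture: cell means equal hand-computed averages
  set.seed(4)
  vals <- array(rnorm(2 * 2 * 2 * 6), c(2, 2, 2, 6))
  labs <- c("patient", "patient", "patient", "control", "control",
            "patient")
  pred <- c(1, 0, 1, 0, 1, 0)    # correct: 1,4 (and 3); wrong: 2,5,6
  rel6 <- relevanceSetFromArray(vals, labels = labs)
  y <- as.integer(labs == "patient")
  for (grp in c("patient", "control")) for (cc in c(TRUE, FALSE)) {
    sel <- which(labs == grp & ((pred == y) == cc))
    a <- aggregateHeatmaps(rel6, pred, grp, cc)
    expect_equal(a$n, length(sel))
    if (length(sel)) {
      manual <- apply(vals[, , , sel, drop = FALSE], 1:3, mean)
      expect_equal(a$mean, manual, tolerance = 1e-12)
    } else expect_null(a$mean)
  }

  # empty cell is missing, not zero
  a0 <- aggregateHeatmaps(rel, c(0, 0, 0), "patient", TRUE)
  expect_null(a0$mean)
  expect_equal(a0$n, 0L)
})

test_that("ROI time course peaks at the right bin; ties go earliest", {
  windows <- cbind(start = seq(0, 750, 50), end = seq(50, 800, 50))
  agg <- array(0, c(4, 4, 16))
  mask <- matrix(FALSE, 4, 4); mask[2:3, 2:3] <- TRUE
  agg[2, 2, 7] <- 5   # only bin 7 (300-350 ms)
  tc <- roiTimeCourse(agg, mask, windows)
  expect_equal(tc$peakBin, 7L)
  expect_equal(unname(tc$peakWindow), c(300, 350))

  uni <- array(1, c(4, 4, 16))
  tcu <- roiTimeCourse(uni, mask, windows)
  expect_equal(tcu$peakBin, 1L)

  expect_error(roiTimeCourse(agg, matrix(FALSE, 4, 4), windows), "empty")
})

test_that("localization score: extremes, chance level, SNR monotonicity", {
  mask <- array(FALSE, c(6, 6, 4))
  mask[2:4, 2:4, 2] <- TRUE

  expect_equal(localizationScore(mask * 1, mask), 1)

  set.seed(7)
  aucs <- replicate(40, localizationScore(array(rnorm(144), c(6, 6, 4)),
                                          mask))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)

  snrs <- c(0.25, 1, 4)
  set.seed(8)
  noise <- array(rnorm(144), c(6, 6, 4))
  got <- sapply(snrs, function(s)
    localizationScore(mask * s + noise, mask))
  expect_true(all(diff(got) > 0))
  expect_true(all(got > min(aucs) & got[3] > 0.9))

  expect_error(localizationScore(noise, array(TRUE, c(6, 6, 4))),
               "degenerate")
})

test_that("Cohen's d reproduces published group summaries", {
  # demographics/questionnaire rows (control vs patient, n = 49 each)
  expect_equal(round(cohenD(4.94, 3.36, 49, 47.53, 19.46, 49), 2), 3.05)
  expect_equal(round(cohenD(28.88, 1.29, 49, 27.27, 2.14, 49), 2), -0.91)
  expect_equal(round(cohenD(66.00, 6.37, 49, 65.96, 5.94, 49), 2), -0.01)
  expect_equal(cohenD(10, 2, 30, 10, 2, 30), 0)
  expect_true(is.na(cohenD(1, 0, 10, 1, 0, 10)))
})

test_that("summary t test agrees with t.test on raw data", {
  tt <- summaryTTest(66.00, 6.37, 49, 65.96, 5.94, 49)
  expect_equal(round(tt$p, 3), 0.974)
  expect_equal(summaryTTest(5, 1, 10, 5, 1, 10)$t, 0)
  expect_equal(summaryTTest(5, 0, 10, 5, 0, 10)$p, 1)

  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(12, 0, 1.3); y <- rnorm(17, 0.4, 1.1)
    ref <- t.test(y, x, var.equal = TRUE)
    got <- summaryTTest(mean(x), sd(x), 12, mean(y), sd(y), 17)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Fisher's exact p agrees with hypergeometric enumeration", {
  enumFisher <- function(m) {
    r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
    ks <- max(0, r1 + c1 - n):min(r1, c1)
    probs <- dhyper(ks, c1, n - c1, r1)
    pObs <- dhyper(m[1, 1], c1, n - c1, r1)
    sum(probs[probs <= pObs * (1 + 1e-7)])
  }
  m <- matrix(c(33, 29, 16, 20), 2)
  expect_equal(fisherExactTest(m), enumFisher(m), tolerance = 1e-9)
  # published value 0.529; the exact point-probability p is 0.52997
  expect_equal(fisherExactTest(m), 0.529, tolerance = 3e-3)
  set.seed(21)
  for (rep in 1:5) {
    m <- matrix(rpois(4, 12), 2)
    expect_equal(fisherExactTest(m), enumFisher(m), tolerance = 1e-9)
  }
})

test_that("one-tailed Pearson correlation and its t-based p value", {
  x <- 1:20
  r1 <- pearsonOneTailed(x, x + 0, "positive")
  expect_equal(r1$rho, 1)
  expect_lt(r1$p, 1e-12)
  r2 <- pearsonOneTailed(x, -x, "positive")
  expect_equal(r2$rho, -1)
  expect_gt(r2$p, 1 - 1e-12)

  # n = 98 with sample correlation ~0.26 is significant at the 0.01 level
  set.seed(31)
  repeat {
    a <- rnorm(98); b <- 0.26 * a + sqrt(1 - 0.26^2) * rnorm(98)
    if (abs(cor(a, b) - 0.26) < 0.02) break
  }
  got <- pearsonOneTailed(a, b, "positive")
  rho <- got$rho
  tOracle <- rho * sqrt((98 - 2) / (1 - rho^2))
  expect_equal(got$p, pt(tOracle, 96, lower.tail = FALSE), tolerance = 1e-9)
  expect_lt(got$p, 0.01)

  expect_true(is.na(pearsonOneTailed(rep(1, 5), rnorm(5))$rho))
})

test_that("ROI current density: constants, planted ordering", {
  surf <- tinySurface()
  # near-constant source: one component with a very wide envelope
  specC <- effectSpec(delta = 1, noiseSd = 0, subjectSd = 0, trialSd = 0,
                      components = data.frame(region = 2L, latencyMs = 0,
                                              widthMs = 1e6,
                                              amplitude = 3.5))
  cohC <- simulateCohort(surf, specC, 2, 2, fsHz = 100, seed = 2)
  v <- roiMeanCurrentDensity(cohC, 2, c(300, 350), preprocess = FALSE)
  expect_equal(unname(v), rep(3.5, 4), tolerance = 1e-6)

  coh <- tinyCohort()   # delta = 0.5
  vals <- roiMeanCurrentDensity(coh, 2, c(300, 350), preprocess = FALSE)
  grp <- cohortMeta(coh)$group
  expect_lt(mean(vals[grp == "patient"]), mean(vals[grp == "control"]))

  expect_error(roiMeanCurrentDensity(coh, 99, c(300, 350)), "unknown")
})

test_that("group statistics table mirrors its underlying tests", {
  meta <- data.frame(group = rep(c("control", "patient"), each = 6),
                     s = c(rnorm(6, 10), rnorm(6, 8)))
  tab <- groupStatsTable(meta, "s")
  expect_equal(tab$cohenD,
               cohenD(tab$controlMean, tab$controlSd, 6,
                      tab$patientMean, tab$patientSd, 6))
  ref <- t.test(meta$s[7:12], meta$s[1:6], var.equal = TRUE)
  expect_equal(tab$p, ref$p.value, tolerance = 1e-9)
})
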