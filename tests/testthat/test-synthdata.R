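test_that("sphere surface construction: unit norms, regions, determinism", {
  s1 <- makeSphereSurface(1, 1, seed = 0)
  expect_equal(nVertices(s1), 1L)
  expect_equal(sqrt(sum(vertexCoords(s1)^2)), 1, tolerance = 1e-12)
  expect_equal(regionLabels(s1), 1L)

  s <- makeSphereSurface(2000, 8, seed = 7)
  expect_true(all(abs(sqrt(rowSums(vertexCoords(s)^2)) - 1) <= 1e-9))
  expect_setequal(unique(regionLabels(s)), 1:8)

  s2 <- makeSphereSurface(2000, 8, seed = 7)
  expect_identical(vertexCoords(s), vertexCoords(s2))
  expect_identical(regionLabels(s), regionLabels(s2))

  expect_error(makeSphereSurface(0, 1), "positive")
  expect_error(makeSphereSurface(4, 0), "positive")
  expect_error(makeSphereSurface(4, 8), ">=")
})

test_that("Fibonacci lattice is near-uniform (nearest-neighbour spacing)", {
  s <- makeSphereSurface(2000, 8, seed = 7)
  v <- vertexCoords(s)
  # nearest-neighbour distance per vertex, computed directly
  nn <- numeric(nrow(v))
  for (i in seq_len(nrow(v))) {
    d2 <- colSums((t(v) - v[i, ])^2)
    nn[i] <- sqrt(min(d2[-i]))
  }
  cv <- sd(nn) / mean(nn)
  expect_lt(cv, 0.5)
})

test_that("lead field: geometry, determinism, channel-site dominance", {
  surf <- makeSphereSurface(100, 4, seed = 1)
  lf <- makeLeadField(surf, 16, seed = 1)
  expect_equal(dim(gainMatrix(lf)), c(16L, 100L))
  expect_true(all(is.finite(gainMatrix(lf))))

  lf2 <- makeLeadField(surf, 16, seed = 1)
  expect_identical(gainMatrix(lf), gainMatrix(lf2))

  # the channel whose site is closest to a vertex has the maximal gain in
  # that vertex's column (sensitivity decays with angular distance)
  dots <- channelSites(lf) %*% t(vertexCoords(surf))
  for (j in c(1, 25, 50, 100))
    expect_equal(which.max(gainMatrix(lf)[, j]), which.max(dots[, j]))

  expect_error(makeLeadField(surf, 1), ">= 2")
})

test_that("cohorts are bit-identical given the seed", {
  surf <- tinySurface()
  c1 <- simulateCohort(surf, effectSpec(delta = 0.7), 2, 3, fsHz = 100,
                       seed = 5)
  c2 <- simulateCohort(surf, effectSpec(delta = 0.7), 2, 3, fsHz = 100,
                       seed = 5)
  expect_identical(cohortMeta(c1), cohortMeta(c2))
  expect_identical(trialData(subjectTrials(c1, "pat01")),
                   trialData(subjectTrials(c2, "pat01")))
})

test_that("no planted effect (delta = 1) leaves groups indistinguishable", {
  surf <- tinySurface()
  spec <- effectSpec(delta = 1)
  sig <- 0L
  for (rep in 1:20) {
    coh <- simulateCohort(surf, spec, nPerGroup = 4, nTrials = 6,
                          fsHz = 100, seed = 100 + rep)
    v <- roiMeanCurrentDensity(coh, 2, c(300, 350), preprocess = FALSE)
    grp <- cohortMeta(coh)$group
    p <- t.test(v[grp == "control"], v[grp == "patient"])$p.value
    if (p < 0.05) sig <- sig + 1L
  }
  expect_lte(sig, 2L)  # non-significant in >= 90% of replicates
})

test_that("noiseless limit recovers the planted attenuation exactly", {
  surf <- tinySurface()
  spec <- effectSpec(delta = 0.5, noiseSd = 0, subjectSd = 0, trialSd = 0)
  coh <- simulateCohort(surf, spec, nPerGroup = 2, nTrials = 2, fsHz = 100,
                        seed = 1)
  v <- roiMeanCurrentDensity(coh, 2, c(300, 350), preprocess = FALSE)
  grp <- cohortMeta(coh)$group
  ratio <- mean(v[grp == "patient"]) / mean(v[grp == "control"])
  expect_equal(ratio, 0.5, tolerance = 0.01)
})

test_that("planted effect size matches the closed-form prediction", {
  surf <- makeSphereSurface(500, 8, seed = 3)
  delta <- 0.6
  spec <- effectSpec(delta = delta)
  coh <- simulateCohort(surf, spec, nPerGroup = 10, nTrials = 20,
                        fsHz = 100, seed = 42)
  v <- roiMeanCurrentDensity(coh, 2, c(300, 350), preprocess = FALSE)
  grp <- cohortMeta(coh)$group
  g1 <- v[grp == "control"]; g2 <- v[grp == "patient"]
  dEmp <- cohenD(mean(g1), sd(g1), length(g1), mean(g2), sd(g2), length(g2))
  # ROI/window mean is a_s * k (control) vs delta * a_s * k (patient) plus
  # a negligible noise term, so |d| ~ (1-delta) / (sd_s * sqrt((1+delta^2)/2))
  dPred <- (1 - delta) / (spec@subjectSd * sqrt((1 + delta^2) / 2))
  expect_lt(abs(abs(dEmp) - dPred) / dPred, 0.30)
})

test_that("stronger attenuation does not weaken the group effect", {
  surf <- tinySurface()
  ds <- sapply(c(1.0, 0.8, 0.6, 0.4), function(delta) {
    coh <- simulateCohort(surf, effectSpec(delta = delta), nPerGroup = 6,
                          nTrials = 8, fsHz = 100, seed = 77)
    v <- roiMeanCurrentDensity(coh, 2, c(300, 350), preprocess = FALSE)
    grp <- cohortMeta(coh)$group
    g1 <- v[grp == "control"]; g2 <- v[grp == "patient"]
    abs(cohenD(mean(g1), sd(g1), length(g1),
               mean(g2), sd(g2), length(g2)))
  })
  expect_true(all(diff(ds) >= -1e-8))
})

test_that("clinical scores hit the target correlation with ground truth", {
  surf <- makeSphereSurface(100, 4, seed = 2)
  spec <- effectSpec()
  coh <- simulateCohort(surf, spec, nPerGroup = 49, nTrials = 1, seed = 9)

  c0 <- simulateClinicalScores(coh, 0, "s0", 10, 2, seed = 31)
  r0 <- cor(cohortMeta(c0)$s0, cohortMeta(c0)$aS)
  expect_lt(abs(r0), 3 / sqrt(98))

  c1 <- simulateClinicalScores(coh, 1, "s1", 10, 2, seed = 32)
  expect_equal(cor(cohortMeta(c1)$s1, cohortMeta(c1)$aS), 1,
               tolerance = 1e-9)

  # rho = 0.26 with n = 98: recovered correlation stays inside the
  # Fisher-z 95% band around the target in >= 90% of replicates
  lo <- tanh(atanh(0.26) - 1.96 / sqrt(95))
  hi <- tanh(atanh(0.26) + 1.96 / sqrt(95))
  inBand <- 0L
  for (rep in 1:20) {
    cc <- simulateClinicalScores(coh, 0.26, "s", 10, 2, seed = 200 + rep)
    r <- cor(cohortMeta(cc)$s, cohortMeta(cc)$aS)
    if (r >= lo && r <= hi) inBand <- inBand + 1L
  }
  expect_gte(inBand, 18L)

  expect_error(simulateClinicalScores(coh, 1.2, "x"), "rhoTarget")
})

test_that("trial preprocessing: baseline removal and filter contracts", {
  fs <- 400
  nt <- round(2000 / 1000 * fs)
  tms <- -1200 + (seq_len(nt) - 1) * 1000 / fs

  # constants vanish entirely
  const <- matrix(5, 3, nt)
  expect_equal(max(abs(preprocessTrial(const, fs, -1200))), 0,
               tolerance = 1e-9)

  # baseline window mean is exactly zero afterwards
  x <- matrix(rnorm(2 * nt), 2, nt)
  y <- preprocessTrial(x, fs, -1200)
  base <- tms >= -200 & tms < 0
  expect_equal(max(abs(rowMeans(y[, base]))), 0, tolerance = 1e-9)

  # 50 Hz is in the stopband, 5 Hz in the passband
  s50 <- matrix(sin(2 * pi * 50 * (tms / 1000)), 1)
  out50 <- preprocessTrial(s50, fs, -1200)
  expect_lt(sqrt(mean(out50^2)) / sqrt(mean(s50^2)), 0.05)

  s5 <- matrix(sin(2 * pi * 5 * (tms / 1000)), 1)
  out5 <- preprocessTrial(s5, fs, -1200)
  ref <- s5 - rowMeans(s5[, base, drop = FALSE])
  expect_lt(abs(sqrt(mean(out5^2)) - sqrt(mean(ref^2))) / sqrt(mean(ref^2)),
            0.05)

  # missing baseline window is a precondition error
  expect_error(preprocessTrial(matrix(0, 1, 80), fsHz = 100, tStartMs = 0),
               "baseline")
})
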