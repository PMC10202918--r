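#' Define the evoked components and the planted group effect
#'
#' The synthetic cohort's trials are built as spatially correlated Gaussian
#' background noise plus Gaussian-envelope evoked components confined to
#' surface regions (the defaults mirror an early visual component at ~200 ms
#' and a later parietal/attention component at ~325 ms). In the patient
#' group, every component whose region equals `roiRegion` has its amplitude
#' multiplied by `delta`; `delta = 1` plants no group difference.
#'
#' @param roiRegion region id carrying the planted effect.
#' @param windowMs planted latency window (ms), must lie inside the epoch.
#' @param delta patient-group amplitude multiplier in \[0, 1\].
#' @param components data.frame with columns `region`, `latencyMs`,
#'   `widthMs` (Gaussian SD, ms), `amplitude` (a.u.).
#' @param noiseSd per-vertex SD of the background noise (a.u.).
#' @param subjectSd SD of the per-subject amplitude factor `aS` around 1.
#' @param trialSd SD of the per-trial multiplicative amplitude jitter.
#' @param noiseKnn neighbourhood size of the spatial noise smoother.
#' @return an [EffectSpec-class].
#' @export
effectSpec <- function(roiRegion = 2L, windowMs = c(300, 350), delta = 1,
                       components = data.frame(
                         region = c(1L, 2L),
                         latencyMs = c(200, 325),
                         widthMs = c(25, 25),
                         amplitude = c(1, 1)),
                       noiseSd = 0.5, subjectSd = 0.2, trialSd = 0.1,
                       noiseKnn = 12L) {
  stopIfNot(length(delta) == 1 && delta >= 0 && delta <= 1,
            "delta must be in [0, 1]")
  new("EffectSpec", roiRegion = as.integer(roiRegion),
      windowMs = as.numeric(windowMs), delta = as.numeric(delta),
      components = components, noiseSd = as.numeric(noiseSd),
      subjectSd = as.numeric(subjectSd), trialSd = as.numeric(trialSd),
      noiseKnn = as.integer(noiseKnn))
}

# Sparse spatial smoothing operator: Gaussian weights over the k nearest
# vertices, rows scaled to unit L2 norm so that smoothing white noise leaves
# the per-vertex standard deviation unchanged.
makeNoiseSmoother <- function(surface, k) {
  v <- vertexCoords(surface)
  n <- nrow(v)
  k <- min(k, n)
  nn <- knnIndex(v, v, k)
  d <- matrix(0, n, k)
  for (j in seq_len(k))
    d[, j] <- sqrt(rowSums((v - v[nn[, j], , drop = FALSE])^2))
  ell <- stats::median(d[, k]) / 2 + 1e-12
  w <- exp(-d^2 / (2 * ell^2))
  w <- w / sqrt(rowSums(w^2))
  Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                       x = as.vector(w), dims = c(n, n))
}

#' Simulate a two-group cohort of trial-wise source activity
#'
#' Generates per-subject metadata (group, ground-truth amplitude factor
#' `aS ~ N(1, subjectSd^2)`) and defines per-trial source current-density
#' time series on the surface: spatially correlated Gaussian background
#' noise plus the evoked components of `spec`, with the patient-group
#' attenuation applied to the planted component. Trials are materialized on
#' demand by [subjectTrials()] (or streamed by [cohortVolumes()] and
#' [roiMeanCurrentDensity()]) from per-trial seeds, so identical seeds give
#' bit-identical cohorts at any scale.
#'
#' @param surface a [SurfaceGeometry-class].
#' @param spec an [EffectSpec-class].
#' @param nPerGroup subjects per group (default desk scale 10; the emulated
#'   full-scale design is 49 + 49).
#' @param nTrials trials per subject (default desk scale 40; full scale 500).
#' @param fsHz sampling rate (Hz), default 400.
#' @param tStartMs,tEndMs epoch bounds (ms) relative to target onset,
#'   default -1200 to 800.
#' @param seed integer cohort seed.
#' @return a [SourceCohort-class].
#' @examples
#' surf <- makeSphereSurface(300, 4, seed = 1)
#' coh <- simulateCohort(surf, effectSpec(delta = 0.5), nPerGroup = 2,
#'                       nTrials = 3, fsHz = 100, seed = 7)
#' cohortMeta(coh)
#' @export
simulateCohort <- function(surface, spec, nPerGroup = 10L, nTrials = 40L,
                           fsHz = 400, tStartMs = -1200, tEndMs = 800,
                           seed = 1L) {
  stopIfNot(is(surface, "SurfaceGeometry"), "surface must be a SurfaceGeometry")
  stopIfNot(is(spec, "EffectSpec"), "spec must be an EffectSpec")
  validObject(spec)
  stopIfNot(nPerGroup >= 1 && nTrials >= 1,
            "nPerGroup and nTrials must be >= 1")
  stopIfNot(spec@windowMs[1] >= tStartMs && spec@windowMs[2] <= tEndMs,
            "planted window must lie inside the epoch")
  stopIfNot(all(spec@components$region %in% regionLabels(surface)),
            "component regions must exist on the surface")
  ids <- c(sprintf("ctrl%02d", seq_len(nPerGroup)),
           sprintf("pat%02d", seq_len(nPerGroup)))
  grp <- rep(c("control", "patient"), each = nPerGroup)
  aS <- withSeed(seed, 1 + spec@subjectSd * stats::rnorm(2 * nPerGroup))
  meta <- data.frame(subjectId = ids, group = grp, aS = aS,
                     nTrials = as.integer(nTrials),
                     stringsAsFactors = FALSE)
  new("SourceCohort", surface = surface, meta = meta, spec = spec,
      fsHz = as.numeric(fsHz), tStartMs = as.numeric(tStartMs),
      tEndMs = as.numeric(tEndMs), seed = as.integer(seed),
      smoother = makeNoiseSmoother(surface, spec@noiseKnn))
}

# One trial's vertices x time current-density matrix.
simTrialMatrix <- function(cohort, subjIdx, trialIdx) {
  spec <- cohort@spec
  surf <- cohort@surface
  n <- nVertices(surf)
  tms <- epochTimesMs(cohort@tStartMs, cohort@tEndMs, cohort@fsHz)
  nt <- length(tms)
  comps <- spec@components
  row <- cohort@meta[subjIdx, ]
  withSeed(trialSeed(cohort@seed, subjIdx, trialIdx), {
    jit <- stats::rnorm(nrow(comps))
    E <- if (spec@noiseSd > 0) {
      spec@noiseSd * as.matrix(cohort@smoother %*%
                                 matrix(stats::rnorm(n * nt), n, nt))
    } else matrix(0, n, nt)
    for (ci in seq_len(nrow(comps))) {
      amp <- row$aS * comps$amplitude[ci] * (1 + spec@trialSd * jit[ci])
      if (row$group == "patient" && comps$region[ci] == spec@roiRegion)
        amp <- amp * spec@delta
      env <- exp(-(tms - comps$latencyMs[ci])^2 / (2 * comps$widthMs[ci]^2))
      idx <- which(regionLabels(surf) == comps$region[ci])
      E[idx, ] <- E[idx, ] + amp * rep(env, each = length(idx))
    }
    E
  })
}

#' Materialize one subject's trials
#'
#' @param cohort a [SourceCohort-class].
#' @param subjectId a subject id present in `cohortMeta(cohort)`.
#' @return a [SourceTrialSet-class] (trials x vertices x time).
#' @export
subjectTrials <- function(cohort, subjectId) {
  si <- match(subjectId, cohort@meta$subjectId)
  stopIfNot(!is.na(si), sprintf("unknown subject '%s'", subjectId))
  nT <- cohort@meta$nTrials[si]
  n <- nVertices(cohort@surface)
  nt <- length(epochTimesMs(cohort@tStartMs, cohort@tEndMs, cohort@fsHz))
  dat <- array(0, c(nT, n, nt))
  for (tr in seq_len(nT))
    dat[tr, , ] <- simTrialMatrix(cohort, si, tr)
  new("SourceTrialSet", data = dat, tStartMs = cohort@tStartMs,
      tEndMs = cohort@tEndMs, fsHz = cohort@fsHz,
      subjectId = as.character(subjectId),
      group = cohort@meta$group[si])
}

#' Attach a simulated clinical score to the cohort table
#'
#' Builds a score as a linear transform of the ground-truth subject
#' amplitude `aS` plus Gaussian noise, tuned so the population correlation
#' between score and `aS` equals `rhoTarget`:
#' `score = mean + sd * (rho * (aS - 1)/subjectSd + sqrt(1 - rho^2) * e)`.
#' The sample correlation converges to `rhoTarget` as the cohort grows.
#'
#' @param cohort a [SourceCohort-class].
#' @param rhoTarget target population correlation in \[-1, 1\].
#' @param scoreName column name for the new score.
#' @param scoreMean,scoreSd score location and scale.
#' @param seed integer seed for the score noise.
#' @return the cohort with the score column added to its metadata table.
#' @export
simulateClinicalScores <- function(cohort, rhoTarget, scoreName = "MMSE",
                                   scoreMean = 27, scoreSd = 2,
                                   seed = 1L) {
  stopIfNot(abs(rhoTarget) <= 1, "|rhoTarget| must be <= 1")
  z <- (cohort@meta$aS - 1) / cohort@spec@subjectSd
  e <- withSeed(seed, stats::rnorm(nrow(cohort@meta)))
  cohort@meta[[scoreName]] <-
    scoreMean + scoreSd * (rhoTarget * z + sqrt(1 - rhoTarget^2) * e)
  cohort
}

#' Lowpass filter and baseline-correct one trial
#'
#' Applies a zero-phase (forward-backward) Butterworth lowpass below
#' `cutoffHz` to each vertex's time series, then subtracts the per-vertex
#' mean over the -200 to 0 ms baseline window, so the baseline mean is
#' exactly zero afterwards.
#'
#' @param trial numeric vertices x time matrix.
#' @param fsHz sampling rate (Hz).
#' @param tStartMs epoch start (ms); the epoch must cover -200..0 ms.
#' @param cutoffHz lowpass cutoff (default 30 Hz).
#' @param order Butterworth order (default 4; applied twice by the
#'   forward-backward pass).
#' @return a matrix of the same shape.
#' @examples
#' tr <- matrix(rnorm(5 * 160), 5, 160)
#' out <- preprocessTrial(tr, fsHz = 100, tStartMs = -1200)
#' @export
preprocessTrial <- function(trial, fsHz, tStartMs, cutoffHz = 30, order = 4) {
  stopIfNot(is.matrix(trial), "trial must be a vertices x time matrix")
  tms <- tStartMs + (seq_len(ncol(trial)) - 1) * 1000 / fsHz
  base <- which(tms >= -200 & tms < 0)
  stopIfNot(length(base) > 0,
            "epoch must cover the -200..0 ms baseline window")
  if (cutoffHz < fsHz / 2) {
    bf <- signal::butter(order, cutoffHz / (fsHz / 2), type = "low")
    trial <- t(.cxFiltFilt(t(trial), bf$b, bf$a))
  }
  trial - rowMeans(trial[, base, drop = FALSE])
}

#' Per-subject mean current density in a region and time window
#'
#' For each subject, averages the (optionally preprocessed) current density
#' over trials, the vertices of `regionId`, and the samples inside
#' `windowMs` — the per-subject quantity correlated against clinical scores.
#'
#' @param cohort a [SourceCohort-class].
#' @param regionId a region id on the cohort surface.
#' @param windowMs (start, end) ms window inside the epoch.
#' @param preprocess apply [preprocessTrial()] to each trial first.
#' @return named numeric vector, one value per subject.
#' @export
roiMeanCurrentDensity <- function(cohort, regionId, windowMs,
                                  preprocess = TRUE) {
  stopIfNot(regionId %in% regionLabels(cohort@surface),
            sprintf("unknown region %s", regionId))
  stopIfNot(windowMs[1] >= cohort@tStartMs && windowMs[2] <= cohort@tEndMs,
            "window must lie inside the epoch")
  tms <- epochTimesMs(cohort@tStartMs, cohort@tEndMs, cohort@fsHz)
  wcols <- which(tms >= windowMs[1] & tms < windowMs[2])
  vidx <- which(regionLabels(cohort@surface) == regionId)
  out <- numeric(nrow(cohort@meta))
  for (si in seq_len(nrow(cohort@meta))) {
    acc <- 0
    nT <- cohort@meta$nTrials[si]
    for (tr in seq_len(nT)) {
      E <- simTrialMatrix(cohort, si, tr)
      if (preprocess) E <- preprocessTrial(E, cohort@fsHz, cohort@tStartMs)
      acc <- acc + mean(E[vidx, wcols])
    }
    out[si] <- acc / nT
  }
  names(out) <- cohort@meta$subjectId
  out
}
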