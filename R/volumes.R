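#' Build one standardized input volume from a trial
#'
#' In `"3d"` mode the current density is averaged per vertex within each of
#' 16 contiguous half-open 50 ms bins covering 0-800 ms, each bin is
#' projected onto the grid and standardized over the ellipse, and the 16
#' frames are stacked depth-wise. In `"2d"` mode a single 200-350 ms
#' average is projected and standardized.
#'
#' @param trial numeric vertices x time matrix (already preprocessed).
#' @param map a [MollweideMap-class].
#' @param mode `"3d"` or `"2d"`.
#' @param fsHz sampling rate of the trial (Hz).
#' @param tStartMs epoch start (ms); the epoch must cover 0-800 ms.
#' @param binMs 3d bin width (default 50 ms).
#' @param spanMs 3d bin span (default `c(0, 800)`); 2d window is 200-350 ms.
#' @return numeric array `gridSize x gridSize x nBins` with attribute
#'   `windows` (nBins x 2 start/end ms).
#' @export
buildVolume <- function(trial, map, mode = c("3d", "2d"), fsHz, tStartMs,
                        binMs = 50, spanMs = c(0, 800)) {
  mode <- match.arg(mode)
  tms <- tStartMs + (seq_len(ncol(trial)) - 1) * 1000 / fsHz
  stopIfNot(min(tms) <= spanMs[1] && max(tms) >= spanMs[2] - 1000 / fsHz,
            "epoch too short: trial must cover the 0-800 ms span")
  windows <- if (mode == "3d") {
    starts <- seq(spanMs[1], spanMs[2] - binMs, by = binMs)
    cbind(start = starts, end = starts + binMs)
  } else cbind(start = 200, end = 350)
  G <- map@gridSize
  out <- array(0, c(G, G, nrow(windows)))
  for (b in seq_len(nrow(windows))) {
    cols <- which(tms >= windows[b, 1] & tms < windows[b, 2])
    frame <- gridProject(map, rowMeans(trial[, cols, drop = FALSE]))
    out[, , b] <- standardizeImage(frame, map@mask)
  }
  attr(out, "windows") <- windows
  out
}

#' Build the CNN input volumes for a whole cohort
#'
#' Streams subjects and trials: each trial is materialized, preprocessed
#' (zero-phase lowpass + baseline correction) and converted with
#' [buildVolume()], so the full source array is never held in memory.
#'
#' @param cohort a [SourceCohort-class].
#' @param map a [MollweideMap-class] for the cohort surface.
#' @param mode `"3d"` (default) or `"2d"`.
#' @param subjects subject ids to include (default all).
#' @param preprocess apply [preprocessTrial()] first (default TRUE).
#' @param transform optional function applied to each raw vertices x time
#'   trial before preprocessing (e.g. a forward-projection + wMNE round
#'   trip).
#' @return a [VolumeSet-class].
#' @export
cohortVolumes <- function(cohort, map, mode = c("3d", "2d"),
                          subjects = NULL, preprocess = TRUE,
                          transform = NULL) {
  mode <- match.arg(mode)
  meta <- cohortMeta(cohort)
  if (is.null(subjects)) subjects <- meta$subjectId
  sidx <- match(subjects, meta$subjectId)
  stopIfNot(!anyNA(sidx), "unknown subject id in 'subjects'")
  nTot <- sum(meta$nTrials[sidx])
  G <- map@gridSize
  D <- if (mode == "3d") 16L else 1L
  vals <- array(0, c(G, G, D, nTot))
  labs <- character(nTot); sid <- character(nTot); tid <- integer(nTot)
  windows <- NULL
  k <- 0L
  for (si in sidx) {
    for (tr in seq_len(meta$nTrials[si])) {
      E <- simTrialMatrix(cohort, si, tr)
      if (!is.null(transform)) E <- transform(E)
      if (preprocess) E <- preprocessTrial(E, cohort@fsHz, cohort@tStartMs)
      vol <- buildVolume(E, map, mode, cohort@fsHz, cohort@tStartMs)
      if (is.null(windows)) windows <- attr(vol, "windows")
      k <- k + 1L
      vals[, , , k] <- vol
      labs[k] <- meta$group[si]; sid[k] <- meta$subjectId[si]; tid[k] <- tr
    }
  }
  new("VolumeSet", values = vals, labels = labs, subjectId = sid,
      trialId = tid, windows = windows, mode = mode, mask = map@mask)
}

#' Subset a VolumeSet by sample index
#'
#' @param x a [VolumeSet-class].
#' @param i sample indices (integer or logical).
#' @return a [VolumeSet-class] with the selected samples.
#' @export
subsetVolumes <- function(x, i) {
  new("VolumeSet", values = x@values[, , , i, drop = FALSE],
      labels = x@labels[i], subjectId = x@subjectId[i],
      trialId = x@trialId[i], windows = x@windows, mode = x@mode,
      mask = x@mask)
}

#' Concatenate VolumeSets
#'
#' @param ... [VolumeSet-class] objects with identical frame geometry.
#' @return a combined [VolumeSet-class].
#' @export
bindVolumes <- function(...) {
  sets <- list(...)
  d <- dim(sets[[1]]@values)[1:3]
  for (s in sets) stopIfNot(all(dim(s@values)[1:3] == d),
                            "volume geometries differ")
  vals <- array(0, c(d, sum(vapply(sets, nSamples, 1L))))
  k <- 0L
  for (s in sets) {
    n <- nSamples(s)
    vals[, , , k + seq_len(n)] <- s@values
    k <- k + n
  }
  new("VolumeSet", values = vals,
      labels = unlist(lapply(sets, function(s) s@labels)),
      subjectId = unlist(lapply(sets, function(s) s@subjectId)),
      trialId = unlist(lapply(sets, function(s) s@trialId)),
      windows = sets[[1]]@windows, mode = sets[[1]]@mode,
      mask = sets[[1]]@mask)
}

#' Ground-truth mask volume of the planted effect
#'
#' The grid footprint of the planted region crossed with the time bins that
#' overlap the planted window — the voxel set a successful localization
#' should highlight.
#'
#' @param map a [MollweideMap-class].
#' @param spec the cohort's [EffectSpec-class].
#' @param windows the volume's nBins x 2 window matrix
#'   (see [volumeWindows()]).
#' @return logical array `gridSize x gridSize x nBins`.
#' @export
plantedMaskVolume <- function(map, spec, windows) {
  roi <- roiGridMask(map, spec@roiRegion)
  inWin <- windows[, 1] < spec@windowMs[2] & windows[, 2] > spec@windowMs[1]
  out <- array(FALSE, c(map@gridSize, map@gridSize, nrow(windows)))
  for (b in which(inWin)) out[, , b] <- roi
  out
}
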