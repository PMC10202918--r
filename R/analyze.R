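# Heatmap aggregation, ROI analysis and cohort statistics.

#' Aggregate heatmaps over a (group, correctness) cell
#'
#' Elementwise mean of the heatmaps whose samples have true label `group`
#' and whose classification matches `correct` (prediction equals label).
#' An empty cell is reported as missing, not as zeros.
#'
#' @param relevance a [RelevanceSet-class].
#' @param predicted integer 0/1 predictions aligned with the samples
#'   (1 = patient).
#' @param group `"patient"` or `"control"` (true-label filter).
#' @param correct `TRUE` for correctly classified samples.
#' @return list with `mean` (3d array or `NULL` when the cell is empty)
#'   and `n` (sample count).
#' @export
aggregateHeatmaps <- function(relevance, predicted, group = "patient",
                              correct = TRUE) {
  labs <- relevance@labels
  stopIfNot(length(predicted) == nSamples(relevance),
            "one prediction per heatmap required")
  y <- as.integer(labs == "patient")
  sel <- which(labs == group & ((predicted == y) == correct))
  if (!length(sel)) return(list(mean = NULL, n = 0L))
  d <- dim(relevance@values)
  acc <- array(0, d[1:3])
  for (j in sel) acc <- acc + relevance@values[, , , j]
  list(mean = acc / length(sel), n = length(sel))
}

#' ROI relevance time course and peak window
#'
#' Averages an aggregated 3d heatmap over a grid ROI mask per time bin and
#' reports the window attaining the maximum (ties broken to the earliest
#' bin).
#'
#' @param aggregate a 3d heatmap array (H x W x nBins), e.g.
#'   `aggregateHeatmaps(...)$mean`.
#' @param roiMask logical H x W mask (see [roiGridMask()]).
#' @param windows nBins x 2 matrix of (startMs, endMs) bin edges.
#' @return list with `values` (per-bin mean relevance), `peakBin`,
#'   `peakWindow` (startMs, endMs).
#' @export
roiTimeCourse <- function(aggregate, roiMask, windows) {
  stopIfNot(any(roiMask), "ROI mask must not be empty")
  stopIfNot(dim(aggregate)[3] == nrow(windows),
            "one window per time bin required")
  vals <- vapply(seq_len(dim(aggregate)[3]),
                 function(b) mean(aggregate[, , b][roiMask]), 1)
  peak <- which.max(vals)
  list(values = vals, peakBin = peak,
       peakWindow = c(start = unname(windows[peak, 1]),
                      end = unname(windows[peak, 2])))
}

#' Localization score of a heatmap against the planted effect
#'
#' Rank-based area under the ROC curve of absolute relevance as a detector
#' of the planted spatiotemporal mask: 1 means the heatmap concentrates
#' exactly on the planted voxels, 0.5 is chance.
#'
#' @param heatmap 3d array (same shape as the mask).
#' @param maskVolume logical 3d array of planted voxels (see
#'   [plantedMaskVolume()]).
#' @return AUC in \[0, 1\].
#' @export
localizationScore <- function(heatmap, maskVolume) {
  stopIfNot(all(dim(heatmap) == dim(maskVolume)), "shapes must match")
  pos <- as.logical(maskVolume)
  stopIfNot(any(pos) && !all(pos),
            "degenerate mask: needs both planted and background voxels")
  r <- rank(abs(as.vector(heatmap)))
  nPos <- sum(pos); nNeg <- sum(!pos)
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Cohen's d from group summary statistics
#'
#' `d = (mean2 - mean1) / sPooled` with the (n-1)-weighted pooled standard
#' deviation; by convention group 1 is the control group and group 2 the
#' patient group, so a negative d means lower patient scores.
#'
#' @param mean1,sd1,n1 control-group summary.
#' @param mean2,sd2,n2 patient-group summary.
#' @return Cohen's d (`NA` when the pooled SD is zero).
#' @examples
#' cohenD(4.94, 3.36, 49, 47.53, 19.46, 49)   # 3.05
#' cohenD(28.88, 1.29, 49, 27.27, 2.14, 49)   # -0.91
#' @export
cohenD <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopIfNot(sd1 >= 0 && sd2 >= 0, "sds must be >= 0")
  stopIfNot(n1 >= 2 && n2 >= 2, "ns must be >= 2")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) return(NA_real_)
  (mean2 - mean1) / sp
}

#' Two-sample t test from summary statistics
#'
#' Pooled-variance independent-samples t test with `n1 + n2 - 2` degrees of
#' freedom, two-sided p. Equal means with zero variance in both groups give
#' p = 1 by convention.
#'
#' @inheritParams cohenD
#' @return list with `t`, `df`, `p`.
#' @examples
#' summaryTTest(66.00, 6.37, 49, 65.96, 5.94, 49)$p   # ~0.974
#' @export
summaryTTest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopIfNot(sd1 >= 0 && sd2 >= 0, "sds must be >= 0")
  stopIfNot(n1 >= 2 && n2 >= 2, "ns must be >= 2")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  df <- n1 + n2 - 2
  if (sp2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean2 - mean1) * Inf, df = df, p = 0))
  }
  t <- (mean2 - mean1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the point-probability rule.
#'
#' @param counts 2x2 matrix of nonnegative counts.
#' @return the two-sided p value.
#' @examples
#' fisherExactTest(matrix(c(33, 29, 16, 20), 2))   # ~0.529
#' @export
fisherExactTest <- function(counts) {
  stopIfNot(all(counts >= 0) && all(dim(counts) == c(2, 2)),
            "counts must be a nonnegative 2x2 matrix")
  stats::fisher.test(counts)$p.value
}

#' One-tailed Pearson correlation
#'
#' Sample correlation with the one-tailed p value from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` in the stated direction.
#'
#' @param x,y numeric vectors (n >= 3, finite).
#' @param direction `"positive"` or `"negative"` alternative.
#' @return list with `rho`, `p`, `n`.
#' @export
pearsonOneTailed <- function(x, y, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  stopIfNot(length(x) == length(y) && length(x) >= 3,
            "x and y must have equal length >= 3")
  stopIfNot(all(is.finite(x)) && all(is.finite(y)), "values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = if (direction == "positive") "greater"
                                      else "less")
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Group statistics table for cohort scores
#'
#' Mean +/- SD per group with pooled-SD Cohen's d and the two-sample t test
#' for each score column — the cohort-characterization layout used for
#' demographics and neuropsychological scores.
#'
#' @param meta cohort metadata data.frame with a `group` column.
#' @param scoreCols character vector of numeric score columns.
#' @return data.frame with one row per score.
#' @export
groupStatsTable <- function(meta, scoreCols) {
  rows <- lapply(scoreCols, function(sc) {
    g1 <- meta[[sc]][meta$group == "control"]
    g2 <- meta[[sc]][meta$group == "patient"]
    tt <- summaryTTest(mean(g1), stats::sd(g1), length(g1),
                       mean(g2), stats::sd(g2), length(g2))
    data.frame(score = sc,
               controlMean = mean(g1), controlSd = stats::sd(g1),
               patientMean = mean(g2), patientSd = stats::sd(g2),
               cohenD = cohenD(mean(g1), stats::sd(g1), length(g1),
                               mean(g2), stats::sd(g2), length(g2)),
               t = tt$t, p = tt$p)
  })
  do.call(rbind, rows)
}
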