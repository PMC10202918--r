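#' Training configuration
#'
#' Defaults follow the reference protocol: Adam on binary cross-entropy,
#' weight decay 1e-5, up to 100 epochs with early stopping after 10 epochs
#' without validation-accuracy improvement, learning rate from the range
#' test when not given. The full-scale batch size is 128; the desk-scale
#' default here is 16.
#'
#' @param batchSize mini-batch size.
#' @param maxEpochs maximum training epochs.
#' @param patience early-stopping patience (epochs without improvement).
#' @param lr learning rate; `NULL` runs [lrRangeTest()] first.
#' @param weightDecay L2 weight decay added to the gradients.
#' @param valFraction validation fraction of the pretraining split.
#' @param seed seed for undersampling, splits and batch shuffling.
#' @return a list of class `"cxTrainConfig"`.
#' @export
trainConfig <- function(batchSize = 16L, maxEpochs = 100L, patience = 10L,
                        lr = NULL, weightDecay = 1e-5, valFraction = 0.1,
                        seed = 1L) {
  stopIfNot(patience <= maxEpochs, "patience must be <= maxEpochs")
  stopIfNot(batchSize >= 1 && maxEpochs >= 1 && patience >= 1 &&
              weightDecay >= 0, "training parameters must be positive")
  structure(list(batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience), lr = lr,
                 weightDecay = weightDecay, valFraction = valFraction,
                 seed = as.integer(seed)),
            class = "cxTrainConfig")
}

paramNames <- function(l) switch(l$type,
  conv = c("W", "b"), dense = c("W", "b"), bn = c("gamma", "beta"),
  character())

adamInit <- function(layers) {
  lapply(layers, function(l) {
    nm <- paramNames(l)
    if (!length(nm)) return(NULL)
    st <- lapply(nm, function(p) list(m = l[[p]] * 0, v = l[[p]] * 0))
    names(st) <- nm
    st
  })
}

adamStep <- function(layers, grads, state, lr, wd, t, freeze = integer()) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  gradName <- c(W = "dW", b = "db", gamma = "dgamma", beta = "dbeta")
  for (i in seq_along(layers)) {
    if (i %in% freeze || is.null(grads[[i]])) next
    for (p in paramNames(layers[[i]])) {
      g <- grads[[i]][[gradName[[p]]]] + wd * layers[[i]][[p]]
      st <- state[[i]][[p]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      mhat <- st$m / (1 - b1^t)
      vhat <- st$v / (1 - b2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

# Stable binary cross-entropy from logits; gradient is sigmoid(z) - y.
bceLoss <- function(z, y) mean(pmax(z, 0) - y * z + log1p(exp(-abs(z))))

modelAccuracy <- function(layers, vals, labels01, batchSize = 64L) {
  n <- length(labels01)
  pred <- numeric(n)
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(n, start + batchSize - 1L)
    inp <- volumesToInput(vals, idx)
    pred[idx] <- nnForward(layers, inp$X, inp$n)$logits
  }
  mean((pred > 0) == (labels01 == 1))
}

# Core mini-batch training loop with early stopping on validation accuracy
# (best-seen parameters are restored; training also stops once validation
# accuracy reaches 1, since it cannot improve further).
trainLoop <- function(model, vals, labels01, trainIdx, valIdx, cfg, lr, wd,
                      freeze = integer(), stopOn = c("val", "train"),
                      bnTrain = TRUE) {
  stopOn <- match.arg(stopOn)
  layers <- model@layers
  state <- adamInit(layers)
  best <- list(acc = -Inf, layers = layers)
  sinceBest <- 0L
  t <- 0L
  log <- data.frame(epoch = integer(), trainLoss = numeric(),
                    valAccuracy = numeric())
  withSeed(cfg$seed + 17L, {
    for (epoch in seq_len(cfg$maxEpochs)) {
      ord <- sample(trainIdx)
      epLoss <- 0; nb <- 0L
      for (start in seq(1L, length(ord), by = cfg$batchSize)) {
        batch <- ord[start:min(length(ord), start + cfg$batchSize - 1L)]
        inp <- volumesToInput(vals, batch)
        fw <- nnForward(layers, inp$X, inp$n, train = bnTrain,
                        keepCache = TRUE)
        layers <- fw$layers
        y <- labels01[batch]
        epLoss <- epLoss + bceLoss(fw$logits, y); nb <- nb + 1L
        dz <- (plogis(fw$logits) - y) / length(batch)
        bw <- nnBackward(layers, fw$cache, inp$n, dz)
        t <- t + 1L
        upd <- adamStep(layers, bw$grads, state, lr, wd, t, freeze)
        layers <- upd$layers; state <- upd$state
      }
      accIdx <- if (stopOn == "val") valIdx else trainIdx
      acc <- modelAccuracy(layers, vals[, , , accIdx, drop = FALSE],
                           labels01[accIdx])
      log <- rbind(log, data.frame(epoch = epoch, trainLoss = epLoss / nb,
                                   valAccuracy = acc))
      if (acc > best$acc) {
        best <- list(acc = acc, layers = layers)
        sinceBest <- 0L
      } else sinceBest <- sinceBest + 1L
      # validation accuracy of 1 cannot improve; training-monitored runs
      # continue to patience so the loss keeps calibrating the output
      if (sinceBest >= cfg$patience ||
          (stopOn == "val" && best$acc >= 1)) break
    }
  })
  model@layers <- best$layers
  model@log <- log
  model
}

#' Seeded random undersampling to balanced classes
#'
#' @param labels character or factor labels.
#' @param seed integer seed.
#' @return integer indices of the retained samples (classes 1:1).
#' @export
undersampleIndices <- function(labels, seed = 1L) {
  tab <- table(labels)
  m <- min(tab)
  withSeed(seed, {
    unlist(lapply(names(tab), function(cl) {
      idx <- which(labels == cl)
      if (length(idx) > m) sort(sample(idx, m)) else idx
    }), use.names = FALSE)
  })
}

#' Pick a learning rate from a range-test loss curve
#'
#' Given losses recorded while the learning rate sweeps exponentially from
#' low to high, anchors the choice on the divergence point — the first
#' rate at which the smoothed loss exceeds `divergeFactor` times the best
#' seen so far. Divergence is the one large, unambiguous feature of a
#' range-test curve, and the returned rate is `lrs[d] / divideBy`:
#' detection lags the true stability edge by the smoothing window, so half
#' a decade below the detected point sits about a decade below the edge
#' itself — on a quadratic objective under gradient descent the result
#' stays below the analytic `2/L` threshold. When nothing diverges within
#' the sweep, the rate achieving the minimum smoothed loss is returned,
#' provided that minimum undercuts both the starting loss and `plateau`
#' (for binary cross-entropy, `log(2)` is the trivial constant-predictor
#' loss; a sweep that never beats it has not demonstrated learning and its
#' minimum is noise). Otherwise falls back to `fallback` with a warning.
#'
#' @param lrs increasing learning rates, one per step.
#' @param losses loss recorded at each step.
#' @param divergeFactor divergence threshold relative to the best loss.
#' @param fallback rate returned when no descent is found.
#' @param plateau trivial-predictor loss level that a trustworthy
#'   non-diverging sweep must undercut (default `log(2)`; pass `Inf` for
#'   other losses).
#' @param divideBy safety divisor applied to the detected divergence
#'   rate (default 5).
#' @return the chosen learning rate.
#' @export
chooseLrFromCurve <- function(lrs, losses, divergeFactor = 4,
                              fallback = 1e-3, plateau = log(2),
                              divideBy = 5) {
  w <- min(5L, length(losses))
  sm <- stats::filter(losses, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- losses[is.na(sm)]
  sm <- as.numeric(sm)
  bestSoFar <- cummin(sm)
  div <- which(sm > divergeFactor * bestSoFar)
  if (length(div))
    return(min(max(lrs[div[1]] / divideBy, min(lrs)), max(lrs)))
  if (min(sm) >= min(sm[1] - 1e-12, plateau)) {
    warning("loss never decreased during the range test; using fallback lr")
    return(min(max(fallback, min(lrs)), max(lrs)))
  }
  lrs[which.min(sm)]
}

#' Learning-rate range test
#'
#' Sweeps the learning rate exponentially from `lrMin` to `lrMax` over
#' successive mini-batches (one Adam step per rate). The loss is measured
#' on a fixed probe batch in evaluation mode before each step, so the
#' recorded curve reflects parameter movement rather than batch-composition
#' noise; the chosen rate sits one order of magnitude below the divergence
#' point of the smoothed curve (see [chooseLrFromCurve()]). Deterministic
#' given the config seed.
#'
#' @param model an untrained [CnnModel-class] (a copy is swept; the model
#'   is not modified).
#' @param volumes a [VolumeSet-class].
#' @param cfg a [trainConfig()].
#' @param lrMin,lrMax sweep bounds (defaults 1e-8 and 1).
#' @param nSteps number of sweep steps.
#' @return chosen learning rate, with the sweep recorded in attributes
#'   `lrs` and `losses`.
#' @export
lrRangeTest <- function(model, volumes, cfg = trainConfig(),
                        lrMin = 1e-8, lrMax = 1, nSteps = 40L) {
  stopIfNot(nSamples(volumes) >= 1, "at least one batch of data required")
  vals <- volumes@values
  labels01 <- as.integer(volumeLabels(volumes) == "patient")
  lrs <- exp(seq(log(lrMin), log(lrMax), length.out = nSteps))
  layers <- model@layers
  state <- adamInit(layers)
  losses <- numeric(nSteps)
  withSeed(cfg$seed + 29L, {
    n <- length(labels01)
    probe <- sample(n, min(2L * cfg$batchSize, n))
    probeInp <- volumesToInput(vals, probe)
    for (s in seq_len(nSteps)) {
      # probe with batch statistics (running stats are untrained early on);
      # the updated layers are discarded, so probing has no side effect
      losses[s] <- bceLoss(nnForward(layers, probeInp$X, probeInp$n,
                                     train = TRUE)$logits, labels01[probe])
      batch <- sample(n, min(cfg$batchSize, n))
      inp <- volumesToInput(vals, batch)
      fw <- nnForward(layers, inp$X, inp$n, train = TRUE, keepCache = TRUE)
      layers <- fw$layers
      y <- labels01[batch]
      dz <- (plogis(fw$logits) - y) / length(batch)
      bw <- nnBackward(layers, fw$cache, inp$n, dz)
      upd <- adamStep(layers, bw$grads, state, lrs[s], cfg$weightDecay, s)
      layers <- upd$layers; state <- upd$state
    }
  })
  lr <- chooseLrFromCurve(lrs, losses)
  structure(lr, lrs = lrs, losses = losses)
}

#' Pretrain a classifier, excluding one held-out subject
#'
#' Implements the pretraining stage of the transfer-learning protocol: all
#' volumes of the held-out subject are removed, classes are randomly
#' undersampled to 1:1, the rest is split 90/10 into training and
#' validation, and the model is trained with early stopping on validation
#' accuracy. The returned model carries the best-validation parameters and
#' a per-epoch training log, plus the protocol record (held-out id,
#' training subjects, learning rate) in `model@arch$protocol`.
#'
#' @param model an initialized [CnnModel-class].
#' @param volumes the cohort [VolumeSet-class].
#' @param heldOutSubjectId subject id to exclude (must exist).
#' @param cfg a [trainConfig()]; `lr = NULL` triggers a range test on the
#'   pretraining data.
#' @return the trained [CnnModel-class].
#' @export
pretrain <- function(model, volumes, heldOutSubjectId, cfg = trainConfig()) {
  sid <- subjectIds(volumes)
  stopIfNot(heldOutSubjectId %in% sid,
            sprintf("held-out subject '%s' not in the cohort volumes",
                    heldOutSubjectId))
  keep <- which(sid != heldOutSubjectId)
  pool <- subsetVolumes(volumes, keep)
  us <- undersampleIndices(volumeLabels(pool), seed = cfg$seed + 7L)
  pool <- subsetVolumes(pool, us)
  n <- nSamples(pool)
  valIdx <- withSeed(cfg$seed + 11L,
                     sort(sample(n, max(1L, round(cfg$valFraction * n)))))
  trainIdx <- setdiff(seq_len(n), valIdx)
  lr <- cfg$lr
  if (is.null(lr))
    lr <- as.numeric(lrRangeTest(model, subsetVolumes(pool, trainIdx), cfg))
  labels01 <- as.integer(volumeLabels(pool) == "patient")
  model <- trainLoop(model, pool@values, labels01, trainIdx, valIdx, cfg,
                     lr = lr, wd = cfg$weightDecay)
  model@arch$protocol <- list(heldOut = heldOutSubjectId,
                              trainedSubjects = unique(subjectIds(pool)),
                              lr = lr, weightDecay = cfg$weightDecay)
  model
}

convLayerIndices <- function(model)
  which(vapply(model@layers, function(l) l$type %in% c("conv", "bn"), TRUE))

#' Fingerprint of the convolutional parameters
#'
#' @param model a [CnnModel-class].
#' @return numeric vector of the concatenated conv/batchnorm parameters
#'   (useful to verify they are untouched by fine-tuning).
#' @export
convParameterVector <- function(model) {
  unlist(lapply(model@layers[convLayerIndices(model)], function(l)
    unlist(l[paramNames(l)], use.names = FALSE)), use.names = FALSE)
}

#' Fine-tune the fully connected layers for one held-out subject
#'
#' Implements the fine-tuning/evaluation stage: the held-out subject's
#' volumes are pooled with reserve-control volumes (controls never seen in
#' pretraining), undersampled to 1:1 when both classes are present, and
#' split 80/20. Only the fully connected and output layers are updated
#' (convolution and batch-normalization parameters stay bit-identical);
#' learning rate and weight decay are 1/10 of the pretraining values.
#' Early stopping monitors training accuracy (the 20% split is reserved
#' for evaluation).
#'
#' @param model a pretrained [CnnModel-class] (from [pretrain()]).
#' @param spVolumes the held-out subject's [VolumeSet-class].
#' @param reserveVolumes reserve-control volumes; their subjects must be
#'   disjoint from the model's pretraining subjects.
#' @param cfg a [trainConfig()].
#' @return list with `model` (fine-tuned) and `evalVolumes` (the held-out
#'   20% evaluation split).
#' @export
fineTune <- function(model, spVolumes, reserveVolumes, cfg = trainConfig()) {
  proto <- model@arch$protocol
  stopIfNot(!is.null(proto), "model must come from pretrain()")
  overlap <- intersect(unique(subjectIds(reserveVolumes)),
                       proto$trainedSubjects)
  stopIfNot(length(overlap) == 0,
            paste("audit error: reserve controls overlap pretraining:",
                  paste(overlap, collapse = ", ")))
  stopIfNot(!unique(subjectIds(spVolumes)) %in% proto$trainedSubjects,
            "audit error: held-out subject appeared in pretraining")
  all <- bindVolumes(spVolumes, reserveVolumes)
  labs <- volumeLabels(all)
  if (length(unique(labs)) > 1) {
    us <- undersampleIndices(labs, seed = cfg$seed + 13L)
    all <- subsetVolumes(all, us)
  }
  n <- nSamples(all)
  evalIdx <- withSeed(cfg$seed + 19L, sort(sample(n, max(1L, round(0.2 * n)))))
  trainIdx <- setdiff(seq_len(n), evalIdx)
  labels01 <- as.integer(volumeLabels(all) == "patient")
  lr <- proto$lr / 10
  wd <- proto$weightDecay / 10
  model <- trainLoop(model, all@values, labels01, trainIdx,
                     valIdx = trainIdx, cfg, lr = lr, wd = wd,
                     freeze = convLayerIndices(model), stopOn = "train",
                     bnTrain = FALSE)
  model@arch$protocol$fineTuneLr <- lr
  list(model = model, evalVolumes = subsetVolumes(all, evalIdx))
}

#' Classification metrics at a decision threshold
#'
#' Accuracy, precision and recall at the threshold, AUROC by the rank
#' statistic over scores, and the confusion counts. Precision/recall are
#' `NA` when their denominator is empty; AUROC is `NA` when only one class
#' is present.
#'
#' @param model a trained [CnnModel-class].
#' @param volumes a [VolumeSet-class] (labels taken from it unless given).
#' @param labels optional label vector overriding the set's labels.
#' @param threshold decision threshold on the sigmoid output (default 0.5).
#' @return list with `accuracy`, `precision`, `recall`, `auroc`, `counts`
#'   (TP/FP/TN/FN), `scores`, `predicted`.
#' @export
evaluateModel <- function(model, volumes, labels = NULL, threshold = 0.5) {
  if (is.null(labels)) labels <- volumeLabels(volumes)
  y <- as.integer(labels == "patient")
  scores <- predictModel(model, volumes)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  auroc <- if (length(unique(y)) < 2) NA_real_ else {
    r <- rank(scores)
    nPos <- sum(y == 1); nNeg <- sum(y == 0)
    (sum(r[y == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  }
  list(accuracy = (tp + tn) / length(y),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       auroc = auroc,
       counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
       scores = scores, predicted = pred)
}

#' Leave-one-subject-out transfer-learning protocol
#'
#' For each patient fold: a fresh model is pretrained on all subjects
#' except the held-out patient and the reserve controls, fine-tuned on the
#' held-out patient plus the reserve controls (convolutions frozen, rates
#' divided by 10), and evaluated on the fine-tuning 20% split. A fraction
#' of control subjects is withheld from every pretraining as the reserve.
#' The learning rate is chosen once by a range test on the first fold's
#' pretraining data and reused across folds.
#'
#' @param volumes the cohort [VolumeSet-class].
#' @param arch an [archConfig()].
#' @param cfg a [trainConfig()].
#' @param reserveFraction fraction of control subjects reserved for
#'   fine-tuning (default 0.2).
#' @param nFolds number of patient folds to run (default all patients).
#' @return list with per-fold results (`subject`, `model`, `metrics`,
#'   `evalVolumes`), `meanMetrics`, `reserveControls` and the shared `lr`.
#' @export
runLoso <- function(volumes, arch, cfg = trainConfig(),
                    reserveFraction = 0.2, nFolds = NULL) {
  sid <- subjectIds(volumes)
  labs <- volumeLabels(volumes)
  subjects <- unique(sid)
  groups <- labs[match(subjects, sid)]
  controls <- subjects[groups == "control"]
  patients <- subjects[groups == "patient"]
  nres <- max(1L, round(reserveFraction * length(controls)))
  reserve <- withSeed(cfg$seed + 23L, sort(sample(controls, nres)))
  if (is.null(nFolds)) nFolds <- length(patients)
  folds <- patients[seq_len(min(nFolds, length(patients)))]
  pretrainPool <- subsetVolumes(volumes, !(sid %in% reserve))
  lr <- cfg$lr
  results <- list()
  for (f in seq_along(folds)) {
    t0 <- proc.time()["elapsed"]
    sp <- folds[f]
    foldCfg <- cfg
    foldCfg$seed <- cfg$seed + f
    model <- buildModel(do.call(archConfig, arch[c("mode", "inputDim",
                                                   "convChannels",
                                                   "fcWidth")]),
                        seed = cfg$seed + 100L + f)
    if (is.null(lr)) {
      sweepPool <- subsetVolumes(pretrainPool, subjectIds(pretrainPool) != sp)
      lr <- as.numeric(lrRangeTest(model, sweepPool, foldCfg))
    }
    foldCfg$lr <- lr
    model <- pretrain(model, pretrainPool, sp, foldCfg)
    ft <- fineTune(model,
                   subsetVolumes(volumes, sid == sp),
                   subsetVolumes(volumes, sid %in% reserve),
                   foldCfg)
    metrics <- evaluateModel(ft$model, ft$evalVolumes)
    results[[sp]] <- list(subject = sp, model = ft$model,
                          metrics = metrics, evalVolumes = ft$evalVolumes,
                          elapsedSec = unname(proc.time()["elapsed"] - t0))
  }
  nums <- c("accuracy", "precision", "recall", "auroc")
  meanMetrics <- sapply(nums, function(m)
    mean(vapply(results, function(r) r$metrics[[m]], 1), na.rm = TRUE))
  list(folds = results, meanMetrics = meanMetrics,
       reserveControls = reserve, lr = lr)
}
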