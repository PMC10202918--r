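# Explainability: layer-wise relevance propagation (LRP-0 / LRP-gamma),
# GradCAM, guided backpropagation and guided GradCAM.

# Fold each batch-normalization layer (eval-mode running statistics) into
# the preceding convolution, so relevance propagation sees plain affine
# layers. Returns the folded layer list.
foldBatchnorm <- function(layers) {
  out <- list()
  i <- 1L
  while (i <= length(layers)) {
    l <- layers[[i]]
    if (l$type == "conv" && i < length(layers) &&
        layers[[i + 1]]$type == "bn") {
      bn <- layers[[i + 1]]
      scale <- bn$gamma / sqrt(bn$runVar + bn$eps)
      l$W <- sweep(l$W, 2, scale, "*")
      l$b <- (l$b - bn$runMean) * scale + bn$beta
      out <- c(out, list(l))
      i <- i + 2L
    } else if (l$type == "bn") {
      stop("unsupported layer for relevance propagation: ",
           "batch normalization without a preceding convolution",
           call. = FALSE)
    } else {
      out <- c(out, list(l))
      i <- i + 1L
    }
  }
  out
}

# Forward pass through a folded (affine/relu/pool/flatten) layer sequence,
# keeping the activation entering each layer and pooling switches.
foldedForward <- function(layers, X, n) {
  acts <- vector("list", length(layers))
  pools <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    acts[[i]] <- X
    if (l$type == "conv") {
      X <- .cxConvFwd(X, n, l$inDim[1], l$inDim[2], l$inDim[3],
                      l$k[1], l$k[2], l$k[3], l$W, l$b)
    } else if (l$type == "relu") {
      X <- pmax(X, 0)
    } else if (l$type == "pool") {
      r <- .cxMaxPoolFwd(X, n, l$inDim[1], l$inDim[2], l$inDim[3],
                         l$p[1], l$p[2], l$p[3])
      pools[[i]] <- list(idx = r$idx, nrowX = nrow(X))
      X <- r$Y
    } else if (l$type == "flatten") {
      X <- nnFlattenFwd(X, n, prod(l$inDim), l$C)
    } else if (l$type == "dense") {
      X <- sweep(X %*% l$W, 2, l$b, "+")
    } else {
      stop("unsupported layer for relevance propagation: ", l$type,
           call. = FALSE)
    }
  }
  list(out = X, acts = acts, pools = pools)
}

stabilize <- function(z, eps) z + eps * ifelse(z >= 0, 1, -1)

relevanceSetFrom <- function(values, method, ref) {
  new("RelevanceSet", values = values, method = method,
      subjectId = ref@subjectId, trialId = ref@trialId,
      labels = ref@labels)
}

#' Layer-wise relevance propagation
#'
#' Propagates the pre-sigmoid output score back to the input nodes with the
#' relevance decomposition `R_j = sum_k z_jk / (sum_j z_jk) R_k`, using the
#' LRP-0 rule (`z_jk = a_j w_jk`) for fully connected layers and the
#' LRP-gamma rule (`z_jk = a_j (w_jk + gamma max(w_jk, 0))`) for
#' convolutional layers, with epsilon-stabilized denominators. Bias
#' contributions are absorbed by the denominators (not redistributed), so
#' total relevance is conserved exactly on bias-free networks. Batch
#' normalization is folded into the adjacent convolution first; max-pooling
#' routes relevance to the winning position.
#'
#' @param model a trained [CnnModel-class].
#' @param volumes a [VolumeSet-class].
#' @param gamma LRP-gamma coefficient for convolutional layers
#'   (default 0.25; 0 gives LRP-0 everywhere).
#' @param epsilon denominator stabilizer (default 1e-9).
#' @param batchSize samples per internal batch.
#' @return a [RelevanceSet-class] with method `"lrp"`.
#' @export
lrp <- function(model, volumes, gamma = 0.25, epsilon = 1e-9,
                batchSize = 16L) {
  stopIfNot(gamma >= 0, "gamma must be >= 0")
  stopIfNot(epsilon > 0, "epsilon must be > 0")
  layers <- foldBatchnorm(model@layers)
  vals <- volumes@values
  d <- dim(vals)
  out <- array(0, d)
  for (start in seq(1L, d[4], by = batchSize)) {
    idx <- start:min(d[4], start + batchSize - 1L)
    inp <- volumesToInput(vals, idx)
    fw <- foldedForward(layers, inp$X, inp$n)
    R <- matrix(as.vector(fw$out), ncol = 1)   # seed: pre-sigmoid logit
    for (i in rev(seq_along(layers))) {
      l <- layers[[i]]
      A <- fw$acts[[i]]
      if (l$type == "dense") {
        Z <- stabilize(sweep(A %*% l$W, 2, l$b, "+"), epsilon)
        R <- A * ((R / Z) %*% t(l$W))
      } else if (l$type == "conv") {
        Wm <- l$W + gamma * pmax(l$W, 0)
        bm <- l$b + gamma * pmax(l$b, 0)
        Z <- stabilize(.cxConvFwd(A, inp$n, l$inDim[1], l$inDim[2],
                                  l$inDim[3], l$k[1], l$k[2], l$k[3],
                                  Wm, bm), epsilon)
        R <- A * .cxConvInputGrad(R / Z, inp$n, l$inDim[1], l$inDim[2],
                                  l$inDim[3], l$k[1], l$k[2], l$k[3],
                                  Wm, l$cin)
      } else if (l$type == "pool") {
        R <- .cxMaxPoolBwd(R, fw$pools[[i]]$idx, fw$pools[[i]]$nrowX)
      } else if (l$type == "flatten") {
        R <- nnFlattenBwd(R, inp$n, prod(l$inDim), l$C)
      }
      # relu: relevance passes through unchanged
    }
    out[, , , idx] <- array(R, c(d[1:3], inp$n))
  }
  relevanceSetFrom(out, "lrp", volumes)
}

# Spatial dimensions at the output of every layer, walked from the input.
layerDims <- function(layers, inputDim) {
  dims <- vector("list", length(layers))
  d <- inputDim
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "pool") d <- d %/% l$p
    if (l$type == "flatten") d <- NA
    dims[[i]] <- d
  }
  dims
}

# Index of the ReLU layer ending each convolutional block (ReLU directly
# followed by max pooling), i.e. the GradCAM target candidates.
blockReluIndices <- function(layers) {
  types <- vapply(layers, function(l) l$type, "")
  which(types == "relu" & c(types[-1], "") == "pool")
}

#' GradCAM importance map
#'
#' Computes the gradient of the pre-sigmoid class score with respect to the
#' activations of a convolutional block output, averages it spatially into
#' per-feature-map weights `w_n`, and forms `ReLU(sum_n w_n A^n)` at that
#' layer's resolution.
#'
#' @param model a trained [CnnModel-class].
#' @param volumes a [VolumeSet-class].
#' @param targetBlock which convolutional block output to target (default:
#'   the last).
#' @param batchSize samples per internal batch.
#' @return a [RelevanceSet-class] with method `"gradcam"`, at the feature
#'   map's spatial shape.
#' @export
gradCam <- function(model, volumes, targetBlock = NULL, batchSize = 16L) {
  cand <- blockReluIndices(model@layers)
  stopIfNot(length(cand) > 0, "model has no convolutional block output")
  if (is.null(targetBlock)) targetBlock <- length(cand)
  stopIfNot(targetBlock >= 1 && targetBlock <= length(cand),
            sprintf("target layer not found: block %s", targetBlock))
  target <- cand[targetBlock]
  dimsAt <- layerDims(model@layers, model@arch$inputDim)[[target]]
  vals <- volumes@values
  n <- dim(vals)[4]
  out <- array(0, c(dimsAt, n))
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(n, start + batchSize - 1L)
    inp <- volumesToInput(vals, idx)
    fw <- nnForward(model@layers, inp$X, inp$n, keepCache = TRUE)
    A <- fw$cache[[target]]$out                       # post-ReLU activations
    bw <- nnBackward(model@layers, fw$cache, inp$n,
                     rep(1, inp$n), recordLayer = target)
    G <- bw$recorded
    S <- prod(dimsAt)
    for (j in seq_along(idx)) {
      rows <- (j - 1L) * S + seq_len(S)
      w <- colMeans(G[rows, , drop = FALSE])
      out[, , , idx[j]] <- array(pmax(A[rows, , drop = FALSE] %*% w, 0),
                                 dimsAt)
    }
  }
  relevanceSetFrom(out, "gradcam", volumes)
}

#' Guided backpropagation gradient map
#'
#' The gradient of the pre-sigmoid class score with respect to the input,
#' where the backward signal at every ReLU is zeroed when either the
#' forward activation or the incoming gradient is non-positive.
#'
#' @inheritParams gradCam
#' @return a [RelevanceSet-class] with method `"gbp"` at input resolution.
#' @export
guidedBackprop <- function(model, volumes, batchSize = 16L) {
  vals <- volumes@values
  d <- dim(vals)
  out <- array(0, d)
  for (start in seq(1L, d[4], by = batchSize)) {
    idx <- start:min(d[4], start + batchSize - 1L)
    inp <- volumesToInput(vals, idx)
    fw <- nnForward(model@layers, inp$X, inp$n, keepCache = TRUE)
    bw <- nnBackward(model@layers, fw$cache, inp$n, rep(1, inp$n),
                     gbp = TRUE)
    out[, , , idx] <- array(bw$dInput, c(d[1:3], inp$n))
  }
  relevanceSetFrom(out, "gbp", volumes)
}

#' Linear upsampling of a volume
#'
#' Separable linear interpolation along each axis (bilinear/trilinear),
#' used to bring a GradCAM map to input resolution.
#'
#' @param arr 3d numeric array.
#' @param outDim target dimensions `c(H, W, D)`.
#' @return resampled array.
#' @export
upsampleVolume <- function(arr, outDim) {
  for (ax in 1:3) {
    nIn <- dim(arr)[ax]
    nOut <- outDim[ax]
    if (nIn == nOut) next
    xin <- seq_len(nIn)
    xout <- (seq_len(nOut) - 0.5) * nIn / nOut + 0.5
    arr <- apply(arr, setdiff(1:3, ax), function(v)
      stats::approx(xin, v, xout, rule = 2)$y)
    # apply returns the interpolated axis first; restore axis order
    arr <- aperm(arr, order(c(ax, setdiff(1:3, ax))))
  }
  arr
}

#' Guided GradCAM
#'
#' Upsamples the GradCAM map to input resolution (linear interpolation) and
#' multiplies it elementwise with the guided-backpropagation gradient; the
#' result is nonnegative wherever the guided gradient is nonnegative.
#'
#' @inheritParams gradCam
#' @return a [RelevanceSet-class] with method `"ggcam"` at input resolution.
#' @export
guidedGradCam <- function(model, volumes, targetBlock = NULL,
                          batchSize = 16L) {
  gc <- gradCam(model, volumes, targetBlock, batchSize)
  gbp <- guidedBackprop(model, volumes, batchSize)
  d <- dim(gbp@values)
  dc <- dim(gc@values)
  up <- array(0, d)
  for (j in seq_len(d[4]))
    up[, , , j] <- upsampleVolume(array(gc@values[, , , j], dc[1:3]),
                                  d[1:3])
  relevanceSetFrom(up * gbp@values, "ggcam", gbp)
}
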