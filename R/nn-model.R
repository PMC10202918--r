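# CNN engine.
#
# Batched activations are stored as (N*S) x C matrices (S spatial positions
# per sample, rows sample-major, spatial index h + H*(w-1) + H*W*(d-1); see
# src/ops.cpp). A VolumeSet sample with one input channel maps onto this
# layout directly via as.vector().

#' Architecture configuration for the CNN classifier
#'
#' Describes the classifier: `length(convChannels)` blocks of convolution
#' (same padding, stride 1), batch normalization, ReLU and max pooling,
#' followed by a flatten, two fully connected ReLU layers of width
#' `fcWidth` and a single sigmoid output unit. In `"3d"` mode kernels are
#' 3x3x3 and pooling is 2x2x1 for the first block, then 2x2x2; in `"2d"`
#' mode kernels are 3x3 and all pooling is 2x2. The full-scale reference
#' configuration is `convChannels = c(64, 128, 256)`, `fcWidth = 512` on
#' 120x120x16 input; a desk-scale variant (`c(8, 16, 32)`, 32, 40x40x16) is
#' used for testing.
#'
#' @param mode `"3d"` or `"2d"`.
#' @param inputDim input array dimensions `c(H, W, D)`; in 2d mode D = 1.
#' @param convChannels output channels per conv block.
#' @param fcWidth width of the two fully connected layers.
#' @return a list of class `"cxArch"` with derived kernels, pool sizes and
#'   per-stage dimensions.
#' @export
archConfig <- function(mode = c("3d", "2d"), inputDim = c(120, 120, 16),
                       convChannels = c(64, 128, 256), fcWidth = 512) {
  mode <- match.arg(mode)
  if (mode == "2d") inputDim[3] <- 1L
  stopIfNot(length(inputDim) == 3 && all(inputDim >= 1),
            "inputDim must be c(H, W, D)")
  nb <- length(convChannels)
  stopIfNot(nb >= 1, "at least one conv block required")
  dims <- list(as.integer(inputDim))
  pools <- vector("list", nb)
  for (b in seq_len(nb)) {
    d <- dims[[b]]
    p <- if (mode == "2d") c(2L, 2L, 1L)
         else if (b == 1L) c(2L, 2L, 1L)
         else c(2L, 2L, if (d[3] >= 2L) 2L else 1L)
    if (any(d %% p != 0) || any(d %/% p < 1))
      stop("input too small for pooling depth (config error): stage ", b,
           " has dims ", paste(d, collapse = "x"), call. = FALSE)
    pools[[b]] <- p
    dims[[b + 1]] <- d %/% p
  }
  kernel <- c(3L, 3L, if (mode == "3d" && inputDim[3] > 1) 3L else 1L)
  structure(list(mode = mode, inputDim = as.integer(inputDim),
                 convChannels = as.integer(convChannels),
                 fcWidth = as.integer(fcWidth), kernel = kernel,
                 pools = pools, dims = dims),
            class = "cxArch")
}

#' Build a CNN classifier with Kaiming-initialized weights
#'
#' Weights are drawn from `N(0, 2/fanIn)` (Kaiming initialization for ReLU
#' networks); biases start at zero; batch normalization starts at identity.
#' Construction is deterministic given `seed`.
#'
#' @param arch an [archConfig()] list.
#' @param seed integer initialization seed.
#' @return a [CnnModel-class].
#' @examples
#' arch <- archConfig("3d", inputDim = c(8, 8, 4), convChannels = c(2, 3, 4),
#'                    fcWidth = 8)
#' m <- buildModel(arch, seed = 1)
#' countParameters(m)
#' @export
buildModel <- function(arch, seed = 1L) {
  stopIfNot(inherits(arch, "cxArch"), "arch must come from archConfig()")
  k <- arch$kernel
  K <- prod(k)
  layers <- list()
  withSeed(seed, {
    cin <- 1L
    for (b in seq_along(arch$convChannels)) {
      cout <- arch$convChannels[b]
      fanIn <- K * cin
      layers <- c(layers, list(
        list(type = "conv",
             W = matrix(stats::rnorm(K * cin * cout, 0, sqrt(2 / fanIn)),
                        K * cin, cout),
             b = numeric(cout), k = k, cin = cin, cout = cout,
             inDim = arch$dims[[b]]),
        list(type = "bn", gamma = rep(1, cout), beta = numeric(cout),
             runMean = numeric(cout), runVar = rep(1, cout),
             momentum = 0.1, eps = 1e-5),
        list(type = "relu"),
        list(type = "pool", p = arch$pools[[b]], inDim = arch$dims[[b]])))
      cin <- cout
    }
    dLast <- arch$dims[[length(arch$dims)]]
    flatIn <- prod(dLast) * cin
    layers <- c(layers, list(
      list(type = "flatten", inDim = dLast, C = cin)))
    widths <- c(flatIn, arch$fcWidth, arch$fcWidth, 1L)
    for (j in 1:3) {
      layers <- c(layers, list(
        list(type = "dense",
             W = matrix(stats::rnorm(widths[j] * widths[j + 1], 0,
                                     sqrt(2 / widths[j])),
                        widths[j], widths[j + 1]),
             b = numeric(widths[j + 1]))))
      if (j < 3) layers <- c(layers, list(list(type = "relu")))
    }
  })
  new("CnnModel", layers = layers, arch = unclass(arch),
      seed = as.integer(seed),
      log = data.frame(epoch = integer(), trainLoss = numeric(),
                       valAccuracy = numeric()))
}

#' @rdname cortexplain-generics
setMethod("countParameters", "CnnModel", function(x) {
  sum(vapply(x@layers, function(l) switch(l$type,
    conv = length(l$W) + length(l$b),
    bn = length(l$gamma) + length(l$beta),
    dense = length(l$W) + length(l$b),
    0L), 1)) |> as.integer()
})

# ---- forward / backward ----

nnFlattenFwd <- function(X, n, S, C) {
  matrix(aperm(array(X, c(S, n, C)), c(2, 1, 3)), nrow = n)
}

nnFlattenBwd <- function(dY, n, S, C) {
  matrix(aperm(array(dY, c(n, S, C)), c(2, 1, 3)), nrow = n * S, ncol = C)
}

# Forward pass over an (N*S) x 1 input matrix. Returns logits, a cache for
# backprop (when keepCache) and layers with updated batchnorm running stats
# (when train).
nnForward <- function(layers, X, n, train = FALSE, keepCache = FALSE) {
  cache <- if (keepCache) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      if (keepCache) cache[[i]] <- list(X = X)
      X <- .cxConvFwd(X, n, l$inDim[1], l$inDim[2], l$inDim[3],
                      l$k[1], l$k[2], l$k[3], l$W, l$b)
    } else if (l$type == "bn") {
      if (train) {
        mv <- .cxColMeanVar(X)
        m <- as.vector(mv$mean); v <- as.vector(mv$var)
        layers[[i]]$runMean <- (1 - l$momentum) * l$runMean + l$momentum * m
        layers[[i]]$runVar <- (1 - l$momentum) * l$runVar + l$momentum * v
      } else {
        m <- l$runMean; v <- l$runVar
      }
      invstd <- 1 / sqrt(v + l$eps)
      xhat <- .cxColAffine(X, invstd, -m * invstd)
      if (keepCache)
        cache[[i]] <- list(xhat = xhat, invstd = invstd, train = train)
      X <- .cxColAffine(xhat, l$gamma, l$beta)
    } else if (l$type == "relu") {
      X <- pmax(X, 0)
      if (keepCache) cache[[i]] <- list(out = X)
    } else if (l$type == "pool") {
      r <- .cxMaxPoolFwd(X, n, l$inDim[1], l$inDim[2], l$inDim[3],
                         l$p[1], l$p[2], l$p[3])
      if (keepCache) cache[[i]] <- list(idx = r$idx, nrowX = nrow(X))
      X <- r$Y
    } else if (l$type == "flatten") {
      if (keepCache) cache[[i]] <- list()
      X <- nnFlattenFwd(X, n, prod(l$inDim), l$C)
    } else if (l$type == "dense") {
      if (keepCache) cache[[i]] <- list(X = X)
      X <- sweep(X %*% l$W, 2, l$b, "+")
    }
  }
  list(logits = as.vector(X), layers = layers, cache = cache)
}

# Backward pass from a gradient on the logits. gbp switches the ReLU
# backward rule to the guided form (gate on both activation and incoming
# gradient). recordLayer (index) stops the pass and returns the gradient
# with respect to that layer's output.
nnBackward <- function(layers, cache, n, dLogit, gbp = FALSE,
                       recordLayer = NULL) {
  grads <- vector("list", length(layers))
  G <- matrix(dLogit, ncol = 1)
  recorded <- NULL
  for (i in rev(seq_along(layers))) {
    if (!is.null(recordLayer) && i == recordLayer) {
      recorded <- G
      break
    }
    l <- layers[[i]]
    if (l$type == "dense") {
      Xin <- cache[[i]]$X
      grads[[i]] <- list(dW = crossprod(Xin, G), db = colSums(G))
      G <- G %*% t(l$W)
    } else if (l$type == "flatten") {
      G <- nnFlattenBwd(G, n, prod(l$inDim), l$C)
    } else if (l$type == "pool") {
      G <- .cxMaxPoolBwd(G, cache[[i]]$idx, cache[[i]]$nrowX)
    } else if (l$type == "relu") {
      gate <- cache[[i]]$out > 0
      if (gbp) gate <- gate & (G > 0)
      G <- G * gate
    } else if (l$type == "bn") {
      # in eval mode the layer is a fixed affine map (no statistics terms)
      r <- .cxBnBwd(G, cache[[i]]$xhat, cache[[i]]$invstd, l$gamma,
                    isTRUE(cache[[i]]$train))
      grads[[i]] <- list(dgamma = as.vector(r$dgamma),
                         dbeta = as.vector(r$dbeta))
      G <- r$dX
    } else if (l$type == "conv") {
      r <- .cxConvBwd(cache[[i]]$X, G, n, l$inDim[1], l$inDim[2], l$inDim[3],
                      l$k[1], l$k[2], l$k[3], l$W, TRUE)
      grads[[i]] <- list(dW = r$dW, db = r$db)
      G <- r$dX
    }
  }
  list(grads = grads, dInput = G, recorded = recorded)
}

volumesToInput <- function(volumes, idx = NULL) {
  vals <- if (is(volumes, "VolumeSet")) volumes@values else volumes
  if (!is.null(idx)) vals <- vals[, , , idx, drop = FALSE]
  list(X = matrix(as.vector(vals), ncol = 1), n = dim(vals)[4])
}

#' Classifier output probabilities
#'
#' Runs the model in evaluation mode (fixed batch-normalization statistics;
#' the forward pass is deterministic) and returns the sigmoid output per
#' sample.
#'
#' @param model a trained [CnnModel-class].
#' @param volumes a [VolumeSet-class] or H x W x D x N array.
#' @param batchSize evaluation batch size.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predictModel <- function(model, volumes, batchSize = 64L) {
  vals <- if (is(volumes, "VolumeSet")) volumes@values else volumes
  n <- dim(vals)[4]
  out <- numeric(n)
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(n, start + batchSize - 1L)
    inp <- volumesToInput(vals, idx)
    out[idx] <- plogis(nnForward(model@layers, inp$X, inp$n)$logits)
  }
  out
}
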