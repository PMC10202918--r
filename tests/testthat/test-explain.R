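test_that("LRP-0 on a single linear layer returns w_j * x_j", {
  w <- c(0.5, -1.2, 2)
  m <- modelFromLayers(list(flattenLayer(c(3, 1, 1)),
                            denseLayer(matrix(w, 3, 1))),
                       inputDim = c(3, 1, 1))
  x <- c(1.5, 0.7, -0.3)
  vols <- volumeSetFrom(array(x, c(3, 1, 1, 1)))
  R <- relevanceArray(lrp(m, vols))
  expect_equal(as.vector(R), w * x, tolerance = 1e-6)
})

test_that("relevance is conserved on bias-free ReLU networks", {
  W1 <- matrix(c(1.2, -0.4, 0.3, 0.9, -1.1, 0.6), 2, 3)
  W2 <- matrix(c(0.8, -0.5, 1.4), 3, 1)
  m <- modelFromLayers(list(flattenLayer(c(2, 1, 1)),
                            denseLayer(W1), reluLayer(), denseLayer(W2)),
                       inputDim = c(2, 1, 1))
  for (x in list(c(1, 2), c(-1, 0.5), c(0.3, -2))) {
    vols <- volumeSetFrom(array(x, c(2, 1, 1, 1)))
    logit <- qlogis(predictModel(m, vols))
    R <- relevanceArray(lrp(m, vols, gamma = 0))
    expect_equal(sum(R), logit, tolerance = 1e-6)
  }
})

test_that("LRP matches a literal per-node oracle (LRP-gamma conv + LRP-0)", {
  set.seed(8)
  dims <- c(4, 4, 1)
  S <- prod(dims)
  k <- c(3, 3, 1)
  Wc <- matrix(rnorm(prod(k) * 2, 0, 0.6), prod(k), 2)
  bc <- c(0.1, -0.2)
  Wd <- matrix(rnorm(S * 2, 0, 0.4), S * 2, 1)
  bd <- 0.05
  m <- modelFromLayers(list(
    convLayer(Wc, k, 1, 2, dims, b = bc),
    reluLayer(),
    flattenLayer(dims, 2),
    denseLayer(Wd, bd)), inputDim = dims)
  x <- rnorm(S)
  vols <- volumeSetFrom(array(x, c(dims, 1)))
  gamma <- 0.25

  # oracle: materialize the convolution as an explicit affine map and apply
  # the propagation rule node by node
  M <- convAsMatrix(Wc, k, 1, 2, dims)
  bFull <- rep(bc, each = S)
  a1 <- as.vector(t(M) %*% x) + bFull
  a1r <- pmax(a1, 0)
  logit <- sum(a1r * Wd) + bd
  Rdense <- lrpAffineOracle(a1r, Wd, bd, logit, gamma = 0)
  Rin <- lrpAffineOracle(x, M, bFull, Rdense, gamma = gamma)

  R <- relevanceArray(lrp(m, vols, gamma = gamma))
  expect_equal(as.vector(R), Rin, tolerance = 1e-9)
})

test_that("batchnorm folding preserves the relevance map", {
  set.seed(9)
  dims <- c(4, 4, 1)
  k <- c(3, 3, 1)
  Wc <- matrix(rnorm(prod(k) * 2, 0, 0.5), prod(k), 2)
  bc <- c(0.2, -0.1)
  bn <- list(type = "bn", gamma = c(1.3, 0.7), beta = c(0.1, -0.3),
             runMean = c(0.05, -0.02), runVar = c(0.8, 1.4),
             momentum = 0.1, eps = 1e-5)
  Wd <- matrix(rnorm(prod(dims) * 2, 0, 0.4), prod(dims) * 2, 1)
  mBn <- modelFromLayers(list(
    convLayer(Wc, k, 1, 2, dims, b = bc), bn, reluLayer(),
    flattenLayer(dims, 2), denseLayer(Wd)), inputDim = dims)
  # manually folded equivalent
  sc <- bn$gamma / sqrt(bn$runVar + bn$eps)
  mFold <- modelFromLayers(list(
    convLayer(sweep(Wc, 2, sc, "*"), k, 1, 2, dims,
              b = (bc - bn$runMean) * sc + bn$beta),
    reluLayer(), flattenLayer(dims, 2), denseLayer(Wd)), inputDim = dims)
  vols <- volumeSetFrom(array(rnorm(prod(dims)), c(dims, 1)))
  expect_equal(predictModel(mBn, vols), predictModel(mFold, vols),
               tolerance = 1e-12)
  expect_equal(relevanceArray(lrp(mBn, vols)),
               relevanceArray(lrp(mFold, vols)), tolerance = 1e-12)
})

# one-block toy with identity batchnorm and 1x1x1 pooling: activations equal
# the input (center-tap kernels), which makes hand evaluation easy
toyConvNet <- function(dims, denseW, kcenters = 1) {
  S <- prod(dims)
  nmaps <- length(kcenters)
  k <- c(3, 3, 1)
  Wc <- matrix(0, prod(k), nmaps)
  Wc[5, ] <- kcenters          # center tap of a 3x3x1 kernel
  modelFromLayers(list(
    convLayer(Wc, k, 1, nmaps, dims),
    identityBnLayer(nmaps), reluLayer(), poolLayer(c(1, 1, 1), dims),
    flattenLayer(dims, nmaps), denseLayer(denseW)), inputDim = dims)
}

test_that("GradCAM: zero gradients and single-map closed forms", {
  dims <- c(4, 4, 1)
  S <- prod(dims)
  x <- cortexplain:::withSeed(10, runif(S, 0.2, 1))
  vols <- volumeSetFrom(array(x, c(dims, 1)))

  m0 <- toyConvNet(dims, matrix(0, S, 1))
  expect_equal(max(abs(relevanceArray(gradCam(m0, vols)))), 0)

  g0 <- 0.7
  m1 <- toyConvNet(dims, matrix(g0, S, 1))
  got <- relevanceArray(gradCam(m1, vols))[, , 1, 1]
  # A = x (identity block), every node's gradient is g0, so w = g0 and the
  # map is ReLU(g0 * A)
  bnScale <- 1            # identity batchnorm
  expect_equal(as.vector(got), pmax(g0 * x * bnScale, 0), tolerance = 1e-9)
})

test_that("GradCAM matches hand evaluation with two feature maps", {
  dims <- c(3, 3, 1)
  S <- prod(dims)
  set.seed(12)
  u1 <- rnorm(S); u2 <- rnorm(S)
  m <- toyConvNet(dims, matrix(c(u1, u2), 2 * S, 1), kcenters = c(1, 2))
  x <- runif(S, 0.2, 1)
  vols <- volumeSetFrom(array(x, c(dims, 1)))
  # activations: A1 = x, A2 = 2x (identity bn, ReLU open for positive x);
  # dy/dA^n = u_n, so w_n = mean(u_n), map = ReLU(w1 A1 + w2 A2)
  expected <- pmax(mean(u1) * x + mean(u2) * (2 * x), 0)
  got <- relevanceArray(gradCam(m, vols))[, , 1, 1]
  expect_equal(as.vector(got), expected, tolerance = 1e-9)
})

test_that("guided backpropagation gates at ReLU nodes", {
  mk <- function(a, b) modelFromLayers(list(
    flattenLayer(c(1, 1, 1)), denseLayer(matrix(a, 1, 1)), reluLayer(),
    denseLayer(matrix(b, 1, 1))), inputDim = c(1, 1, 1))

  # negative pre-activation: gradient blocked (plain BP too)
  volsNeg <- volumeSetFrom(array(-2, c(1, 1, 1, 1)))
  expect_equal(as.vector(relevanceArray(
    guidedBackprop(mk(1, 1), volsNeg))), 0)

  # positive activation but negative upstream gradient: GBP blocks it,
  # plain BP propagates a * b
  volsPos <- volumeSetFrom(array(2, c(1, 1, 1, 1)))
  m <- mk(1.5, -2)
  expect_equal(as.vector(relevanceArray(guidedBackprop(m, volsPos))), 0)
  inp <- cortexplain:::volumesToInput(volsPos@values)
  fw <- cortexplain:::nnForward(m@layers, inp$X, 1, keepCache = TRUE)
  bw <- cortexplain:::nnBackward(m@layers, fw$cache, 1, 1)
  expect_equal(as.vector(bw$dInput), 1.5 * -2)

  # all activations and upstream gradients positive: GBP == plain BP
  set.seed(13)
  dims <- c(4, 4, 1)
  S <- prod(dims)
  mPos <- toyConvNet(dims, matrix(runif(S, 0.1, 1), S, 1))
  vols <- volumeSetFrom(array(runif(S, 0.2, 1), c(dims, 1)))
  gbp <- relevanceArray(guidedBackprop(mPos, vols))
  inp <- cortexplain:::volumesToInput(vols@values)
  fw <- cortexplain:::nnForward(mPos@layers, inp$X, 1, keepCache = TRUE)
  bw <- cortexplain:::nnBackward(mPos@layers, fw$cache, 1, 1)
  expect_equal(as.vector(gbp), as.vector(bw$dInput), tolerance = 1e-12)
})

test_that("guided GradCAM composes its two constituents", {
  dims <- c(4, 4, 1)
  S <- prod(dims)
  set.seed(14)
  u <- rnorm(S)
  m <- toyConvNet(dims, matrix(u, S, 1))
  x <- runif(S, 0.2, 1)
  vols <- volumeSetFrom(array(x, c(dims, 1)))

  # oracle constituents: GradCAM map ReLU(mean(u) * x); GBP gradient is u
  # gated by the upstream sign (activations all positive, no pooling)
  cam <- pmax(mean(u) * x, 0)
  gbp <- u * (u > 0)
  got <- relevanceArray(guidedGradCam(m, vols))
  expect_equal(as.vector(got), cam * gbp, tolerance = 1e-9)

  # zero GradCAM map: zero GGCAM even where GBP is nonzero
  m0 <- toyConvNet(dims, matrix(0, S, 1))
  expect_equal(max(abs(relevanceArray(guidedGradCam(m0, vols)))), 0)
})

test_that("upsampling is linear and preserves constants", {
  arr <- array(3.3, c(2, 3, 2))
  up <- upsampleVolume(arr, c(6, 6, 4))
  expect_equal(dim(up), c(6, 6, 4))
  expect_equal(max(abs(up - 3.3)), 0, tolerance = 1e-12)
  a <- array(rnorm(8), c(2, 2, 2))
  b <- array(rnorm(8), c(2, 2, 2))
  expect_equal(upsampleVolume(a + 2 * b, c(4, 4, 2)),
               upsampleVolume(a, c(4, 4, 2)) +
                 2 * upsampleVolume(b, c(4, 4, 2)), tolerance = 1e-12)
})

test_that("all methods point at the single responding pixel", {
  dims <- c(4, 4, 1)
  S <- prod(dims)
  p <- 6L
  e <- numeric(S); e[p] <- 1
  m <- toyConvNet(dims, matrix(e, S, 1))
  x <- cortexplain:::withSeed(15, runif(S, 0.1, 0.5))
  x[p] <- 2
  vols <- volumeSetFrom(array(x, c(dims, 1)))
  for (fn in list(lrp, guidedBackprop, gradCam, guidedGradCam)) {
    R <- relevanceArray(fn(m, vols))
    expect_equal(which.max(abs(R)), p)
  }
})
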