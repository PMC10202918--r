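# Shared fixtures. Heavy objects are built once per test run and cached in
# this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

tinySurface <- function() fixture("tinySurface",
  function() makeSphereSurface(300, 8, seed = 11))

tinyMap <- function() fixture("tinyMap",
  function() mollweideMap(tinySurface(), gridSize = 24))

# Small cohort for generator-level checks (coarse sampling keeps it fast).
tinyCohort <- function() fixture("tinyCohort", function()
  simulateCohort(tinySurface(), effectSpec(delta = 0.5), nPerGroup = 4,
                 nTrials = 6, fsHz = 100, seed = 21))

# Wrap a hand-built layer list as a CnnModel (for oracle-sized networks).
modelFromLayers <- function(layers, inputDim, mode = "3d") {
  new("CnnModel", layers = layers, arch = list(mode = mode,
      inputDim = as.integer(inputDim), convChannels = integer(),
      fcWidth = 0L),
      seed = 0L, log = data.frame(epoch = integer(), trainLoss = numeric(),
                                  valAccuracy = numeric()))
}

denseLayer <- function(W, b = numeric(ncol(W)))
  list(type = "dense", W = W, b = b)

flattenLayer <- function(inDim, C = 1L)
  list(type = "flatten", inDim = as.integer(inDim), C = as.integer(C))

reluLayer <- function() list(type = "relu")

convLayer <- function(W, k, cin, cout, inDim, b = numeric(cout))
  list(type = "conv", W = W, b = b, k = as.integer(k), cin = as.integer(cin),
       cout = as.integer(cout), inDim = as.integer(inDim))

identityBnLayer <- function(cout)
  list(type = "bn", gamma = rep(1, cout), beta = numeric(cout),
       runMean = numeric(cout), runVar = rep(1 - 1e-5, cout),
       momentum = 0.1, eps = 1e-5)

poolLayer <- function(p, inDim)
  list(type = "pool", p = as.integer(p), inDim = as.integer(inDim))

# VolumeSet from a plain array.
volumeSetFrom <- function(vals, labels = NULL,
                          windows = NULL) {
  d <- dim(vals)
  if (is.null(labels)) labels <- rep("patient", d[4])
  if (is.null(windows))
    windows <- cbind(start = (seq_len(d[3]) - 1) * 50,
                     end = seq_len(d[3]) * 50)
  new("VolumeSet", values = vals, labels = labels,
      subjectId = sprintf("s%02d", seq_len(d[4])),
      trialId = seq_len(d[4]), windows = windows, mode = "3d",
      mask = matrix(TRUE, d[1], d[2]))
}

relevanceSetFromArray <- function(vals, method = "lrp", labels = NULL) {
  d <- dim(vals)
  if (is.null(labels)) labels <- rep("patient", d[4])
  new("RelevanceSet", values = vals, method = method,
      subjectId = sprintf("s%02d", seq_len(d[4])),
      trialId = seq_len(d[4]), labels = labels)
}

# Materialize a same-padded stride-1 convolution as an explicit affine map
# (loop-based, independent of the package's im2col kernels). Returns the
# (S*Cin) x (S*Cout) matrix M with out = M' %*% in ordering matching the
# engine's (spatial-major, then channel) layout.
convAsMatrix <- function(Wmat, k, cin, cout, dims) {
  H <- dims[1]; W <- dims[2]; D <- dims[3]
  S <- H * W * D
  K <- prod(k)
  M <- matrix(0, S * cin, S * cout)
  r <- (k - 1) %/% 2
  for (d in 1:D) for (w in 1:W) for (h in 1:H) {
    s <- h + H * (w - 1) + H * W * (d - 1)
    for (id in 1:k[3]) for (iw in 1:k[2]) for (ih in 1:k[1]) {
      hh <- h + ih - 1 - r[1]; ww <- w + iw - 1 - r[2]
      dd <- d + id - 1 - r[3]
      if (hh < 1 || hh > H || ww < 1 || ww > W || dd < 1 || dd > D) next
      src <- hh + H * (ww - 1) + H * W * (dd - 1)
      o <- (ih - 1) + k[1] * (iw - 1) + k[1] * k[2] * (id - 1)
      for (ci in 1:cin) for (co in 1:cout)
        M[src + S * (ci - 1), s + S * (co - 1)] <-
          M[src + S * (ci - 1), s + S * (co - 1)] +
          Wmat[o + 1 + K * (ci - 1), co]
    }
  }
  M
}

# Literal, per-node relevance propagation through one affine layer
# (numerator z_jk = a_j * Wmod_jk; denominator includes the rule-modified
# bias; epsilon-stabilized).
lrpAffineOracle <- function(a, M, b, R, gamma = 0, eps = 1e-9) {
  Wm <- M + gamma * pmax(M, 0)
  bm <- b + gamma * pmax(b, 0)
  Rout <- numeric(length(a))
  for (kk in seq_along(R)) {
    z <- a * Wm[, kk]
    den <- sum(z) + bm[kk]
    den <- den + eps * ifelse(den >= 0, 1, -1)
    Rout <- Rout + z / den * R[kk]
  }
  Rout
}
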