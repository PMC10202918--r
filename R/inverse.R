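#' Project source activity to the sensors
#'
#' Forward step `y = G x + noise` used to exercise the inverse stage on
#' synthetic data.
#'
#' @param sources a [SourceTrialSet-class] or a trials x vertices x time
#'   array.
#' @param leadField a [LeadField-class]; its vertex count must match.
#' @param sensorNoiseSd SD of additive Gaussian sensor noise (0 for none).
#' @param seed integer seed for the sensor noise.
#' @return trials x channels x time array.
#' @export
projectToSensors <- function(sources, leadField, sensorNoiseSd = 0,
                             seed = 1L) {
  dat <- if (is(sources, "SourceTrialSet")) trialData(sources) else sources
  stopIfNot(length(dim(dat)) == 3, "sources must be trials x vertices x time")
  G <- gainMatrix(leadField)
  stopIfNot(dim(dat)[2] == ncol(G),
            "vertex count of sources and lead field must match")
  nTr <- dim(dat)[1]; nt <- dim(dat)[3]; nc <- nrow(G)
  out <- array(0, c(nTr, nc, nt))
  withSeed(seed, {
    for (tr in seq_len(nTr)) {
      y <- G %*% dat[tr, , ]
      if (sensorNoiseSd > 0)
        y <- y + sensorNoiseSd * matrix(stats::rnorm(nc * nt), nc, nt)
      out[tr, , ] <- y
    }
  })
  out
}

#' Weighted minimum-norm inverse kernel
#'
#' Builds the linear inverse operator
#' `K = W G' (G W G' + lambda I)^(-1)` with diagonal depth weights
#' `W_jj = ||g_j||^(-2 * depthExponent)`. When `lambda` is `NULL` it is set
#' from a target signal-to-noise ratio by the common heuristic
#' `lambda = trace(G W G') / (nChannels * snr^2)`.
#'
#' @param leadField a [LeadField-class].
#' @param lambda nonnegative regularization parameter, or `NULL` to derive
#'   it from `snr`.
#' @param depthExponent depth-weighting exponent (default 0.5).
#' @param snr assumed amplitude SNR used when `lambda` is `NULL` (default 3).
#' @return list with `kernel` (vertices x channels), `lambda`,
#'   `depthExponent`.
#' @export
wmneKernel <- function(leadField, lambda = NULL, depthExponent = 0.5,
                       snr = 3) {
  G <- gainMatrix(leadField)
  w <- colSums(G^2)^(-depthExponent)
  GW <- sweep(G, 2, w, "*")          # G W
  A <- GW %*% t(G)                   # G W G'
  if (is.null(lambda)) lambda <- sum(diag(A)) / (nrow(G) * snr^2)
  stopIfNot(lambda >= 0, "lambda must be >= 0")
  Ar <- A + diag(lambda, nrow(G))
  inv <- tryCatch(solve(Ar), error = function(e)
    stop("singular sensor covariance; increase lambda (got lambda = ",
         lambda, ")", call. = FALSE))
  list(kernel = t(GW) %*% inv, lambda = lambda,
       depthExponent = depthExponent)
}

#' Weighted minimum-norm source estimate
#'
#' Applies the wMNE kernel to sensor data, per time sample; the estimator is
#' linear in the data.
#'
#' @param sensors trials x channels x time array (or channels x time matrix
#'   for a single trial).
#' @param leadField a [LeadField-class].
#' @inheritParams wmneKernel
#' @return trials x vertices x time array (matrix input gives a matrix).
#' @export
wmneInverse <- function(sensors, leadField, lambda = NULL,
                        depthExponent = 0.5, snr = 3) {
  K <- wmneKernel(leadField, lambda, depthExponent, snr)$kernel
  if (is.matrix(sensors)) return(K %*% sensors)
  stopIfNot(length(dim(sensors)) == 3,
            "sensors must be trials x channels x time")
  nTr <- dim(sensors)[1]; nt <- dim(sensors)[3]
  out <- array(0, c(nTr, nrow(K), nt))
  for (tr in seq_len(nTr)) out[tr, , ] <- K %*% sensors[tr, , ]
  out
}
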