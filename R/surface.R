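#' Construct a near-uniform spherical surface with region labels
#'
#' Places `nVertices` points on the unit sphere as a Fibonacci lattice and
#' partitions them into `nRegions` spherical Voronoi cells around a set of
#' seed directions (a coarse Fibonacci lattice under a seeded random
#' rotation). Stands in for a registered cortical surface: the desk-scale
#' default is 2,000 vertices; 15,002 is supported.
#'
#' @param nVertices number of surface vertices (>= nRegions).
#' @param nRegions number of regions (>= 1).
#' @param seed integer seed controlling the region layout.
#' @return a [SurfaceGeometry-class].
#' @examples
#' surf <- makeSphereSurface(500, 8, seed = 1)
#' table(regionLabels(surf))
#' @export
makeSphereSurface <- function(nVertices, nRegions = 8L, seed = 1L) {
  stopIfNot(length(nVertices) == 1 && nVertices >= 1,
            "nVertices must be a positive integer")
  stopIfNot(length(nRegions) == 1 && nRegions >= 1,
            "nRegions must be a positive integer")
  stopIfNot(nVertices >= nRegions, "nVertices must be >= nRegions")
  v <- fibonacciSphere(as.integer(nVertices))
  if (nRegions == 1L) {
    reg <- rep(1L, nrow(v))
  } else {
    seeds <- withSeed(seed, fibonacciSphere(as.integer(nRegions)) %*%
                        t(randomRotation()))
    reg <- max.col(v %*% t(seeds), ties.method = "first")
  }
  new("SurfaceGeometry", vertices = v, regions = as.integer(reg))
}

#' Construct a smooth synthetic lead field
#'
#' Builds a channels x vertices gain matrix in which each channel's
#' sensitivity decays smoothly with angular distance from its site on the
#' sphere: `gain[c, j] = exp((site_c . v_j - 1) / kappa)`. Channel sites are
#' a coarse Fibonacci lattice under a seeded random rotation. A synthetic
#' stand-in for a boundary-element forward model.
#'
#' @param surface a [SurfaceGeometry-class].
#' @param nChannels number of sensor channels (>= 2).
#' @param seed integer seed controlling the channel layout.
#' @param kappa angular decay scale of the sensitivity profile.
#' @return a [LeadField-class].
#' @examples
#' surf <- makeSphereSurface(100, 4, seed = 1)
#' lf <- makeLeadField(surf, 16, seed = 1)
#' dim(gainMatrix(lf))
#' @export
makeLeadField <- function(surface, nChannels, seed = 1L, kappa = 0.5) {
  stopIfNot(is(surface, "SurfaceGeometry"), "surface must be a SurfaceGeometry")
  stopIfNot(length(nChannels) == 1 && nChannels >= 2,
            "nChannels must be >= 2")
  sites <- withSeed(seed, fibonacciSphere(as.integer(nChannels)) %*%
                      t(randomRotation()))
  gain <- exp((sites %*% t(vertexCoords(surface)) - 1) / kappa)
  new("LeadField", gain = unname(gain), sites = sites)
}
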