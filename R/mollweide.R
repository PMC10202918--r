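#' Mollweide projection of spherical coordinates
#'
#' Maps latitude/longitude (radians) to the 2:1 Mollweide ellipse,
#' `x in [-2*sqrt(2), 2*sqrt(2)]`, `y in [-sqrt(2), sqrt(2)]`. The auxiliary
#' angle solves `2*theta + sin(2*theta) = pi * sin(lat)` by Newton iteration
#' to 1e-12 (poles handled analytically), then
#' `x = (2*sqrt(2)/pi) * lon * cos(theta)`, `y = sqrt(2) * sin(theta)`.
#'
#' @param latRad latitude(s) in \[-pi/2, pi/2\].
#' @param lonRad longitude(s) in \[-pi, pi\].
#' @return matrix with columns `x`, `y`.
#' @examples
#' mollweideXY(0, 0)          # centre
#' mollweideXY(pi / 2, 1)     # pole -> (0, sqrt(2))
#' mollweideXY(0, pi)         # equator edge -> (2*sqrt(2), 0)
#' @export
mollweideXY <- function(latRad, lonRad) {
  stopIfNot(all(abs(latRad) <= pi / 2 + 1e-12),
            "latitude must lie in [-pi/2, pi/2]")
  stopIfNot(all(abs(lonRad) <= pi + 1e-12),
            "longitude must lie in [-pi, pi]")
  n <- max(length(latRad), length(lonRad))
  lat <- rep_len(latRad, n); lon <- rep_len(lonRad, n)
  theta <- lat
  pole <- abs(abs(lat) - pi / 2) < 1e-12
  theta[pole] <- sign(lat[pole]) * pi / 2
  act <- which(!pole)
  if (length(act)) {
    target <- pi * sin(lat[act])
    th <- lat[act]
    for (it in 1:100) {
      f <- 2 * th + sin(2 * th) - target
      th <- th - f / (2 + 2 * cos(2 * th))
      if (max(abs(f)) < 1e-12) break
    }
    theta[act] <- th
  }
  cbind(x = 2 * sqrt(2) / pi * lon * cos(theta), y = sqrt(2) * sin(theta))
}

#' Precompute the sphere-to-grid projection of a surface
#'
#' Projects the surface vertices through the Mollweide map (latitude from
#' the z coordinate, longitude from `atan2(y, x)`) and precomputes a sparse
#' interpolation operator from vertex values onto an equally spaced
#' `gridSize x gridSize` grid over the ellipse's bounding box: each
#' in-ellipse pixel takes an inverse-squared-distance weighted average of
#' its `knn` nearest projected vertices (weights sum to one, so constants
#' are reproduced exactly); off-ellipse pixels are zero. Grid rows run top
#' (`y = +sqrt(2)`) to bottom, columns left (`x = -2*sqrt(2)`) to right.
#'
#' The map depends only on the geometry and is computed once per surface
#' and grid size.
#'
#' @param surface a [SurfaceGeometry-class].
#' @param gridSize grid side length (default 120).
#' @param knn neighbours per pixel for the interpolation (default 4).
#' @return a [MollweideMap-class].
#' @export
mollweideMap <- function(surface, gridSize = 120L, knn = 4L) {
  stopIfNot(gridSize >= 2, "gridSize must be >= 2")
  v <- vertexCoords(surface)
  lat <- asin(pmin(1, pmax(-1, v[, 3])))
  lon <- atan2(v[, 2], v[, 1])
  xy <- mollweideXY(lat, lon)
  G <- as.integer(gridSize)
  px <- -2 * sqrt(2) + (seq_len(G) - 0.5) * (4 * sqrt(2) / G)  # columns
  py <- sqrt(2) - (seq_len(G) - 0.5) * (2 * sqrt(2) / G)       # rows
  cx <- rep(px, each = G)   # column-major linear index: row + (col-1)*G
  cy <- rep(py, times = G)
  inEll <- (cx / (2 * sqrt(2)))^2 + (cy / sqrt(2))^2 <= 1
  pix <- which(inEll)
  k <- min(as.integer(knn), nrow(xy))
  nn <- knnIndex(cbind(cx[pix], cy[pix]), xy, k)
  d2 <- matrix(0, length(pix), k)
  for (j in seq_len(k))
    d2[, j] <- (cx[pix] - xy[nn[, j], 1])^2 + (cy[pix] - xy[nn[, j], 2])^2
  w <- 1 / (d2 + 1e-12)
  w <- w / rowSums(w)
  proj <- Matrix::sparseMatrix(i = rep(pix, k), j = as.vector(nn),
                               x = as.vector(w),
                               dims = c(G * G, nrow(xy)))
  pixelRegion <- rep(NA_integer_, G * G)
  pixelRegion[pix] <- regionLabels(surface)[nn[, 1]]
  col <- pmin(G, pmax(1L, ceiling((xy[, 1] + 2 * sqrt(2)) / (4 * sqrt(2) / G))))
  row <- pmin(G, pmax(1L, ceiling((sqrt(2) - xy[, 2]) / (2 * sqrt(2) / G))))
  new("MollweideMap", xy = xy, gridSize = G,
      mask = matrix(inEll, G, G), proj = proj,
      pixelRegion = pixelRegion,
      vertexPixel = as.integer(row + (col - 1L) * G))
}

#' Interpolate per-vertex values onto the grid
#'
#' @param map a [MollweideMap-class].
#' @param vertexValues numeric vector, one value per surface vertex.
#' @return a `gridSize x gridSize` image matrix (0 outside the ellipse).
#' @export
gridProject <- function(map, vertexValues) {
  stopIfNot(length(vertexValues) == nrow(map@xy),
            "one value per vertex required")
  matrix(as.vector(map@proj %*% vertexValues), map@gridSize, map@gridSize)
}

#' Standardize an image over the in-ellipse pixels
#'
#' Converts in-ellipse pixel intensities to z-scores (mean 0, SD 1 over the
#' ellipse); off-ellipse pixels stay 0. A constant image (SD 0) maps to all
#' zeros. Idempotent.
#'
#' @param image a grid image matrix.
#' @param mask logical in-ellipse mask of the same shape.
#' @return the standardized image.
#' @export
standardizeImage <- function(image, mask) {
  v <- image[mask]
  s <- stats::sd(v)
  out <- matrix(0, nrow(image), ncol(image))
  if (is.finite(s) && s > 1e-12) out[mask] <- (v - mean(v)) / s
  out
}

#' Grid footprint of a surface region
#'
#' The set of in-ellipse pixels whose nearest projected vertex belongs to
#' `regionId` — the projected region-of-interest mask used for ROI time
#' courses and localization scoring.
#'
#' @param map a [MollweideMap-class].
#' @param regionId a region id.
#' @return logical `gridSize x gridSize` mask.
#' @export
roiGridMask <- function(map, regionId) {
  m <- matrix(!is.na(map@pixelRegion) & map@pixelRegion == regionId,
              map@gridSize, map@gridSize)
  stopIfNot(any(m), sprintf("region %s has an empty grid footprint", regionId))
  m
}
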