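#' SurfaceGeometry: vertices on a registered unit sphere
#'
#' Holds a near-uniform point set on the unit sphere together with a
#' partition of the vertices into contiguous regions (spherical Voronoi cells
#' of a set of seed directions). Stands in for a registered cortical surface;
#' the default desk-scale resolution is 2,000 vertices and the full-scale
#' 15,002-vertex configuration is supported.
#'
#' @slot vertices numeric matrix, one unit 3-vector per row.
#' @slot regions integer vector, one region id per vertex.
#'
#' @seealso [makeSphereSurface()]
#' @export
setClass("SurfaceGeometry",
  representation(vertices = "matrix", regions = "integer"))

setValidity("SurfaceGeometry", function(object) {
  v <- object@vertices
  if (ncol(v) != 3L) return("vertices must be an n x 3 matrix")
  if (length(object@regions) != nrow(v))
    return("one region id per vertex required")
  nrm <- sqrt(rowSums(v^2))
  if (any(abs(nrm - 1) > 1e-9))
    return("all vertices must lie on the unit sphere (|norm - 1| <= 1e-9)")
  if (anyNA(object@regions)) return("region ids must not be NA")
  TRUE
})

#' LeadField: linear source-to-sensor gain
#'
#' A smooth synthetic gain matrix mapping source amplitudes at surface
#' vertices to sensor measurements; channel sensitivity decays with angular
#' distance from the channel site.
#'
#' @slot gain numeric matrix, channels x vertices.
#' @slot sites numeric matrix of channel site unit vectors, channels x 3.
#'
#' @seealso [makeLeadField()]
#' @export
setClass("LeadField", representation(gain = "matrix", sites = "matrix"))

setValidity("LeadField", function(object) {
  if (nrow(object@sites) != nrow(object@gain))
    return("one site per channel required")
  if (!all(is.finite(object@gain))) return("gain must be finite")
  if (any(colSums(abs(object@gain)) == 0))
    return("gain must have no all-zero column")
  TRUE
})

#' EffectSpec: planted spatiotemporal group effect
#'
#' Describes the evoked components of the synthetic cohort and the planted
#' group difference: in the patient group, the amplitude of every component
#' whose region equals `roiRegion` is multiplied by `delta` (a multiplicative
#' attenuation in \[0, 1\]; `delta = 1` plants no effect).
#'
#' @slot roiRegion integer region id carrying the planted effect.
#' @slot windowMs numeric length-2, the planted latency window (ms).
#' @slot delta numeric in \[0, 1\], patient-group amplitude multiplier.
#' @slot components data.frame with columns `region`, `latencyMs`, `widthMs`,
#'   `amplitude`: Gaussian-envelope evoked components.
#' @slot noiseSd numeric, per-vertex SD of the spatially correlated background.
#' @slot subjectSd numeric, SD of the per-subject amplitude factor around 1.
#' @slot trialSd numeric, SD of the per-trial multiplicative amplitude jitter.
#' @slot noiseKnn integer, neighbourhood size of the spatial noise smoother.
#'
#' @seealso [effectSpec()], [simulateCohort()]
#' @export
setClass("EffectSpec",
  representation(roiRegion = "integer", windowMs = "numeric",
                 delta = "numeric", components = "data.frame",
                 noiseSd = "numeric", subjectSd = "numeric",
                 trialSd = "numeric", noiseKnn = "integer"))

setValidity("EffectSpec", function(object) {
  if (length(object@delta) != 1 || object@delta < 0 || object@delta > 1)
    return("delta must be a single value in [0, 1]")
  if (length(object@windowMs) != 2 || diff(object@windowMs) <= 0)
    return("windowMs must be (start, end) with start < end")
  need <- c("region", "latencyMs", "widthMs", "amplitude")
  if (!all(need %in% names(object@components)))
    return("components needs columns region/latencyMs/widthMs/amplitude")
  TRUE
})

#' SourceTrialSet: one subject's trial-wise source activity
#'
#' Trials x vertices x time array of cortical current density (arbitrary
#' units) with epoch timing metadata.
#'
#' @slot data numeric array, trials x vertices x time.
#' @slot tStartMs,tEndMs epoch bounds in ms relative to target onset.
#' @slot fsHz sampling rate in Hz.
#' @slot subjectId character scalar.
#' @slot group `"control"` or `"patient"`.
#'
#' @seealso [subjectTrials()]
#' @export
setClass("SourceTrialSet",
  representation(data = "array", tStartMs = "numeric", tEndMs = "numeric",
                 fsHz = "numeric", subjectId = "character",
                 group = "character"))

setValidity("SourceTrialSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3) return("data must be trials x vertices x time")
  nt <- round((object@tEndMs - object@tStartMs) / 1000 * object@fsHz)
  if (d[3] != nt)
    return(sprintf("time axis must have (tEnd-tStart)/1000*fs = %d samples", nt))
  if (!object@group %in% c("control", "patient"))
    return("group must be 'control' or 'patient'")
  TRUE
})

#' SourceCohort: a simulated two-group cohort
#'
#' Holds the surface, the per-subject metadata table (group, ground-truth
#' amplitude factor `aS`, clinical scores) and the generator parameters.
#' Trial data are materialized on demand with [subjectTrials()] from
#' per-trial seeds derived from the cohort seed, so identical seeds yield
#' bit-identical cohorts without holding the full trial array in memory.
#'
#' @slot surface a [SurfaceGeometry-class].
#' @slot meta data.frame with one row per subject (`subjectId`, `group`,
#'   `aS`, `nTrials`, optional score columns).
#' @slot spec an [EffectSpec-class].
#' @slot fsHz,tStartMs,tEndMs epoch definition.
#' @slot seed integer cohort seed.
#' @slot smoother sparse spatial smoothing operator for the background noise.
#'
#' @seealso [simulateCohort()]
#' @export
setClass("SourceCohort",
  representation(surface = "SurfaceGeometry", meta = "data.frame",
                 spec = "EffectSpec", fsHz = "numeric", tStartMs = "numeric",
                 tEndMs = "numeric", seed = "integer", smoother = "ANY"))

#' MollweideMap: fixed sphere-to-grid projection
#'
#' Precomputed Mollweide projection of a surface onto a `gridSize` x
#' `gridSize` plane: per-vertex planar coordinates, the in-ellipse pixel
#' mask, a sparse interpolation operator from vertex values to pixels, and
#' the per-pixel dominant region id (used for region footprints).
#'
#' @slot xy numeric matrix of projected vertex coordinates,
#'   x in \[-2*sqrt(2), 2*sqrt(2)\], y in \[-sqrt(2), sqrt(2)\].
#' @slot gridSize integer grid side length (default 120).
#' @slot mask logical gridSize x gridSize in-ellipse pixel mask.
#' @slot proj sparse (gridSize^2) x nVertices interpolation matrix.
#' @slot pixelRegion integer vector of per-pixel region ids (NA off-ellipse).
#' @slot vertexPixel integer vector, the grid pixel nearest to each vertex.
#'
#' @seealso [mollweideMap()], [gridProject()]
#' @export
setClass("MollweideMap",
  representation(xy = "matrix", gridSize = "integer", mask = "matrix",
                 proj = "ANY", pixelRegion = "integer",
                 vertexPixel = "integer"))

setValidity("MollweideMap", function(object) {
  x <- object@xy[, 1]; y <- object@xy[, 2]
  if (any((x / (2 * sqrt(2)))^2 + (y / sqrt(2))^2 > 1 + 1e-9))
    return("projected vertices must lie inside the 2:1 Mollweide ellipse")
  TRUE
})

#' VolumeSet: standardized CNN input volumes
#'
#' A batch of standardized image volumes: `gridSize x gridSize x nBins` per
#' sample (16 bins of 50 ms covering 0-800 ms in 3d mode; one 200-350 ms
#' frame in 2d mode), with subject/trial/label provenance.
#'
#' @slot values numeric array H x W x D x N.
#' @slot labels character vector of `"control"`/`"patient"` per sample.
#' @slot subjectId character vector per sample.
#' @slot trialId integer vector per sample.
#' @slot windows numeric D x 2 matrix of (startMs, endMs) per frame.
#' @slot mode `"3d"` or `"2d"`.
#' @slot mask logical in-ellipse pixel mask shared by all frames.
#'
#' @seealso [buildVolume()], [cohortVolumes()]
#' @export
setClass("VolumeSet",
  representation(values = "array", labels = "character",
                 subjectId = "character", trialId = "integer",
                 windows = "matrix", mode = "character", mask = "matrix"))

setValidity("VolumeSet", function(object) {
  d <- dim(object@values)
  if (length(d) != 4) return("values must be H x W x D x N")
  if (nrow(object@windows) != d[3])
    return("one (start, end) window per frame required")
  n <- d[4]
  if (length(object@labels) != n || length(object@subjectId) != n ||
      length(object@trialId) != n)
    return("labels/subjectId/trialId must have one entry per sample")
  TRUE
})

#' CnnModel: a 2d/3d convolutional classifier
#'
#' The classifier used throughout the package: repeated blocks of
#' convolution, batch normalization, ReLU and max pooling, followed by two
#' fully connected ReLU layers and a single sigmoid output unit. Built by
#' [buildModel()]; layers are stored as an ordered list of parameter
#' bundles and consumed by the training and explainability routines.
#'
#' @slot layers list of layer descriptors (internal representation).
#' @slot arch the architecture configuration list (see [archConfig()]).
#' @slot seed integer initialization seed.
#' @slot log data.frame training log (one row per epoch), empty before
#'   training.
#'
#' @seealso [buildModel()], [pretrain()], [fineTune()]
#' @export
setClass("CnnModel",
  representation(layers = "list", arch = "list", seed = "integer",
                 log = "data.frame"))

#' RelevanceSet: heatmaps aligned with input volumes
#'
#' Relevance/importance maps with the same shape as the input volumes they
#' explain, tagged with the attribution method and sample provenance.
#'
#' @slot values numeric array H x W x D x N.
#' @slot method one of `"lrp"`, `"gradcam"`, `"gbp"`, `"ggcam"`.
#' @slot subjectId,trialId,labels provenance vectors copied from the inputs.
#'
#' @seealso [lrp()], [guidedGradCam()]
#' @export
setClass("RelevanceSet",
  representation(values = "array", method = "character",
                 subjectId = "character", trialId = "integer",
                 labels = "character"))

setValidity("RelevanceSet", function(object) {
  if (!object@method %in% c("lrp", "gradcam", "gbp", "ggcam"))
    return("method must be one of lrp/gradcam/gbp/ggcam")
  if (!all(is.finite(object@values))) return("relevance values must be finite")
  if (object@method == "gradcam" && min(object@values) < -1e-9)
    return("gradcam values must be nonnegative")
  TRUE
})

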