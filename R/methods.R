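# Accessor and show methods for the package classes.


#' @rdname cortexplain-generics
#' @aliases nVertices,SurfaceGeometry-method
setMethod("nVertices", "SurfaceGeometry", function(x) nrow(x@vertices))

#' @rdname cortexplain-generics
setMethod("vertexCoords", "SurfaceGeometry", function(x) x@vertices)

#' @rdname cortexplain-generics
setMethod("regionLabels", "SurfaceGeometry", function(x) x@regions)

#' @rdname cortexplain-generics
setMethod("gainMatrix", "LeadField", function(x) x@gain)

#' @rdname cortexplain-generics
setMethod("channelSites", "LeadField", function(x) x@sites)

#' @rdname cortexplain-generics
setMethod("cohortMeta", "SourceCohort", function(x) x@meta)

#' @rdname cortexplain-generics
setMethod("cohortSurface", "SourceCohort", function(x) x@surface)

#' @rdname cortexplain-generics
setMethod("subjectIds", "SourceCohort", function(x) x@meta$subjectId)

#' @rdname cortexplain-generics
setMethod("subjectIds", "VolumeSet", function(x) x@subjectId)

#' @rdname cortexplain-generics
setMethod("trialData", "SourceTrialSet", function(x) x@data)

#' @rdname cortexplain-generics
setMethod("samplingRate", "SourceTrialSet", function(x) x@fsHz)

#' @rdname cortexplain-generics
setMethod("samplingRate", "SourceCohort", function(x) x@fsHz)

#' @rdname cortexplain-generics
setMethod("epochBounds", "SourceTrialSet",
          function(x) c(x@tStartMs, x@tEndMs))

#' @rdname cortexplain-generics
setMethod("epochBounds", "SourceCohort",
          function(x) c(x@tStartMs, x@tEndMs))

#' @rdname cortexplain-generics
setMethod("gridSize", "MollweideMap", function(x) x@gridSize)

#' @rdname cortexplain-generics
setMethod("ellipseMask", "MollweideMap", function(x) x@mask)

#' @rdname cortexplain-generics
setMethod("ellipseMask", "VolumeSet", function(x) x@mask)

#' @rdname cortexplain-generics
setMethod("volumeArray", "VolumeSet", function(x) x@values)

#' @rdname cortexplain-generics
setMethod("volumeLabels", "VolumeSet", function(x) x@labels)

#' @rdname cortexplain-generics
setMethod("volumeWindows", "VolumeSet", function(x) x@windows)

#' @rdname cortexplain-generics
setMethod("nSamples", "VolumeSet", function(x) dim(x@values)[4])

#' @rdname cortexplain-generics
setMethod("nSamples", "RelevanceSet", function(x) dim(x@values)[4])

#' @rdname cortexplain-generics
setMethod("relevanceArray", "RelevanceSet", function(x) x@values)

#' @rdname cortexplain-generics
setMethod("relevanceMethod", "RelevanceSet", function(x) x@method)

#' @rdname cortexplain-generics
setMethod("volumeLabels", "RelevanceSet", function(x) x@labels)

# ---- show methods ----

setMethod("show", "SurfaceGeometry", function(object) {
  cat(sprintf("SurfaceGeometry: %d unit-sphere vertices, %d regions\n",
              nrow(object@vertices), length(unique(object@regions))))
})

setMethod("show", "LeadField", function(object) {
  cat(sprintf("LeadField: %d channels x %d vertices\n",
              nrow(object@gain), ncol(object@gain)))
})

setMethod("show", "EffectSpec", function(object) {
  cat(sprintf(
    "EffectSpec: delta = %.2f on region %d in %g-%g ms; %d evoked component(s)\n",
    object@delta, object@roiRegion, object@windowMs[1], object@windowMs[2],
    nrow(object@components)))
})

setMethod("show", "SourceTrialSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "SourceTrialSet '%s' (%s): %d trials x %d vertices x %d samples, %g Hz, %g..%g ms\n",
    object@subjectId, object@group, d[1], d[2], d[3], object@fsHz,
    object@tStartMs, object@tEndMs))
})

setMethod("show", "SourceCohort", function(object) {
  tab <- table(object@meta$group)
  cat(sprintf(
    "SourceCohort: %s; %d trials/subject, %d vertices, %g Hz, %g..%g ms, seed %d\n",
    paste(sprintf("%d %s", tab, names(tab)), collapse = " + "),
    object@meta$nTrials[1], nVertices(object@surface), object@fsHz,
    object@tStartMs, object@tEndMs, object@seed))
})

setMethod("show", "MollweideMap", function(object) {
  cat(sprintf("MollweideMap: %d vertices -> %dx%d grid (%d in-ellipse pixels)\n",
              nrow(object@xy), object@gridSize, object@gridSize,
              sum(object@mask)))
})

setMethod("show", "VolumeSet", function(object) {
  d <- dim(object@values)
  cat(sprintf("VolumeSet (%s): %d samples of %dx%dx%d (%s)\n",
              object@mode, d[4], d[1], d[2], d[3],
              paste(sprintf("%d %s", table(object@labels),
                            names(table(object@labels))), collapse = " + ")))
})

setMethod("show", "CnnModel", function(object) {
  cat(sprintf(
    "CnnModel (%s): input %s, conv channels [%s], fc width %d, %s parameters%s\n",
    object@arch$mode, paste(object@arch$inputDim, collapse = "x"),
    paste(object@arch$convChannels, collapse = ", "), object@arch$fcWidth,
    format(countParameters(object), big.mark = ","),
    if (nrow(object@log)) sprintf(" (trained %d epochs)", max(object@log$epoch))
    else " (untrained)"))
})

setMethod("show", "RelevanceSet", function(object) {
  d <- dim(object@values)
  cat(sprintf("RelevanceSet (%s): %d heatmaps of %dx%dx%d\n",
              object@method, d[4], d[1], d[2], d[3]))
})
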