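#' @name cortexplain-generics
#' @title Accessor generics
#'
#' @description Accessor generics for the package's S4 containers. Each class
#' documents which accessors apply to it.
#'
#' @param x an object.
#' @return The accessed component; see the class documentation pages.
NULL

#' @rdname cortexplain-generics
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname cortexplain-generics
#' @export
setGeneric("vertexCoords", function(x) standardGeneric("vertexCoords"))

#' @rdname cortexplain-generics
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname cortexplain-generics
#' @export
setGeneric("gainMatrix", function(x) standardGeneric("gainMatrix"))

#' @rdname cortexplain-generics
#' @export
setGeneric("channelSites", function(x) standardGeneric("channelSites"))

#' @rdname cortexplain-generics
#' @export
setGeneric("cohortMeta", function(x) standardGeneric("cohortMeta"))

#' @rdname cortexplain-generics
#' @export
setGeneric("cohortSurface", function(x) standardGeneric("cohortSurface"))

#' @rdname cortexplain-generics
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname cortexplain-generics
#' @export
setGeneric("trialData", function(x) standardGeneric("trialData"))

#' @rdname cortexplain-generics
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname cortexplain-generics
#' @export
setGeneric("epochBounds", function(x) standardGeneric("epochBounds"))

#' @rdname cortexplain-generics
#' @export
setGeneric("gridSize", function(x) standardGeneric("gridSize"))

#' @rdname cortexplain-generics
#' @export
setGeneric("ellipseMask", function(x) standardGeneric("ellipseMask"))

#' @rdname cortexplain-generics
#' @export
setGeneric("volumeArray", function(x) standardGeneric("volumeArray"))

#' @rdname cortexplain-generics
#' @export
setGeneric("volumeLabels", function(x) standardGeneric("volumeLabels"))

#' @rdname cortexplain-generics
#' @export
setGeneric("volumeWindows", function(x) standardGeneric("volumeWindows"))

#' @rdname cortexplain-generics
#' @export
setGeneric("relevanceArray", function(x) standardGeneric("relevanceArray"))

#' @rdname cortexplain-generics
#' @export
setGeneric("relevanceMethod", function(x) standardGeneric("relevanceMethod"))

#' @rdname cortexplain-generics
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname cortexplain-generics
#' @export
setGeneric("countParameters", function(x) standardGeneric("countParameters"))
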