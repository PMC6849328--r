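#' @rdname IntensityImage-class
#' @param x an object.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname IntensityImage-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname IntensityImage-class
#' @export
setGeneric("channelLabel", function(x) standardGeneric("channelLabel"))

#' @rdname GroundTruth-class
#' @param x an object.
#' @export
setGeneric("cellMask", function(x) standardGeneric("cellMask"))

#' @rdname GroundTruth-class
#' @export
setGeneric("dropletMask", function(x) standardGeneric("dropletMask"))

#' @rdname GroundTruth-class
#' @export
setGeneric("trueLipidFraction", function(x) standardGeneric("trueLipidFraction"))

#' @rdname GroundTruth-class
#' @export
setGeneric("trueCellCount", function(x) standardGeneric("trueCellCount"))

#' @rdname ROISet-class
#' @param x an object.
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' @rdname ROISet-class
#' @export
setGeneric("nRois", function(x) standardGeneric("nRois"))

#' @rdname PipelineSummary-class
#' @param x an object.
#' @export
setGeneric("fovTable", function(x) standardGeneric("fovTable"))

#' @rdname PipelineSummary-class
#' @export
setGeneric("nFovsIncluded", function(x) standardGeneric("nFovsIncluded"))

#' @rdname PipelineSummary-class
#' @export
setGeneric("meanLipidRatio", function(x) standardGeneric("meanLipidRatio"))

#' @rdname PipelineSummary-class
#' @export
setGeneric("meanNormalizedRatio",
           function(x) standardGeneric("meanNormalizedRatio"))
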