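#' @rdname IntensityImage-class
#' @export
setMethod("pixels", "IntensityImage", function(x) x@pixels)

#' @rdname IntensityImage-class
#' @export
setMethod("pixelSize", "IntensityImage", function(x) x@pixelSizeUm)

#' @rdname IntensityImage-class
#' @export
setMethod("channelLabel", "IntensityImage", function(x) x@channelLabel)

#' @rdname IntensityImage-class
#' @export
setMethod("dim", "IntensityImage", function(x) dim(x@pixels))

#' @rdname GroundTruth-class
#' @export
setMethod("cellMask", "GroundTruth", function(x) x@cellMask)

#' @rdname GroundTruth-class
#' @export
setMethod("dropletMask", "GroundTruth", function(x) x@dropletMask)

#' @rdname GroundTruth-class
#' @export
setMethod("trueLipidFraction", "GroundTruth", function(x) x@trueLipidFraction)

#' @rdname GroundTruth-class
#' @export
setMethod("trueCellCount", "GroundTruth", function(x) x@trueCellCount)

#' @rdname ROISet-class
#' @export
setMethod("roiLabels", "ROISet", function(x) x@labels)

#' @rdname ROISet-class
#' @export
setMethod("nRois", "ROISet", function(x) max(x@labels, 0L))

#' @rdname PipelineSummary-class
#' @export
setMethod("fovTable", "PipelineSummary", function(x) x@fovs)

#' @rdname PipelineSummary-class
#' @export
setMethod("nFovsIncluded", "PipelineSummary", function(x) x@nFovsIncluded)

#' @rdname PipelineSummary-class
#' @export
setMethod("meanLipidRatio", "PipelineSummary", function(x) x@meanLipidRatio)

#' @rdname PipelineSummary-class
#' @export
setMethod("meanNormalizedRatio", "PipelineSummary",
          function(x) x@meanNormalizedRatio)

setMethod("show", "IntensityImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("IntensityImage %d x %d px (%.3g um/px), channel '%s'\n",
              d[1], d[2], object@pixelSizeUm, object@channelLabel))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d cells, lipid fraction %.4f%s (%d droplet px / %d cell px)\n",
    object@trueCellCount, object@trueLipidFraction,
    if (object@lipidFractionDefined) "" else " [undefined: no cells]",
    sum(object@dropletMask), sum(object@cellMask)))
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  window %d px, step %d px, confluence gate >= %.2f\n",
              object@windowPx, object@stepPx, object@confluenceMin))
  cat(sprintf("  background: %s + %g SD; droplets: %s (min %d px)\n",
              object@backgroundStat, object@foregroundK,
              object@dropletMethod, object@minDropletPx))
  cat(sprintf("  cells: %s, normalize by %s\n",
              object@cellCountSource, object@normalizeBy))
})

setMethod("show", "PipelineSummary", function(object) {
  cat(sprintf("PipelineSummary: %d/%d FOVs included\n",
              object@nFovsIncluded, object@nFovsTotal))
  cat(sprintf("  background %.4g, foreground threshold %.4g\n",
              object@backgroundLevel, object@foregroundThreshold))
  if (object@nFovsIncluded > 0) {
    cat(sprintf("  lipid ratio %.4f +/- %.4f; normalized %.4g +/- %.4g\n",
                object@meanLipidRatio, object@sdLipidRatio,
                object@meanNormalizedRatio, object@sdNormalizedRatio))
  }
})

setMethod("show", "ROISet", function(object) {
  cat(sprintf("ROISet: %d ROIs from '%s' (%d x %d px, %.3g um/px)\n",
              max(object@labels, 0L), object@sourceChannel,
              nrow(object@labels), ncol(object@labels), object@pixelSizeUm))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult: %s\n", object@testName))
  stat <- paste(sprintf("%s = %.4g", names(object@statistic), object@statistic),
                collapse = ", ")
  if (is.null(names(object@statistic)))
    stat <- sprintf("statistic = %.4g", object@statistic)
  cat("  ", stat, "; df = ", paste(object@df, collapse = ", "),
      "; p = ", paste(signif(object@pValue, 4), collapse = ", "), "\n",
      sep = "")
  if (nrow(object@postHoc)) {
    cat(sprintf("  %d post-hoc comparisons, %d significant at 0.05\n",
                nrow(object@postHoc), sum(object@postHoc$significant)))
  }
})
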