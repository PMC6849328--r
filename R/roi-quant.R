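## Marker-masked ROI quantification: the in-package replacement for manual
## ImageJ outlining (e.g. calbindin-outlined neuron somata measured in a
## filipin channel, or macrophage area in stained liver sections), plus
## Pearson co-localization and confluence gating of tiled acquisitions.

#' Build an ROI set from a marker channel
#'
#' Thresholds the marker image (Otsu by default, or a fixed manual
#' threshold), removes components below a minimum area, and labels the
#' surviving connected components in scan order.
#'
#' @param marker an [IntensityImage-class] marker channel.
#' @param thresholdRule \code{"otsu"} or a single numeric threshold; pixels
#'   strictly above it belong to ROIs.
#' @param minAreaPx minimum ROI area in pixels (default 0).
#' @return An [ROISet-class]; a blank marker yields zero ROIs.
#' @examples
#' m <- matrix(0, 50, 50); m[10:20, 10:20] <- 100
#' rois <- maskFromMarker(IntensityImage(m))
#' nRois(rois)
#' @export
maskFromMarker <- function(marker, thresholdRule = "otsu", minAreaPx = 0L) {
  stopifnot(is(marker, "IntensityImage"))
  px <- marker@pixels
  thr <- if (identical(thresholdRule, "otsu")) otsuThreshold(px)
         else if (is.numeric(thresholdRule) && length(thresholdRule) == 1L)
           thresholdRule
         else stop("thresholdRule must be 'otsu' or a single number")
  lab <- labelComponents(px > thr, minSizePx = as.integer(minAreaPx))
  new("ROISet", labels = lab, pixelSizeUm = marker@pixelSizeUm,
      sourceChannel = marker@channelLabel)
}

#' Measure intensity and area per ROI
#'
#' Reports, for every ROI, its pixel and physical area and its mean and
#' integrated intensity in the target channel. "Intensity" of an outlined
#' region is emitted both ways (mean and integrated = mean x area) since
#' either convention is in common use. The background (label 0) mean is
#' attached as attribute \code{"background_mean"} and can optionally be
#' subtracted from the ROI means.
#'
#' @param target an [IntensityImage-class] measured within the ROIs.
#' @param rois an [ROISet-class] of identical shape.
#' @param backgroundSubtract if TRUE, subtract the label-0 mean intensity
#'   from every ROI mean (and recompute integrated intensity accordingly).
#' @return data.frame with columns \code{roi_id}, \code{area_px},
#'   \code{area_um2}, \code{mean_intensity}, \code{integrated_intensity};
#'   zero rows for an empty ROI set.
#' @export
measureRois <- function(target, rois, backgroundSubtract = FALSE) {
  stopifnot(is(target, "IntensityImage"), is(rois, "ROISet"))
  if (!identical(dim(target@pixels), dim(rois@labels)))
    stop("target and ROI label image have different shapes")
  lab <- rois@labels
  px <- target@pixels
  k <- max(lab, 0L)
  bgMean <- if (any(lab == 0L)) mean(px[lab == 0L]) else NA_real_
  if (k == 0L) {
    out <- data.frame(roi_id = integer(0), area_px = integer(0),
                      area_um2 = numeric(0), mean_intensity = numeric(0),
                      integrated_intensity = numeric(0))
    attr(out, "background_mean") <- bgMean
    return(out)
  }
  inRoi <- lab > 0L
  area <- tabulate(lab[inRoi], k)
  tot <- as.numeric(rowsum(px[inRoi], lab[inRoi], reorder = TRUE))
  m <- tot / area
  if (backgroundSubtract && !is.na(bgMean)) m <- m - bgMean
  out <- data.frame(
    roi_id = seq_len(k),
    area_px = area,
    area_um2 = area * rois@pixelSizeUm^2,
    mean_intensity = m,
    integrated_intensity = m * area)
  attr(out, "background_mean") <- bgMean
  out
}

#' Pearson co-localization coefficient of two channels
#'
#' Pearson correlation of paired pixel intensities, optionally restricted
#' to a mask (e.g. the cell area). Symmetric in its arguments and invariant
#' to affine intensity rescaling with positive slope. A zero-variance
#' channel makes the coefficient undefined; NA is returned with a warning.
#'
#' @param channelA,channelB [IntensityImage-class] objects (or matrices) of
#'   identical shape.
#' @param mask optional logical matrix selecting the pixels to correlate.
#' @return numeric in [-1, 1], or NA if undefined.
#' @examples
#' a <- matrix(runif(100), 10)
#' pearsonColocalization(a, 2 * a + 1)    # exactly 1
#' @export
pearsonColocalization <- function(channelA, channelB, mask = NULL) {
  a <- if (is(channelA, "IntensityImage")) channelA@pixels else channelA
  b <- if (is(channelB, "IntensityImage")) channelB@pixels else channelB
  if (!identical(dim(a), dim(b))) stop("channel shapes differ")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(a))) stop("mask shape differs")
    if (!any(mask)) stop("mask is empty")
    a <- a[mask]; b <- b[mask]
  }
  if (stats::var(as.numeric(a)) == 0 || stats::var(as.numeric(b)) == 0) {
    warning("zero-variance channel: co-localization undefined")
    return(NA_real_)
  }
  stats::cor(as.numeric(a), as.numeric(b))
}

#' Gate tiled acquisitions by cell confluence
#'
#' Screens a set of tiled images (e.g. the 16 tiles of an automated
#' epifluorescence acquisition) and keeps those whose cell confluence
#' reaches the gate (>= 0.90 by default), reusing the pipeline's
#' background/foreground classifier per tile unless a common foreground
#' threshold is supplied.
#'
#' @param tiles list of [IntensityImage-class] tiles.
#' @param threshold confluence gate in [0, 1] (default 0.90).
#' @param foregroundThreshold optional fixed intensity threshold applied to
#'   every tile instead of per-tile estimation.
#' @param config [PipelineConfig-class] driving per-tile estimation.
#' @return data.frame with \code{tile}, \code{confluence}, \code{included};
#'   attribute \code{"included_tiles"} holds the retained tiles.
#' @export
gateTilesByConfluence <- function(tiles, threshold = 0.90,
                                  foregroundThreshold = NULL,
                                  config = pipelineConfig()) {
  stopifnot(is.list(tiles))
  conf <- vapply(tiles, function(t) {
    stopifnot(is(t, "IntensityImage"))
    thr <- if (is.null(foregroundThreshold))
      estimateBackground(t, config)$foregroundThreshold
    else foregroundThreshold
    mean(t@pixels > thr)
  }, numeric(1))
  out <- data.frame(tile = seq_along(tiles), confluence = conf,
                    included = conf >= threshold)
  attr(out, "included_tiles") <- tiles[out$included]
  out
}
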