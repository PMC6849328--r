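## The two-layer automated thresholding pipeline for SRS lipid images:
## background/foreground split -> sliding-window confluence gating ->
## within-cell droplet segmentation -> per-FOV lipid-area ratio.

#' Estimate background level and the cell/media threshold
#'
#' First layer of the two-layer thresholding scheme. Because the image
#' model is tri-modal (media, cell cytoplasm, lipid droplets), a
#' two-threshold Otsu partition of the whole image bootstraps the
#' provisional media set as its darkest class (a single Otsu cut would
#' instead split droplets from everything else on highly confluent,
#' droplet-rich images). The background level is the configured statistic
#' (mean by default) of that set and the cell/media threshold is
#' background level + foregroundK x SD(background set). In the exactly
#' noiseless limit the background spread is zero and the lower Otsu cut
#' itself — which lies strictly between the media and cell modes — is used
#' as the threshold.
#'
#' @param image an [IntensityImage-class].
#' @param config a [PipelineConfig-class].
#' @return list with \code{backgroundLevel} and \code{foregroundThreshold};
#'   pixels strictly above the threshold are classified as cells.
#' @examples
#' g <- generateSrsImage(imageGenParams(heightPx = 200, widthPx = 200,
#'                                      confluence = 0.5, seed = 1))
#' estimateBackground(g$image, pipelineConfig())
#' @export
estimateBackground <- function(image, config = pipelineConfig()) {
  stopifnot(is(image, "IntensityImage"), is(config, "PipelineConfig"))
  px <- image@pixels
  cut <- .otsuThreshold2(px)[1L]
  bgSet <- px[px <= cut]
  if (length(bgSet) == 0L) bgSet <- px   # cannot happen with Otsu's cut rule
  level <- if (config@backgroundStat == "mean") mean(bgSet)
           else stats::median(bgSet)
  spread <- if (length(bgSet) > 1L) stats::sd(bgSet) else 0
  thr <- if (spread > 0) level + config@foregroundK * spread else cut
  list(backgroundLevel = level, foregroundThreshold = thr)
}

#' Enumerate sliding-window fields of view
#'
#' Places every window of side \code{windowPx} at offsets that are
#' multiples of \code{stepPx} and fully inside the image (windows that
#' would overhang are dropped, not padded). Offsets are 0-based and
#' half-open: window k covers rows [row0, row0 + windowPx). The count per
#' axis is floor((dim - window)/step) + 1 and records are emitted in
#' row-major order.
#'
#' @param image an [IntensityImage-class] (or a plain matrix).
#' @param config a [PipelineConfig-class]; only \code{windowPx} and
#'   \code{stepPx} are used.
#' @return data.frame with columns \code{row0}, \code{col0}.
#' @examples
#' img <- IntensityImage(matrix(0, 2000, 2000))
#' nrow(tileFovs(img, pipelineConfig()))   # 18 * 18 = 324
#' @export
tileFovs <- function(image, config = pipelineConfig()) {
  d <- if (is(image, "IntensityImage")) dim(image@pixels) else dim(image)
  w <- config@windowPx; s <- config@stepPx
  if (w > min(d))
    stop("window (", w, " px) larger than image (", d[1], " x ", d[2], ")")
  rows <- seq.int(0L, d[1] - w, by = s)
  cols <- seq.int(0L, d[2] - w, by = s)
  data.frame(row0 = rep(rows, each = length(cols)),
             col0 = rep(cols, times = length(rows)))
}

#' Fraction of window pixels classified as cells
#'
#' Confluence of one field of view: the fraction of its pixels strictly
#' above the cell/media threshold.
#'
#' @param image an [IntensityImage-class].
#' @param fov list or one-row data.frame with \code{row0}, \code{col0}
#'   (0-based top-left corner).
#' @param foregroundThreshold threshold from [estimateBackground()].
#' @param windowPx window side length in pixels.
#' @return numeric in [0, 1].
#' @export
computeConfluence <- function(image, fov, foregroundThreshold,
                              windowPx = 250L) {
  px <- if (is(image, "IntensityImage")) image@pixels else image
  r0 <- fov$row0; c0 <- fov$col0
  stopifnot(r0 >= 0, c0 >= 0,
            r0 + windowPx <= nrow(px), c0 + windowPx <= ncol(px))
  win <- px[(r0 + 1L):(r0 + windowPx), (c0 + 1L):(c0 + windowPx)]
  mean(win > foregroundThreshold)
}

#' Apply the confluence gate to a FOV table
#'
#' Keeps fields of view whose confluence reaches the gate. The published
#' default gate is 0.90, applied inclusively (confluence >= gate); input
#' order is preserved.
#'
#' @param fovs data.frame with a \code{confluence} column.
#' @param confluenceMin the gate (default 0.90).
#' @return The subset of \code{fovs} with \code{included == TRUE} added.
#' @export
selectFovs <- function(fovs, confluenceMin = 0.90) {
  stopifnot("confluence" %in% names(fovs))
  fovs$included <- fovs$confluence >= confluenceMin
  fovs[fovs$included, , drop = FALSE]
}

#' Segment intracellular lipid droplets in one field of view
#'
#' Second thresholding layer: within the intracellular (foreground) pixels
#' of the window, droplets are the high-intensity class. Two rules are
#' available: an Otsu split of the intracellular intensities (default) or
#' intracellular mean + dropletK x SD. Connected droplet components smaller
#' than \code{minDropletPx} are discarded. When the intracellular
#' intensities are constant (no contrast) no droplet pixels are returned.
#'
#' @param image an [IntensityImage-class].
#' @param fov list/one-row data.frame with \code{row0}, \code{col0}.
#' @param foregroundMask logical matrix (whole image), TRUE on cell pixels.
#' @param config a [PipelineConfig-class].
#' @return list: \code{dropletMask} (window-sized logical matrix),
#'   \code{lipidPx}, \code{intracellularPx}, \code{defined} (FALSE when the
#'   window holds no intracellular pixels).
#' @export
segmentLipidDroplets <- function(image, fov, foregroundMask,
                                 config = pipelineConfig()) {
  px <- if (is(image, "IntensityImage")) image@pixels else image
  w <- config@windowPx
  r <- (fov$row0 + 1L):(fov$row0 + w)
  cl <- (fov$col0 + 1L):(fov$col0 + w)
  win <- px[r, cl]
  intr <- foregroundMask[r, cl]
  nIntr <- sum(intr)
  if (nIntr == 0L)
    return(list(dropletMask = matrix(FALSE, w, w), lipidPx = 0L,
                intracellularPx = 0L, defined = FALSE))
  vals <- win[intr]
  thr <- if (config@dropletMethod == "otsu_within_cells") {
    otsuThreshold(vals)
  } else {
    mean(vals) + config@dropletK * (if (nIntr > 1L) stats::sd(vals) else 0)
  }
  drop <- intr & (win > thr)
  if (config@minDropletPx > 0L && any(drop))
    drop <- labelComponents(drop, minSizePx = config@minDropletPx) > 0L
  list(dropletMask = drop, lipidPx = sum(drop), intracellularPx = nIntr,
       defined = TRUE)
}

#' Count cells intersecting one field of view
#'
#' In \code{component_count} mode, cells are the size-filtered connected
#' components of the foreground mask and a window's count is the number of
#' distinct components intersecting it (a component touching several
#' windows is counted once per window; two touching cells merge into one
#' component — a documented bias of the mode). \code{marker_channel} mode
#' does the same on an Otsu-thresholded marker image (e.g. a nuclear
#' stain); \code{provided} mode looks the count up in a user table.
#'
#' @param image an [IntensityImage-class] (ignored in provided mode).
#' @param fov list/one-row data.frame with \code{row0}, \code{col0}.
#' @param config a [PipelineConfig-class].
#' @param marker optional marker-channel [IntensityImage-class].
#' @param provided optional data.frame (\code{row0}, \code{col0},
#'   \code{cell_count}) for provided mode.
#' @param labelImage optional precomputed label matrix (skips segmentation;
#'   used internally by [runSrsPipeline()]).
#' @return non-negative integer.
#' @export
countCells <- function(image, fov, config = pipelineConfig(), marker = NULL,
                       provided = NULL, labelImage = NULL) {
  if (config@cellCountSource == "provided") {
    if (is.null(provided))
      stop("cellCountSource = 'provided' requires a counts table")
    hit <- provided$row0 == fov$row0 & provided$col0 == fov$col0
    if (!any(hit))
      stop("no provided cell count for FOV (", fov$row0, ", ", fov$col0, ")")
    return(as.integer(provided$cell_count[which(hit)[1L]]))
  }
  if (is.null(labelImage)) {
    src <- if (config@cellCountSource == "marker_channel") {
      if (is.null(marker)) stop("marker_channel mode requires a marker image")
      marker
    } else image
    bg <- estimateBackground(src, config)
    fg <- (if (is(src, "IntensityImage")) src@pixels else src) >
      bg$foregroundThreshold
    labelImage <- labelComponents(fg, minSizePx = config@minCellPx)
  }
  w <- config@windowPx
  win <- labelImage[(fov$row0 + 1L):(fov$row0 + w),
                    (fov$col0 + 1L):(fov$col0 + w)]
  length(unique(win[win > 0L]))
}

#' Run the full SRS lipid-quantification pipeline on one image
#'
#' Composition of the pipeline stages: background/foreground thresholding,
#' exhaustive sliding-window tiling, confluence gating, within-cell droplet
#' segmentation and cell counting, yielding per-FOV lipid-area ratios
#' (lipid pixels / intracellular pixels) and cell-normalized ratios, plus
#' image-level aggregates over the included FOVs. Fully deterministic for a
#' fixed image and configuration. An image with zero included FOVs yields a
#' summary with empty aggregates, not an error.
#'
#' @param image an [IntensityImage-class].
#' @param config a [PipelineConfig-class]; defaults are the published
#'   settings (250 px window, 100 px step, 0.90 gate).
#' @param marker optional marker channel for cell counting.
#' @param provided optional per-FOV cell-count table (provided mode), or a
#'   single number used as the whole-image count.
#' @return A [PipelineSummary-class].
#' @examples
#' g <- generateSrsImage(imageGenParams(heightPx = 600, widthPx = 600,
#'        confluence = 0.95, targetLipidFraction = 0.1, seed = 3))
#' s <- runSrsPipeline(g$image)
#' meanLipidRatio(s)          # close to trueLipidFraction(g$truth)
#' @export
runSrsPipeline <- function(image, config = pipelineConfig(), marker = NULL,
                           provided = NULL) {
  stopifnot(is(image, "IntensityImage"), is(config, "PipelineConfig"))
  bg <- estimateBackground(image, config)
  px <- image@pixels
  fg <- px > bg$foregroundThreshold
  fovs <- tileFovs(image, config)
  w <- config@windowPx

  S <- .integralImage(fg)
  fovs$confluence <- mapply(function(r0, c0)
    .windowSum(S, r0, c0, w, w) / (w * w), fovs$row0, fovs$col0)
  fovs$included <- fovs$confluence >= config@confluenceMin

  needCounts <- config@cellCountSource != "provided" ||
    (is.numeric(provided) && length(provided) == 1L)
  labelImage <- NULL
  if (config@cellCountSource == "component_count") {
    labelImage <- labelComponents(fg, minSizePx = config@minCellPx)
  } else if (config@cellCountSource == "marker_channel") {
    if (is.null(marker)) stop("marker_channel mode requires a marker image")
    mbg <- estimateBackground(marker, config)
    labelImage <- labelComponents(marker@pixels > mbg$foregroundThreshold,
                                  minSizePx = config@minCellPx)
  }
  imageCellCount <- if (!is.null(labelImage)) max(labelImage, 0L)
    else if (is.numeric(provided) && length(provided) == 1L)
      as.integer(provided)
    else NA_integer_

  n <- nrow(fovs)
  intrPx <- lipidPx <- cellCount <- rep(NA_integer_, n)
  ratio <- normRatio <- rep(NA_real_, n)
  ratioDef <- normDef <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!fovs$included[i]) next
    fov <- fovs[i, ]
    seg <- segmentLipidDroplets(image, fov, fg, config)
    intrPx[i] <- seg$intracellularPx
    lipidPx[i] <- seg$lipidPx
    ratioDef[i] <- seg$defined
    if (seg$defined) ratio[i] <- seg$lipidPx / seg$intracellularPx
    cc <- if (config@normalizeBy == "image") {
      imageCellCount
    } else if (!is.null(labelImage)) {
      countCells(image, fov, config, labelImage = labelImage)
    } else {
      countCells(image, fov, config, provided = provided)
    }
    cellCount[i] <- cc
    if (seg$defined && !is.na(cc) && cc > 0L) {
      normRatio[i] <- ratio[i] / cc
      normDef[i] <- TRUE
    }
  }
  fovs$intracellular_px <- intrPx
  fovs$lipid_px <- lipidPx
  fovs$lipid_ratio <- ratio
  fovs$cell_count <- cellCount
  fovs$normalized_ratio <- normRatio
  fovs$ratio_defined <- ratioDef
  fovs$norm_defined <- normDef

  incRatio <- ratio[fovs$included & ratioDef]
  incNorm <- normRatio[fovs$included & normDef]
  agg <- function(x, f) if (length(x)) f(x) else NA_real_
  new("PipelineSummary",
    fovs = fovs,
    nFovsTotal = n, nFovsIncluded = sum(fovs$included),
    backgroundLevel = bg$backgroundLevel,
    foregroundThreshold = bg$foregroundThreshold,
    meanLipidRatio = agg(incRatio, mean),
    sdLipidRatio = agg(incRatio, function(x) if (length(x) > 1) stats::sd(x) else NA_real_),
    meanNormalizedRatio = agg(incNorm, mean),
    sdNormalizedRatio = agg(incNorm, function(x) if (length(x) > 1) stats::sd(x) else NA_real_),
    config = config)
}
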