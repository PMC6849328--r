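#' @import methods
NULL

#' IntensityImage: a single-channel microscopy image
#'
#' Container for a 2-D scalar intensity field, the raw input to all imaging
#' operations in the package. Typically holds the greyscale channel acquired
#' at the 2845 cm-1 CH2 Raman shift (lipid-selective contrast), or a
#' fluorescence / marker channel.
#'
#' @slot pixels numeric matrix of finite, non-negative intensities
#'   (rows = image rows, row 1 at the top).
#' @slot pixelSizeUm positive numeric, physical pixel size in micrometres.
#' @slot channelLabel character, free-text channel description, e.g.
#'   \code{"2845cm-1"}.
#'
#' @seealso [IntensityImage()], [readIntensityImage()], [runSrsPipeline()]
#' @export
setClass("IntensityImage",
  representation(
    pixels = "matrix",
    pixelSizeUm = "numeric",
    channelLabel = "character"
  ),
  prototype(pixelSizeUm = 1, channelLabel = "2845cm-1")
)

setValidity("IntensityImage", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels)) msg <- c(msg, "pixels must be numeric")
  if (length(object@pixels) == 0L) msg <- c(msg, "pixels must be non-empty")
  if (is.numeric(object@pixels) && !all(is.finite(object@pixels)))
    msg <- c(msg, "pixels must be finite (no NA/NaN/Inf)")
  if (is.numeric(object@pixels) && length(object@pixels) &&
      min(object@pixels) < 0)
    msg <- c(msg, "pixels must be non-negative")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct an IntensityImage
#'
#' @param pixels numeric matrix of intensities.
#' @param pixelSizeUm physical pixel size in micrometres per pixel.
#' @param channelLabel channel description string.
#' @return An [IntensityImage-class] object.
#' @examples
#' img <- IntensityImage(matrix(runif(100), 10, 10))
#' dim(img)
#' @export
IntensityImage <- function(pixels, pixelSizeUm = 1, channelLabel = "2845cm-1") {
  if (is.vector(pixels)) pixels <- matrix(pixels, nrow = 1L)
  storage.mode(pixels) <- "double"
  new("IntensityImage", pixels = pixels, pixelSizeUm = pixelSizeUm,
      channelLabel = channelLabel)
}

#' GroundTruth: exact truth for a synthetic SRS image
#'
#' Stores the generator's true cell and droplet masks, the exact
#' mask-derived lipid-area fraction, and the number of placed cells, so that
#' downstream pipeline estimates can be tested for recovery against known
#' truth.
#'
#' @slot cellMask logical matrix; TRUE where a cell covers the pixel.
#' @slot dropletMask logical matrix; TRUE on lipid-droplet pixels
#'   (always a subset of \code{cellMask}).
#' @slot perCellLabels integer matrix; 0 = background, k = pixel last
#'   painted by placed cell k (overlapping cells overwrite).
#' @slot centers numeric matrix (nCells x 2) of placed cell centres
#'   (row, col); cell count is defined by placed centres even when masks
#'   merge.
#' @slot trueLipidFraction numeric; droplet pixels / cell pixels, exactly.
#' @slot lipidFractionDefined logical; FALSE iff there are no cell pixels
#'   (the fraction is then reported as 0 with this flag unset).
#' @slot trueCellCount integer; number of placed cells.
#' @export
setClass("GroundTruth",
  representation(
    cellMask = "matrix",
    dropletMask = "matrix",
    perCellLabels = "matrix",
    centers = "matrix",
    trueLipidFraction = "numeric",
    lipidFractionDefined = "logical",
    trueCellCount = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!identical(dim(object@cellMask), dim(object@dropletMask)))
    msg <- c(msg, "cellMask and dropletMask must have identical shape")
  if (any(object@dropletMask & !object@cellMask))
    msg <- c(msg, "dropletMask must be a subset of cellMask")
  ncell <- sum(object@cellMask)
  frac <- if (ncell > 0) sum(object@dropletMask) / ncell else 0
  if (!isTRUE(all.equal(frac, object@trueLipidFraction, tolerance = 0)))
    msg <- c(msg, "trueLipidFraction must equal the exact mask ratio")
  if ((ncell == 0) == object@lipidFractionDefined)
    msg <- c(msg, "lipidFractionDefined must flag the empty-cell case")
  if (nrow(object@centers) != object@trueCellCount)
    msg <- c(msg, "trueCellCount must equal the number of placed centres")
  if (length(msg)) msg else TRUE
})

#' PipelineConfig: parameters of the SRS quantification pipeline
#'
#' All defaults follow the published acquisition/analysis settings where one
#' exists (250 px window, 100 px step, 0.90 confluence gate); the remaining
#' knobs are documented design choices (see the methods vignette).
#'
#' @slot windowPx sliding-window side length in pixels (default 250).
#' @slot stepPx window step in pixels (default 100).
#' @slot confluenceMin minimum fraction of foreground (cell) pixels for a
#'   field of view to be included (default 0.90, applied inclusively).
#' @slot backgroundStat statistic over the provisional media set used as the
#'   background level: \code{"mean"} (default) or \code{"median"}.
#' @slot foregroundK multiplier on the background-set standard deviation for
#'   the cell/media threshold (default 3).
#' @slot dropletMethod second-layer droplet threshold rule:
#'   \code{"otsu_within_cells"} (default) or \code{"foreground_mean_plus_kSD"}.
#' @slot dropletK multiplier for the \code{foreground_mean_plus_kSD} rule
#'   (default 2).
#' @slot minDropletPx connected droplet components smaller than this are
#'   discarded (default 4; 0 disables).
#' @slot minCellPx foreground components smaller than this are ignored when
#'   counting cells (default 64; suppresses supra-threshold noise speckles).
#' @slot cellCountSource \code{"component_count"} (default),
#'   \code{"marker_channel"} or \code{"provided"}.
#' @slot normalizeBy \code{"fov"} (default; divide each FOV's lipid ratio by
#'   the cells intersecting that FOV) or \code{"image"} (divide by the
#'   whole-image cell count).
#' @seealso [pipelineConfig()], [runSrsPipeline()]
#' @export
setClass("PipelineConfig",
  representation(
    windowPx = "integer",
    stepPx = "integer",
    confluenceMin = "numeric",
    backgroundStat = "character",
    foregroundK = "numeric",
    dropletMethod = "character",
    dropletK = "numeric",
    minDropletPx = "integer",
    minCellPx = "integer",
    cellCountSource = "character",
    normalizeBy = "character"
  ),
  prototype(
    windowPx = 250L, stepPx = 100L, confluenceMin = 0.90,
    backgroundStat = "mean", foregroundK = 3,
    dropletMethod = "otsu_within_cells", dropletK = 2,
    minDropletPx = 4L, minCellPx = 64L,
    cellCountSource = "component_count", normalizeBy = "fov"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@windowPx < 1L) msg <- c(msg, "windowPx must be positive")
  if (object@stepPx < 1L) msg <- c(msg, "stepPx must be positive")
  if (!(object@confluenceMin > 0 && object@confluenceMin <= 1))
    msg <- c(msg, "confluenceMin must lie in (0, 1]")
  if (!object@backgroundStat %in% c("mean", "median"))
    msg <- c(msg, "backgroundStat must be 'mean' or 'median'")
  if (object@foregroundK < 0) msg <- c(msg, "foregroundK must be >= 0")
  if (!object@dropletMethod %in%
        c("otsu_within_cells", "foreground_mean_plus_kSD"))
    msg <- c(msg, "unknown dropletMethod")
  if (object@dropletK < 0) msg <- c(msg, "dropletK must be >= 0")
  if (object@minDropletPx < 0L) msg <- c(msg, "minDropletPx must be >= 0")
  if (object@minCellPx < 0L) msg <- c(msg, "minCellPx must be >= 0")
  if (!object@cellCountSource %in%
        c("component_count", "marker_channel", "provided"))
    msg <- c(msg, "unknown cellCountSource")
  if (!object@normalizeBy %in% c("fov", "image"))
    msg <- c(msg, "normalizeBy must be 'fov' or 'image'")
  if (length(msg)) msg else TRUE
})

#' Construct a PipelineConfig
#'
#' @param windowPx,stepPx,confluenceMin,backgroundStat,foregroundK
#'   see [PipelineConfig-class].
#' @param dropletMethod,dropletK,minDropletPx,minCellPx,cellCountSource,normalizeBy
#'   see [PipelineConfig-class].
#' @return A validated [PipelineConfig-class].
#' @examples
#' cfg <- pipelineConfig()            # published defaults: 250 / 100 / 0.90
#' cfg <- pipelineConfig(stepPx = 250)  # non-overlapping tiling
#' @export
pipelineConfig <- function(windowPx = 250, stepPx = 100, confluenceMin = 0.90,
                           backgroundStat = c("mean", "median"),
                           foregroundK = 3,
                           dropletMethod = c("otsu_within_cells",
                                             "foreground_mean_plus_kSD"),
                           dropletK = 2, minDropletPx = 4, minCellPx = 64,
                           cellCountSource = c("component_count",
                                               "marker_channel", "provided"),
                           normalizeBy = c("fov", "image")) {
  cfg <- new("PipelineConfig",
    windowPx = as.integer(windowPx), stepPx = as.integer(stepPx),
    confluenceMin = confluenceMin,
    backgroundStat = match.arg(backgroundStat),
    foregroundK = foregroundK,
    dropletMethod = match.arg(dropletMethod),
    dropletK = dropletK,
    minDropletPx = as.integer(minDropletPx),
    minCellPx = as.integer(minCellPx),
    cellCountSource = match.arg(cellCountSource),
    normalizeBy = match.arg(normalizeBy))
  if (cfg@stepPx > cfg@windowPx)
    warning("stepPx > windowPx: the tiling leaves uncovered gaps",
            call. = FALSE)
  cfg
}

#' PipelineSummary: full output of the SRS quantification pipeline
#'
#' @slot fovs data.frame of per-FOV records with columns \code{row0},
#'   \code{col0}, \code{confluence}, \code{included}, \code{intracellular_px},
#'   \code{lipid_px}, \code{lipid_ratio}, \code{cell_count},
#'   \code{normalized_ratio}, \code{ratio_defined}, \code{norm_defined}.
#'   Undefined values are NA with their flag column FALSE — never NaN.
#' @slot nFovsTotal,nFovsIncluded integer tile counts.
#' @slot backgroundLevel,foregroundThreshold image-level background estimate
#'   and the derived cell/media threshold.
#' @slot meanLipidRatio,sdLipidRatio,meanNormalizedRatio,sdNormalizedRatio
#'   image-level aggregates over included FOVs (NA when no FOV is included).
#' @slot config the [PipelineConfig-class] used.
#' @export
setClass("PipelineSummary",
  representation(
    fovs = "data.frame",
    nFovsTotal = "integer",
    nFovsIncluded = "integer",
    backgroundLevel = "numeric",
    foregroundThreshold = "numeric",
    meanLipidRatio = "numeric",
    sdLipidRatio = "numeric",
    meanNormalizedRatio = "numeric",
    sdNormalizedRatio = "numeric",
    config = "PipelineConfig"
  )
)

setValidity("PipelineSummary", function(object) {
  msg <- character()
  if (object@nFovsIncluded > object@nFovsTotal)
    msg <- c(msg, "nFovsIncluded must not exceed nFovsTotal")
  lr <- object@fovs$lipid_ratio
  if (!is.null(lr) && any(!is.na(lr) & (lr < 0 | lr > 1)))
    msg <- c(msg, "lipid_ratio must lie in [0, 1]")
  if (any(vapply(object@fovs, function(col) any(is.nan(col)), logical(1))))
    msg <- c(msg, "NaN is not allowed in the FOV table (use NA + flag)")
  if (length(msg)) msg else TRUE
})

#' ROISet: labelled regions of interest
#'
#' A label image produced by thresholding a marker channel (the in-package
#' replacement for manual/ImageJ outlining): 0 marks background, k marks
#' ROI k; labels are contiguous positive integers in scan order.
#'
#' @slot labels integer matrix of ROI labels.
#' @slot pixelSizeUm physical pixel size in micrometres.
#' @slot sourceChannel description of the marker channel the ROIs came from.
#' @seealso [maskFromMarker()], [measureRois()]
#' @export
setClass("ROISet",
  representation(
    labels = "matrix",
    pixelSizeUm = "numeric",
    sourceChannel = "character"
  ),
  prototype(pixelSizeUm = 1, sourceChannel = "marker")
)

setValidity("ROISet", function(object) {
  msg <- character()
  labs <- object@labels
  if (length(labs) && min(labs) < 0L)
    msg <- c(msg, "labels must be non-negative")
  k <- suppressWarnings(max(labs, 0L))
  present <- sort(unique(labs[labs > 0L]))
  if (k > 0L && !identical(as.integer(present), seq_len(k)))
    msg <- c(msg, "positive labels must be contiguous 1..K")
  if (object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be positive")
  if (length(msg)) msg else TRUE
})

#' TestResult: outcome of a group-comparison test
#'
#' @slot testName one of \code{"t_test"}, \code{"anova1_tukey"},
#'   \code{"anova2_bonferroni"}.
#' @slot statistic the t or F statistic (two-way ANOVA: named vector of the
#'   three F values).
#' @slot df degrees of freedom (named vector).
#' @slot pValue p value(s) matching \code{statistic}.
#' @slot postHoc data.frame of pairwise comparisons: \code{pair},
#'   \code{estimate}, \code{p_adjusted}, \code{significant} (alpha 0.05).
#' @export
setClass("TestResult",
  representation(
    testName = "character",
    statistic = "numeric",
    df = "numeric",
    pValue = "numeric",
    postHoc = "data.frame"
  )
)

setValidity("TestResult", function(object) {
  p <- c(object@pValue, object@postHoc$p_adjusted)
  if (any(!is.na(p) & (p < 0 | p > 1))) "p values must lie in [0, 1]" else TRUE
})

#' ImageGenParams: parameters of the synthetic SRS image generator
#'
#' The generator emulates the statistical structure of a lipid-selective
#' 2845 cm-1 SRS channel: a dim uniform media background, brighter cell
#' foreground (random perturbed ellipses), and high-intensity punctate lipid
#' droplets clipped to cell interiors, with additive Gaussian or Poisson
#' noise. It does not simulate Raman physics.
#'
#' @slot heightPx,widthPx image dimensions in pixels (default 2000 x 2000,
#'   a 2 mm x 2 mm field at the default 1 um/px).
#' @slot pixelSizeUm micrometres per pixel (default 1).
#' @slot confluence target fraction of pixels covered by cells, in
#'   [0, 0.995]; used to derive the number of cells when \code{nCells} is NA.
#' @slot nCells number of cells to place, or NA to derive from
#'   \code{confluence}.
#' @slot cellRadiusPx,cellRadiusDispersion mean cell radius (px) and
#'   lognormal dispersion of per-cell radii.
#' @slot dropletDensity mean droplets per cell (ignored when
#'   \code{targetLipidFraction} is set).
#' @slot dropletRadiusPx mean droplet radius in pixels.
#' @slot targetLipidFraction if not NA, droplets are added until the
#'   mask-derived lipid-area fraction reaches this value.
#' @slot intensityBackground,intensityCell,intensityDroplet the three
#'   noiseless intensity levels; must satisfy droplet > cell > background.
#' @slot noiseSd Gaussian noise standard deviation (0 = noiseless limit).
#' @slot noiseModel \code{"gaussian"} (default) or \code{"poisson"}.
#' @slot seed integer RNG seed; identical params + seed give bit-identical
#'   output.
#' @seealso [imageGenParams()], [generateSrsImage()]
#' @export
setClass("ImageGenParams",
  representation(
    heightPx = "integer", widthPx = "integer", pixelSizeUm = "numeric",
    confluence = "numeric", nCells = "integer",
    cellRadiusPx = "numeric", cellRadiusDispersion = "numeric",
    dropletDensity = "numeric", dropletRadiusPx = "numeric",
    targetLipidFraction = "numeric",
    intensityBackground = "numeric", intensityCell = "numeric",
    intensityDroplet = "numeric",
    noiseSd = "numeric", noiseModel = "character", seed = "integer"
  )
)

setValidity("ImageGenParams", function(object) {
  msg <- character()
  if (object@heightPx < 1L || object@widthPx < 1L)
    msg <- c(msg, "image dimensions must be positive")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be positive")
  if (object@confluence < 0 || object@confluence > 1)
    msg <- c(msg, "confluence must lie in [0, 1]")
  if (!is.na(object@nCells) && object@nCells < 0L)
    msg <- c(msg, "nCells must be non-negative")
  if (object@cellRadiusPx <= 0) msg <- c(msg, "cellRadiusPx must be positive")
  if (object@dropletDensity < 0)
    msg <- c(msg, "dropletDensity must be non-negative")
  if (object@dropletRadiusPx <= 0)
    msg <- c(msg, "dropletRadiusPx must be positive")
  if (!is.na(object@targetLipidFraction) &&
      (object@targetLipidFraction < 0 || object@targetLipidFraction >= 1))
    msg <- c(msg, "targetLipidFraction must lie in [0, 1)")
  if (!(object@intensityDroplet > object@intensityCell &&
        object@intensityCell > object@intensityBackground))
    msg <- c(msg,
      "intensity ordering violated: need droplet > cell > background")
  if (object@intensityBackground <= 0)
    msg <- c(msg, "intensityBackground must be positive")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (!object@noiseModel %in% c("gaussian", "poisson"))
    msg <- c(msg, "noiseModel must be 'gaussian' or 'poisson'")
  if (length(msg)) msg else TRUE
})

#' Construct ImageGenParams
#'
#' @param heightPx,widthPx,pixelSizeUm,confluence,nCells,cellRadiusPx
#'   see [ImageGenParams-class].
#' @param cellRadiusDispersion,dropletDensity,dropletRadiusPx see
#'   [ImageGenParams-class].
#' @param targetLipidFraction,intensityBackground,intensityCell see
#'   [ImageGenParams-class].
#' @param intensityDroplet,noiseSd,noiseModel,seed see
#'   [ImageGenParams-class].
#' @return A validated [ImageGenParams-class].
#' @examples
#' p <- imageGenParams(heightPx = 600, widthPx = 600, seed = 1)
#' @export
imageGenParams <- function(heightPx = 2000, widthPx = 2000, pixelSizeUm = 1,
                           confluence = 0.95, nCells = NA,
                           cellRadiusPx = 40, cellRadiusDispersion = 0.15,
                           dropletDensity = 10, dropletRadiusPx = 3,
                           targetLipidFraction = NA,
                           intensityBackground = 10, intensityCell = 100,
                           intensityDroplet = 200,
                           noiseSd = 5,
                           noiseModel = c("gaussian", "poisson"),
                           seed = 1L) {
  new("ImageGenParams",
    heightPx = as.integer(heightPx), widthPx = as.integer(widthPx),
    pixelSizeUm = pixelSizeUm, confluence = confluence,
    nCells = as.integer(nCells),
    cellRadiusPx = cellRadiusPx, cellRadiusDispersion = cellRadiusDispersion,
    dropletDensity = dropletDensity, dropletRadiusPx = dropletRadiusPx,
    targetLipidFraction = as.numeric(targetLipidFraction),
    intensityBackground = intensityBackground, intensityCell = intensityCell,
    intensityDroplet = intensityDroplet, noiseSd = noiseSd,
    noiseModel = match.arg(noiseModel), seed = as.integer(seed))
}

#' AssayGenParams: parameters of the synthetic efflux-assay generator
#'
#' @slot nWellsPerGroup wells per condition.
#' @slot groupMeans named numeric vector mapping condition to its true
#'   efflux fraction in [0, 1].
#' @slot countScale expected total scintillation counts per well.
#' @slot noiseModel \code{"poisson"} (counting statistics) or
#'   \code{"gaussian"}.
#' @slot noiseSd Gaussian noise SD on each fraction's counts (ignored for
#'   Poisson; 0 gives noiseless tables).
#' @slot seed integer RNG seed.
#' @seealso [assayGenParams()], [generateEffluxTable()]
#' @export
setClass("AssayGenParams",
  representation(
    nWellsPerGroup = "integer",
    groupMeans = "numeric",
    countScale = "numeric",
    noiseModel = "character",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("AssayGenParams", function(object) {
  msg <- character()
  if (object@nWellsPerGroup < 1L)
    msg <- c(msg, "nWellsPerGroup must be positive")
  if (is.null(names(object@groupMeans)) || any(names(object@groupMeans) == ""))
    msg <- c(msg, "groupMeans must be a named vector (condition -> fraction)")
  if (any(object@groupMeans < 0 | object@groupMeans > 1))
    msg <- c(msg, "true efflux fractions must lie in [0, 1]")
  if (object@countScale <= 0) msg <- c(msg, "countScale must be positive")
  if (!object@noiseModel %in% c("poisson", "gaussian"))
    msg <- c(msg, "noiseModel must be 'poisson' or 'gaussian'")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct AssayGenParams
#'
#' @param nWellsPerGroup,groupMeans,countScale,noiseModel,noiseSd,seed see
#'   [AssayGenParams-class].
#' @return A validated [AssayGenParams-class].
#' @examples
#' p <- assayGenParams(groupMeans = c(Veh = 0.05, `5A-SM` = 0.6))
#' @export
assayGenParams <- function(nWellsPerGroup = 3,
                           groupMeans = c(Veh = 0.05, Treated = 0.6),
                           countScale = 1e5,
                           noiseModel = c("poisson", "gaussian"),
                           noiseSd = 0, seed = 1L) {
  new("AssayGenParams",
    nWellsPerGroup = as.integer(nWellsPerGroup), groupMeans = groupMeans,
    countScale = countScale, noiseModel = match.arg(noiseModel),
    noiseSd = noiseSd, seed = as.integer(seed))
}
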