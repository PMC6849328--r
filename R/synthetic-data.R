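## Seeded synthetic-data generators: SRS-like images with exact ground
## truth, efflux count tables, and Ct tables. Every generator uses a local
## RNG scope so identical parameters + seed give bit-identical output and
## no global RNG state leaks.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(expr)
}

# Rasterize one perturbed ellipse into linear pixel indices of an H x W grid.
# Centre (cy, cx) in 1-based pixel coords; semi-axes a >= b; rotation theta;
# smooth radial boundary perturbation via low-order Fourier modes.
.rasterCell <- function(cy, cx, a, b, theta, amps, phases, H, W) {
  half <- ceiling(max(a, b) * (1 + sum(abs(amps))) + 1)
  r0 <- max(1L, floor(cy - half)); r1 <- min(H, ceiling(cy + half))
  c0 <- max(1L, floor(cx - half)); c1 <- min(W, ceiling(cx + half))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  dy <- rows - cy; dx <- rep(cols - cx, each = length(rows))
  dy <- rep(dy, times = length(cols))
  ct <- cos(theta); st <- sin(theta)
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  rho <- sqrt((u / a)^2 + (v / b)^2)
  phi <- atan2(v, u)
  bound <- 1
  for (k in seq_along(amps))
    bound <- bound + amps[k] * cos((k + 1) * phi + phases[k])
  inside <- rho <= bound
  if (!any(inside)) return(integer(0))
  idx <- rep((cols - 1L) * H, each = length(rows)) + rep(rows, length(cols))
  idx[inside]
}

# Stamp discs of one integer radius at the given linear-index centres.
.stampDiscs <- function(centerIdx, radius, H, W) {
  r <- max(1L, as.integer(round(radius)))
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= r^2, , drop = FALSE]
  cr <- ((centerIdx - 1L) %% H) + 1L
  cc <- ((centerIdx - 1L) %/% H) + 1L
  rr <- rep(cr, each = nrow(off)) + rep(off$dr, times = length(cr))
  cc2 <- rep(cc, each = nrow(off)) + rep(off$dc, times = length(cr))
  ok <- rr >= 1L & rr <= H & cc2 >= 1L & cc2 <= W
  (cc2[ok] - 1L) * H + rr[ok]
}

#' Generate a synthetic SRS-like image with exact ground truth
#'
#' Emulates a label-free lipid-channel image of a cell monolayer: a dim
#' uniform media background, brighter cell foreground built from randomly
#' placed perturbed ellipses (overlaps merge in the mask but every placed
#' centre counts towards the true cell count), and high-intensity punctate
#' lipid droplets confined to cell interiors, plus Gaussian or Poisson
#' noise. The returned [GroundTruth-class] records the exact masks, the
#' mask-derived lipid-area fraction and the placed-cell count, which
#' downstream recovery tests treat as truth.
#'
#' @param params an [ImageGenParams-class] from [imageGenParams()].
#' @return A list with elements \code{image} ([IntensityImage-class]) and
#'   \code{truth} ([GroundTruth-class]).
#' @details When \code{nCells} is NA the cell number is derived from the
#'   target \code{confluence} by inverting the Boolean coverage model
#'   \eqn{c = 1 - \exp(-n A_{cell} / A_{img})}; coverage above 0.995 is
#'   refused because random blob placement cannot reach full confluence.
#'   When \code{targetLipidFraction} is set, droplets are placed in chunks
#'   until the droplet/cell pixel ratio reaches the target; otherwise
#'   \code{round(dropletDensity * nCells)} droplets are placed.
#' @examples
#' g <- generateSrsImage(imageGenParams(heightPx = 300, widthPx = 300,
#'                                      confluence = 0.6, seed = 7))
#' g$truth
#' @export
generateSrsImage <- function(params) {
  stopifnot(is(params, "ImageGenParams"))
  validObject(params)
  H <- params@heightPx; W <- params@widthPx
  meanCellArea <- pi * params@cellRadiusPx^2
  nCells <- params@nCells
  if (is.na(nCells)) {
    if (params@confluence > 0.995)
      stop("confluence > 0.995 cannot be reached by random cell placement; ",
           "use a lower target or a constant image")
    nCells <- as.integer(round(-log(1 - params@confluence) * H * W /
                                 meanCellArea))
  }
  if (nCells * meanCellArea > 10 * H * W)
    stop("impossible geometry: ", nCells, " cells of mean area ",
         round(meanCellArea), " px cannot fit a ", H, " x ", W, " image")
  .withSeed(params@seed, {
    cellMask <- matrix(FALSE, H, W)
    labels <- matrix(0L, H, W)
    centers <- matrix(numeric(0), 0L, 2L,
                      dimnames = list(NULL, c("row", "col")))
    if (nCells > 0L) {
      cy <- runif(nCells, 1, H); cx <- runif(nCells, 1, W)
      centers <- cbind(row = cy, col = cx)
      rad <- params@cellRadiusPx *
        exp(rnorm(nCells, 0, params@cellRadiusDispersion))
      ecc <- exp(rnorm(nCells, 0, 0.2))
      theta <- runif(nCells, 0, pi)
      for (i in seq_len(nCells)) {
        amps <- rnorm(3, 0, 0.04)
        phases <- runif(3, 0, 2 * pi)
        idx <- .rasterCell(cy[i], cx[i], rad[i] * sqrt(ecc[i]),
                           rad[i] / sqrt(ecc[i]), theta[i],
                           amps, phases, H, W)
        cellMask[idx] <- TRUE
        labels[idx] <- i
      }
    }
    nCellPx <- sum(cellMask)
    dropletMask <- matrix(FALSE, H, W)
    if (nCellPx > 0L) {
      cellIdx <- which(cellMask)
      dropArea <- pi * params@dropletRadiusPx^2
      if (!is.na(params@targetLipidFraction) &&
          params@targetLipidFraction > 0) {
        needed <- ceiling(params@targetLipidFraction * nCellPx)
        for (iter in 1:200) {
          have <- sum(dropletMask)
          if (have >= needed) break
          # undershoot each chunk (x0.7) so the final overshoot stays small
          chunk <- max(10L, ceiling(0.7 * (needed - have) / dropArea))
          ctr <- cellIdx[sample.int(nCellPx, chunk, replace = TRUE)]
          dropletMask[.stampDiscs(ctr, params@dropletRadiusPx, H, W)] <- TRUE
          dropletMask <- dropletMask & cellMask
        }
      } else if (params@dropletDensity > 0 && nCells > 0L) {
        nDrop <- as.integer(round(params@dropletDensity * nCells))
        if (nDrop > 0L) {
          ctr <- cellIdx[sample.int(nCellPx, nDrop, replace = TRUE)]
          dropletMask[.stampDiscs(ctr, params@dropletRadiusPx, H, W)] <- TRUE
          dropletMask <- dropletMask & cellMask
        }
      }
    }
    img <- matrix(params@intensityBackground, H, W)
    img[cellMask] <- params@intensityCell
    img[dropletMask] <- params@intensityDroplet
    if (params@noiseModel == "gaussian") {
      if (params@noiseSd > 0)
        img[] <- pmax(0, img + rnorm(H * W, 0, params@noiseSd))
    } else {
      img[] <- as.numeric(rpois(H * W, img))
    }
    truth <- new("GroundTruth",
      cellMask = cellMask, dropletMask = dropletMask,
      perCellLabels = labels, centers = centers,
      trueLipidFraction = if (nCellPx > 0) sum(dropletMask) / nCellPx else 0,
      lipidFractionDefined = nCellPx > 0L,
      trueCellCount = nCells)
    list(image = IntensityImage(img, params@pixelSizeUm, "2845cm-1"),
         truth = truth)
  })
}

#' Generate a synthetic radiolabel efflux count table
#'
#' Emulates the paired media/cell scintillation counts of a lipid efflux
#' assay. Per well, the expected media counts are (true fraction x
#' countScale) and expected cell counts the remainder, so that expected
#' media/(media+cell) equals the condition's true efflux fraction.
#'
#' @param params an [AssayGenParams-class] from [assayGenParams()].
#' @return data.frame with columns \code{well_id}, \code{condition},
#'   \code{media_counts}, \code{cell_counts}.
#' @examples
#' tbl <- generateEffluxTable(assayGenParams(
#'   groupMeans = c(Veh = 0.05, `5A-SM` = 0.6), noiseModel = "gaussian"))
#' head(tbl)
#' @export
generateEffluxTable <- function(params) {
  stopifnot(is(params, "AssayGenParams"))
  validObject(params)
  .withSeed(params@seed, {
    conds <- names(params@groupMeans)
    n <- params@nWellsPerGroup
    condition <- rep(conds, each = n)
    f <- rep(params@groupMeans, each = n)
    mediaMu <- f * params@countScale
    cellMu <- (1 - f) * params@countScale
    if (params@noiseModel == "poisson") {
      media <- as.numeric(rpois(length(f), mediaMu))
      cells <- as.numeric(rpois(length(f), cellMu))
    } else {
      media <- pmax(0, mediaMu + rnorm(length(f), 0, params@noiseSd))
      cells <- pmax(0, cellMu + rnorm(length(f), 0, params@noiseSd))
    }
    data.frame(
      well_id = sprintf("%s_w%02d", condition, rep(seq_len(n), length(conds))),
      condition = condition,
      media_counts = media,
      cell_counts = cells,
      stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic qPCR Ct table
#'
#' Builds a long-format Ct table (one row per sample x gene) in which the
#' target gene's expected Ct is shifted by -log2(fold change) relative to
#' the calibrator condition while the reference gene stays constant in
#' expectation, so that the 2^-ddCt computation recovers the configured
#' fold changes.
#'
#' @param conditions character vector of condition names; the first is the
#'   calibrator unless \code{calibrator} says otherwise.
#' @param trueFoldChanges named numeric vector of true fold changes relative
#'   to the calibrator (all > 0); conditions missing from it default to 1.
#' @param ctNoiseSd Gaussian noise SD on every Ct value (cycles; 0 =
#'   noiseless).
#' @param seed integer RNG seed.
#' @param nPerCondition biological samples per condition (default 3).
#' @param targetGene,referenceGene gene labels (defaults "TARGET", "GAPDH").
#' @param calibrator calibrator condition (default first of
#'   \code{conditions}).
#' @param baseCtTarget,baseCtReference expected Ct of the target gene in the
#'   calibrator and of the reference gene everywhere (defaults 25 and 20).
#' @return data.frame with columns \code{sample_id}, \code{condition},
#'   \code{gene}, \code{ct}.
#' @examples
#' ct <- generateCtTable(c("Veh", "5A-SM"), c(`5A-SM` = 4), ctNoiseSd = 0)
#' ddctRelativeExpression(ct)    # recovers fold 4 exactly
#' @export
generateCtTable <- function(conditions, trueFoldChanges = NULL,
                            ctNoiseSd = 0, seed = 1L, nPerCondition = 3L,
                            targetGene = "TARGET", referenceGene = "GAPDH",
                            calibrator = conditions[1L],
                            baseCtTarget = 25, baseCtReference = 20) {
  folds <- setNames(rep(1, length(conditions)), conditions)
  if (!is.null(trueFoldChanges)) {
    if (any(trueFoldChanges <= 0))
      stop("fold changes must be positive")
    bad <- setdiff(names(trueFoldChanges), conditions)
    if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "))
    folds[names(trueFoldChanges)] <- trueFoldChanges
  }
  if (!calibrator %in% conditions) stop("calibrator must be a condition")
  .withSeed(seed, {
    rows <- lapply(conditions, function(cond) {
      sid <- sprintf("%s_s%02d", cond, seq_len(nPerCondition))
      ctT <- baseCtTarget - log2(folds[[cond]] / folds[[calibrator]]) +
        rnorm(nPerCondition, 0, ctNoiseSd)
      ctR <- baseCtReference + rnorm(nPerCondition, 0, ctNoiseSd)
      data.frame(
        sample_id = rep(sid, 2L),
        condition = cond,
        gene = rep(c(targetGene, referenceGene), each = nPerCondition),
        ct = c(ctT, ctR),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
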