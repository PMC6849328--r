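# The two-layer thresholding pipeline, stage by stage, against generator
# ground truth and enumeration oracles.

test_that("background estimation separates media from cells", {
  # all-zero image: background level 0, nothing classified foreground
  z <- IntensityImage(matrix(0, 60, 60))
  bg <- estimateBackground(z)
  expect_identical(bg$backgroundLevel, 0)
  expect_false(any(pixels(z) > bg$foregroundThreshold))

  # exact two-level image: foreground mask is exactly the bright pixels
  img <- twoLevelImage(100, fg = 0.5, low = 10, high = 100)
  bg2 <- estimateBackground(img)
  expect_identical(pixels(img) > bg2$foregroundThreshold, pixels(img) == 100)

  # noiseless synthetic: threshold strictly between the two modes
  g <- smallSynthetic(seed = 2, confluence = 0.7, size = 400)
  bg3 <- estimateBackground(g$image)
  expect_gt(bg3$foregroundThreshold, 10)
  expect_lt(bg3$foregroundThreshold, 100)
  expect_equal(bg3$backgroundLevel, 10)

  # with droplets and high confluence the media class must still win
  gd <- smallSynthetic(seed = 2, confluence = 0.9, target = 0.15,
                       size = 400, noiseSd = 5)
  bg4 <- estimateBackground(gd$image)
  expect_lt(bg4$foregroundThreshold, 100)
  expect_lt(abs(bg4$backgroundLevel - 10), 2)
})

test_that("tiling equals exhaustive enumeration and rejects oversize windows", {
  img <- IntensityImage(matrix(0, 250, 250))
  expect_identical(tileFovs(img), data.frame(row0 = 0L, col0 = 0L))

  # 300x300: offset 100 would overhang, so exactly one window survives
  expect_identical(nrow(tileFovs(IntensityImage(matrix(0, 300, 300)))), 1L)

  # property: random rectangular sizes match the loop oracle exactly
  set.seed(404)
  for (i in 1:15) {
    h <- sample(250:900, 1); w <- sample(250:900, 1)
    got <- tileFovs(IntensityImage(matrix(0, h, w)))
    want <- enumerateWindowsOracle(h, w, 250L, 100L)
    expect_identical(got$row0, as.integer(want$row0))
    expect_identical(got$col0, as.integer(want$col0))
  }
  expect_error(tileFovs(IntensityImage(matrix(0, 200, 500))), "larger")
  expect_warning(pipelineConfig(windowPx = 50, stepPx = 80), "gaps")
})

test_that("confluence is the in-window foreground fraction", {
  cfg <- pipelineConfig()
  px <- matrix(10, 250, 250)
  img <- IntensityImage(px)
  expect_identical(computeConfluence(img, list(row0 = 0, col0 = 0), 50), 0)
  img2 <- IntensityImage(matrix(100, 250, 250))
  expect_identical(computeConfluence(img2, list(row0 = 0, col0 = 0), 50), 1)
  # half-covered window, exact split
  px[, 1:125] <- 100
  expect_identical(computeConfluence(IntensityImage(px),
                                     list(row0 = 0, col0 = 0), 50), 0.5)
})

test_that("FOV selection matches the ground-truth oracle in the noiseless limit", {
  g <- smallSynthetic(seed = 9, confluence = 0.8, size = 700)
  bg <- estimateBackground(g$image)
  fovs <- tileFovs(g$image)
  fovs$confluence <- vapply(seq_len(nrow(fovs)), function(i)
    computeConfluence(g$image, fovs[i, ], bg$foregroundThreshold), 0)
  sel <- selectFovs(fovs)
  # oracle: per-window coverage computed directly from the true cell mask
  oracle <- vapply(seq_len(nrow(fovs)), function(i) {
    r <- fovs$row0[i] + 1:250; cl <- fovs$col0[i] + 1:250
    mean(cellMask(g$truth)[r, cl]) >= 0.9
  }, NA)
  expect_identical(fovs$confluence >= 0.9, oracle)
  expect_identical(nrow(sel), sum(oracle))
  expect_true(all(sel$included))

  # blank image: empty selection
  blank <- IntensityImage(matrix(5, 400, 400))
  bfov <- tileFovs(blank)
  bfov$confluence <- 0
  expect_identical(nrow(selectFovs(bfov)), 0L)
})

test_that("droplet segmentation recovers the true droplet mask", {
  # no contrast within cells: zero droplet pixels under both rules
  flat <- IntensityImage(matrix(100, 250, 250))
  fg <- matrix(TRUE, 250, 250)
  for (m in c("otsu_within_cells", "foreground_mean_plus_kSD")) {
    seg <- segmentLipidDroplets(flat, list(row0 = 0, col0 = 0), fg,
                                pipelineConfig(dropletMethod = m))
    expect_identical(seg$lipidPx, 0L)
  }

  # noiseless synthetic FOV: exact recovery (size filter disabled so
  # border-clipped droplets below 4 px are kept too)
  g <- smallSynthetic(seed = 4, confluence = 0.95, target = 0.1, size = 400)
  bg <- estimateBackground(g$image)
  fgm <- pixels(g$image) > bg$foregroundThreshold
  cfg <- pipelineConfig(minDropletPx = 0)
  seg <- segmentLipidDroplets(g$image, list(row0 = 50, col0 = 50), fgm, cfg)
  truthWin <- dropletMask(g$truth)[51:300, 51:300]
  expect_identical(seg$dropletMask, truthWin)

  # size filter: a 3-px droplet vanishes when min_droplet_px = 5
  px <- matrix(100, 250, 250); px[10, 10:12] <- 200
  seg2 <- segmentLipidDroplets(IntensityImage(px), list(row0 = 0, col0 = 0),
                               matrix(TRUE, 250, 250),
                               pipelineConfig(minDropletPx = 5))
  expect_identical(seg2$lipidPx, 0L)

  # empty intracellular set is flagged, not an error
  seg3 <- segmentLipidDroplets(flat, list(row0 = 0, col0 = 0),
                               matrix(FALSE, 250, 250), pipelineConfig())
  expect_false(seg3$defined)
})

test_that("cell counting counts components intersecting the window", {
  # 5 well-separated discs inside one window
  px <- matrix(10, 300, 300)
  centers <- cbind(c(50, 50, 150, 150, 250), c(50, 250, 150, 60, 250))
  for (i in 1:5) {
    r <- centers[i, 1]; c <- centers[i, 2]
    px[(r - 12):(r + 12), (c - 12):(c + 12)] <- 100
  }
  img <- IntensityImage(px)
  cfg <- pipelineConfig(windowPx = 300, stepPx = 300)
  expect_identical(countCells(img, list(row0 = 0, col0 = 0), cfg), 5L)

  # two overlapping discs merge into one component: documented bias
  px2 <- matrix(10, 300, 300)
  px2[100:160, 100:160] <- 100
  px2[150:210, 150:210] <- 100
  expect_identical(countCells(IntensityImage(px2),
                              list(row0 = 0, col0 = 0), cfg), 1L)

  # zero-cell image: count 0 and normalized ratio flagged undefined
  blank <- IntensityImage(matrix(10, 300, 300))
  s <- runSrsPipeline(blank, pipelineConfig(windowPx = 300, stepPx = 300))
  expect_identical(s@nFovsIncluded, 0L)
  expect_false(any(fovTable(s)$norm_defined))

  expect_error(countCells(img, list(row0 = 0, col0 = 0),
                          pipelineConfig(cellCountSource = "provided")),
               "counts table")
})

test_that("full pipeline recovers truth, is deterministic and monotone", {
  # droplet-free confluent image: mean lipid ratio exactly 0
  g0 <- smallSynthetic(seed = 5, confluence = 0.97, size = 500)
  s0 <- runSrsPipeline(g0$image)
  expect_gt(nFovsIncluded(s0), 0)
  expect_identical(meanLipidRatio(s0), 0)

  # recovery at low noise
  g <- generateSrsImage(imageGenParams(heightPx = 500, widthPx = 500,
    confluence = 0.95, targetLipidFraction = 0.10, noiseSd = 2, seed = 6))
  s <- runSrsPipeline(g$image)
  expect_lt(abs(meanLipidRatio(s) - trueLipidFraction(g$truth)), 0.02)

  # determinism: identical image + config -> identical summary
  s2 <- runSrsPipeline(g$image)
  expect_identical(fovTable(s), fovTable(s2))
  expect_identical(meanLipidRatio(s), meanLipidRatio(s2))

  # monotonicity: more droplets never lowers the estimate (noiseless,
  # same seed so the cell geometry is identical across densities)
  est <- vapply(c(0, 3, 8, 15), function(d) {
    gi <- generateSrsImage(imageGenParams(heightPx = 400, widthPx = 400,
      confluence = 0.95, dropletDensity = d, noiseSd = 0, seed = 77))
    meanLipidRatio(runSrsPipeline(gi$image))
  }, 0)
  expect_true(all(diff(est) >= 0))

  # ratios bounded, never NaN
  tab <- fovTable(s)
  ok <- !is.na(tab$lipid_ratio)
  expect_true(all(tab$lipid_ratio[ok] >= 0 & tab$lipid_ratio[ok] <= 1))
  expect_false(any(vapply(tab, function(col) any(is.nan(col)), NA)))
  expect_true(all(tab$lipid_px[ok] <= tab$intracellular_px[ok]))
})

test_that("normalization modes and provided counts are honoured", {
  g <- smallSynthetic(seed = 8, confluence = 0.95, target = 0.05,
                      size = 400, noiseSd = 2)
  sImg <- runSrsPipeline(g$image, pipelineConfig(normalizeBy = "image"))
  tab <- fovTable(sImg)
  inc <- tab[tab$included & tab$norm_defined, ]
  # image mode: every FOV divided by the same whole-image count
  expect_true(length(unique(inc$cell_count)) == 1L)
  expect_equal(inc$normalized_ratio, inc$lipid_ratio / inc$cell_count[1])

  sProv <- runSrsPipeline(g$image,
    pipelineConfig(cellCountSource = "provided", normalizeBy = "image"),
    provided = 10)
  inc2 <- fovTable(sProv)
  inc2 <- inc2[inc2$included, ]
  expect_true(all(inc2$cell_count == 10L))
})
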