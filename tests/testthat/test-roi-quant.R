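# Marker-masked ROI quantification and co-localization.

test_that("marker thresholding yields one ROI per disjoint blob", {
  blank <- IntensityImage(matrix(0, 80, 80), channelLabel = "marker")
  expect_identical(nRois(maskFromMarker(blank)), 0L)

  # three disjoint blobs with known areas
  m <- matrix(0, 120, 120)
  m[10:19, 10:19] <- 100      # 100 px
  m[50:69, 50:59] <- 100      # 200 px
  m[100:102, 100:109] <- 100  # 30 px
  rois <- maskFromMarker(IntensityImage(m, pixelSizeUm = 2))
  expect_identical(nRois(rois), 3L)
  meas <- measureRois(IntensityImage(matrix(7, 120, 120)), rois)
  expect_setequal(meas$area_px, c(100L, 200L, 30L))
  expect_equal(meas$area_um2, meas$area_px * 4)
  expect_equal(meas$mean_intensity, rep(7, 3))

  # min area filter removes the small blob
  expect_identical(nRois(maskFromMarker(IntensityImage(m), minAreaPx = 50)),
                   2L)

  # two blobs that touch merge into a single ROI
  m2 <- matrix(0, 60, 60)
  m2[10:30, 10:30] <- 100
  m2[30:50, 30:50] <- 100
  expect_identical(nRois(maskFromMarker(IntensityImage(m2))), 1L)
})

test_that("ROI measurements match direct arithmetic and respect labels", {
  lab <- matrix(0L, 20, 20)
  lab[3, 1:10] <- 1L                      # one 10-px ROI
  rois <- new("ROISet", labels = lab, pixelSizeUm = 1,
              sourceChannel = "manual")
  px <- matrix(0, 20, 20)
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 100)
  px[3, 1:10] <- vals
  meas <- measureRois(IntensityImage(px), rois)
  expect_equal(meas$mean_intensity, mean(vals))
  expect_equal(meas$integrated_intensity, sum(vals))
  expect_equal(attr(meas, "background_mean"), 0)

  # background subtraction mode
  px[lab == 0L] <- 5
  ms <- measureRois(IntensityImage(px), rois, backgroundSubtract = TRUE)
  expect_equal(ms$mean_intensity, mean(vals) - 5)

  # empty ROI set -> empty measurement table
  empty <- new("ROISet", labels = matrix(0L, 20, 20))
  expect_identical(nrow(measureRois(IntensityImage(px), empty)), 0L)

  # measurements are invariant to ROI label permutation
  lab2 <- matrix(0L, 20, 20)
  lab2[1, 1:5] <- 1L; lab2[10, 1:8] <- 2L
  perm <- lab2
  perm[perm == 1L] <- 9L; perm[perm == 2L] <- 1L; perm[perm == 9L] <- 2L
  target <- IntensityImage(matrix(runif(400), 20, 20))
  a <- measureRois(target, new("ROISet", labels = lab2))
  b <- measureRois(target, new("ROISet", labels = perm))
  expect_equal(sort(a$mean_intensity), sort(b$mean_intensity))
  expect_lte(sum(a$area_px), 400)
})

test_that("Pearson co-localization behaves like a correlation", {
  set.seed(12)
  a <- matrix(runif(10000, 10, 200), 100, 100)
  expect_equal(pearsonColocalization(a, a), 1)
  expect_equal(pearsonColocalization(a, -a + 300), -1)
  # independent channels decorrelate
  b <- matrix(runif(10000, 10, 200), 100, 100)
  expect_lt(abs(pearsonColocalization(a, b)), 0.05)
  # symmetry and affine invariance (positive slope)
  r1 <- pearsonColocalization(a, b)
  expect_equal(pearsonColocalization(b, a), r1)
  expect_equal(pearsonColocalization(2.5 * a + 7, b), r1)
  # masked version only sees masked pixels
  mask <- matrix(FALSE, 100, 100); mask[1:50, ] <- TRUE
  expect_equal(pearsonColocalization(a, b, mask),
               cor(as.numeric(a[mask]), as.numeric(b[mask])))
  # degenerate channel flagged undefined
  expect_warning(r0 <- pearsonColocalization(a, matrix(1, 100, 100)),
                 "zero-variance")
  expect_true(is.na(r0))
  expect_error(pearsonColocalization(a, b[1:50, ]), "shapes")
})

test_that("tile gating keeps exactly the tiles above the confluence gate", {
  # 16 tiles with known coverage; 12 at or above 0.90
  cov <- c(0.95, 0.2, 0.97, 0.91, 0.5, 0.99, 0.93, 0.92, 0.97, 0.96,
           0.90, 0.94, 0.1, 0.98, 0.3, 0.95)
  tiles <- lapply(cov, function(f) twoLevelImage(60, fg = f))
  gated <- gateTilesByConfluence(tiles)
  expect_identical(gated$included, cov >= 0.90)
  expect_identical(sum(gated$included), 12L)
  expect_length(attr(gated, "included_tiles"), 12L)

  # all-blank tiles: none retained (constant image -> zero confluence)
  blanks <- lapply(1:4, function(i) IntensityImage(matrix(3, 60, 60)))
  expect_identical(sum(gateTilesByConfluence(blanks)$included), 0L)

  # threshold 0 retains everything
  expect_true(all(gateTilesByConfluence(tiles, threshold = 0)$included))
})
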