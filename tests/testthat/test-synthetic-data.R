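# Synthetic-data generators: determinism, ground-truth consistency, and
# recovery of configured truths by the downstream calculations.

test_that("image generator handles degenerate cases and refuses bad params", {
  # empty image: no cells, no droplets; fraction reported 0 with flag unset
  g <- smallSynthetic(nCells = 0, size = 120)
  expect_false(any(cellMask(g$truth)))
  expect_identical(trueLipidFraction(g$truth), 0)
  expect_false(g$truth@lipidFractionDefined)
  expect_identical(trueCellCount(g$truth), 0L)

  # cells but zero droplet density: lipid fraction exactly 0
  g2 <- smallSynthetic(nCells = 20, size = 300, dropletDensity = 0)
  expect_true(any(cellMask(g2$truth)))
  expect_false(any(dropletMask(g2$truth)))
  expect_identical(trueLipidFraction(g2$truth), 0)

  # invalid intensity ordering refused
  expect_error(imageGenParams(intensityDroplet = 50, intensityCell = 100),
               "ordering")
  # impossible geometry refused, not silently truncated
  expect_error(generateSrsImage(imageGenParams(
    heightPx = 100, widthPx = 100, nCells = 5000, cellRadiusPx = 40)),
    "impossible geometry")
  # unreachable full confluence refused
  expect_error(generateSrsImage(imageGenParams(
    heightPx = 100, widthPx = 100, confluence = 1)), "confluence")
})

test_that("generators are bit-identical under a fixed seed", {
  p <- imageGenParams(heightPx = 200, widthPx = 200, confluence = 0.7,
                      targetLipidFraction = 0.08, seed = 42)
  a <- generateSrsImage(p)
  b <- generateSrsImage(p)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(cellMask(a$truth), cellMask(b$truth))
  expect_identical(dropletMask(a$truth), dropletMask(b$truth))

  ap <- assayGenParams(groupMeans = c(Veh = 0.05, Trt = 0.6), seed = 7)
  expect_identical(generateEffluxTable(ap), generateEffluxTable(ap))
  expect_identical(generateCtTable(c("a", "b"), c(b = 2), 0.2, seed = 9),
                   generateCtTable(c("a", "b"), c(b = 2), 0.2, seed = 9))
  # generators do not disturb the caller's RNG stream
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(generateSrsImage(p)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("ground truth is internally consistent across seeds", {
  for (seed in 1:5) {
    g <- smallSynthetic(seed = seed, confluence = 0.6, target = 0.1,
                        size = 250)
    tr <- g$truth
    expect_false(any(dropletMask(tr) & !cellMask(tr)))
    expect_identical(trueLipidFraction(tr),
                     sum(dropletMask(tr)) / sum(cellMask(tr)))
    expect_identical(nrow(tr@centers), trueCellCount(tr))
    # target fraction reached and not grossly overshot
    expect_gte(trueLipidFraction(tr), 0.1)
    expect_lt(trueLipidFraction(tr), 0.115)
  }
})

test_that("noiseless image is exactly tri-modal at the configured levels", {
  g <- smallSynthetic(seed = 3, confluence = 0.5, target = 0.1, size = 300)
  expect_setequal(unique(as.vector(pixels(g$image))), c(10, 100, 200))
  expect_identical(sum(pixels(g$image) == 200), sum(dropletMask(g$truth)))
})

test_that("efflux tables carry the configured truth", {
  # zero-fraction group, noiseless: all media counts exactly 0
  t0 <- generateEffluxTable(assayGenParams(
    groupMeans = c(Veh = 0), noiseModel = "gaussian", noiseSd = 0))
  expect_true(all(t0$media_counts == 0))

  # noiseless recovery: percent efflux is exactly 60 on every well
  t1 <- generateEffluxTable(assayGenParams(
    groupMeans = c(x = 0.6), noiseModel = "gaussian", noiseSd = 0))
  expect_equal(percentEfflux(t1$media_counts, t1$cell_counts),
               rep(60, nrow(t1)))
  expect_equal(mean(t1$media_counts + t1$cell_counts), 1e5)

  # Poisson sampling: mean within 3 SE of truth (binomial-style oracle)
  tp <- generateEffluxTable(assayGenParams(
    nWellsPerGroup = 200, groupMeans = c(x = 0.6), countScale = 1e5,
    noiseModel = "poisson", seed = 11))
  p <- percentEfflux(tp$media_counts, tp$cell_counts) / 100
  se <- sqrt(0.6 * 0.4 / 1e5) / sqrt(200)
  expect_lt(abs(mean(p) - 0.6), 3 * se)

  expect_error(assayGenParams(countScale = -1), "positive")
  expect_error(assayGenParams(groupMeans = c(x = 1.2)), "\\[0, 1\\]")
})

test_that("Ct tables encode fold changes as -log2 shifts", {
  # fold 1, noiseless: every ddCt is 0
  c1 <- generateCtTable(c("Veh", "Trt"), c(Trt = 1), ctNoiseSd = 0)
  r1 <- ddctRelativeExpression(c1)
  expect_equal(r1$ddct, c(0, 0))

  # fold 4, noiseless: target Ct shifted by exactly -2 cycles
  c4 <- generateCtTable(c("Veh", "Trt"), c(Trt = 4), ctNoiseSd = 0)
  tgt <- tapply(c4$ct[c4$gene == "TARGET"],
                c4$condition[c4$gene == "TARGET"], unique)
  expect_equal(unname(tgt["Trt"] - tgt["Veh"]), -2)

  # Monte-Carlo recovery: fold 2 at sd 0.1, n = 50 -> within 10%
  cm <- generateCtTable(c("Veh", "Trt"), c(Trt = 2), ctNoiseSd = 0.1,
                        seed = 5, nPerCondition = 50)
  fold <- ddctRelativeExpression(cm)
  expect_lt(abs(fold$fold_change[fold$condition == "Trt"] - 2), 0.2)

  expect_error(generateCtTable(c("a", "b"), c(b = -1)), "positive")
})
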