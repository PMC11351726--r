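test_that("fitThreshold separates a sparse bright class from background", {
  set.seed(11)
  x <- matrix(10, 100, 100)
  x[sample(1e4, 100)] <- 200          # 1% cells
  st <- fitThreshold(x)
  expect_gt(st@baseThreshold, 10)
  expect_lt(st@baseThreshold, 200)
  expect_equal(st@baseBrightness, 10)
})

test_that("fitThreshold rejects constant images", {
  expect_error(fitThreshold(matrix(7, 10, 10)), "degenerate image")
})

test_that("Otsu threshold matches an exhaustive between-class-variance search", {
  set.seed(42)
  x <- matrix(c(rnorm(9000, 100, 10), rnorm(1000, 200, 10)), 100, 100)
  x <- pmax(x, 0)
  st <- fitThreshold(x, kFloor = NA)     # pure Otsu
  oracle <- bruteForceOtsu(x)
  binWidth <- diff(range(x)) / 256
  expect_lt(abs(st@baseThreshold - oracle), 2 * binWidth + 1e-9)
  # and the threshold sits in the gap between the modes
  expect_gt(st@baseThreshold, 130)
  expect_lt(st@baseThreshold, 170)
})

test_that("background floor rescues thresholding of very sparse streaks", {
  # streaks cover ~1e-3 of the image: Otsu's objective peaks inside the
  # background mode, the median + k*mad floor stays above it
  set.seed(13)
  x <- matrix(rnorm(300 * 300, 500, 100), 300, 300)
  x[10:14, 10:29] <- 1000              # one streak, SNR 5
  x <- pmax(x, 0)
  stPure <- fitThreshold(x, kFloor = NA)
  stFloor <- fitThreshold(x)
  expect_lt(stPure@baseThreshold, 800)           # Otsu alone fails here
  expect_gt(stFloor@baseThreshold, 800)
  expect_lt(stFloor@baseThreshold, 1000)
  mask <- x > stFloor@baseThreshold
  expect_gt(mean(mask[10:14, 10:29]), 0.9)
})

test_that("adaptThreshold is the identity on the fitting record and scales
          homogeneously with brightness", {
  set.seed(7)
  x <- matrix(c(rnorm(5000, 100, 10), rnorm(5000, 300, 10)), 100, 100)
  x <- pmax(x, 0)
  st <- fitThreshold(x, kFloor = NA)
  expect_equal(adaptThreshold(st, x), st@baseThreshold)
  expect_equal(adaptThreshold(st, x * 1.5), 1.5 * st@baseThreshold)
  expect_equal(adaptThreshold(st, x * 10), 2.0 * st@baseThreshold)  # clipped
  expect_equal(adaptThreshold(st, x * 0.1), 0.5 * st@baseThreshold)
  st0 <- new("ThresholdState", baseThreshold = 5, baseBrightness = 0,
             scaleBounds = c(0.5, 2))
  expect_error(adaptThreshold(st0, x), "degenerate state")
})

test_that("detection is equivariant to a constant intensity offset", {
  sim <- simulateRecord(smallParams(seed = 21L, noiseSd = 50))
  ch <- channelMatrix(sim$kymograph, "reporter")
  st1 <- fitThreshold(ch)
  st2 <- fitThreshold(ch + 500)
  m1 <- ch > st1@baseThreshold
  m2 <- (ch + 500) > st2@baseThreshold
  expect_identical(m1, m2)
})

test_that("labelComponents agrees with a flood-fill oracle on random grids", {
  set.seed(99)
  for (i in 1:60) {
    nr <- sample(3:12, 1); nc <- sample(3:12, 1)
    mask <- matrix(runif(nr * nc) < 0.4, nr, nc)
    for (conn in c(8L, 4L)) {
      mine <- labelComponents(mask, conn)
      oracle <- floodFillLabels(mask, conn)
      expect_equal(max(mine), max(oracle))
      expect_true(samePartition(mine, oracle))
    }
  }
})

test_that("8-connectivity joins diagonal pixels, 4-connectivity does not", {
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(max(labelComponents(m, 8L)), 1L)
  expect_equal(max(labelComponents(m, 4L)), 2L)
})

test_that("detectCells measures a single blob correctly", {
  kymo <- blobKymograph()       # 4 lines x 3 px blob, 0.6 um px, 750 Hz
  ev <- detectCells(kymo, "reporter", 100)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$d_um, 1.8)
  expect_equal(ev$t_ms, 4 / 750 * 1000, tolerance = 1e-12)
  expect_equal(ev$v_um_s, 1.8 / (ev$t_ms / 1000))
  expect_equal(ev$area_px, 12)
  expect_false(ev$truncated)
  expect_equal(ev$mean_intensity_reporter, 200)
  expect_equal(ev$max_intensity_vessel, 3000)
})

test_that("components below the minimum area are discarded", {
  kymo <- blobKymograph()
  px <- kymo@pixels
  px[15, 3, 2] <- 500   # 1-px speck
  kymo2 <- Kymograph(px, scanMetadata(kymo))
  ev <- detectCells(kymo2, "reporter", 100, minAreaPx = 4L)
  expect_equal(nrow(ev), 1L)
  ev2 <- detectCells(kymo2, "reporter", 100, minAreaPx = 1L)
  expect_equal(nrow(ev2), 2L)
})

test_that("a blob touching the temporal boundary is flagged truncated", {
  kymo <- blobKymograph(blobRows = 1:3)
  ev <- detectCells(kymo, "reporter", 100)
  expect_true(ev$truncated)
  expect_equal(ev$line_start, 0)
})

test_that("detectCells rejects unknown channels", {
  expect_error(detectCells(blobKymograph(), "antibody", 100),
               "unknown channel")
})

test_that("vessel diameter is the median lumen run length", {
  # lumen at pixels 11..60 inclusive on every line: 50 px * 0.6 um = 30 um
  md <- ScanMetadata(750, 0.6, 60L, 80L, c("vessel", "reporter"))
  dye <- matrix(100, 60, 80); dye[, 11:60] <- 3000
  kymo <- Kymograph(array(c(dye, matrix(10, 60, 80)), c(60, 80, 2)), md)
  vm <- measureVesselDiameter(kymo)
  expect_equal(vm@DUm, 30)
  expect_equal(diff(vm@pxBounds) * 0.6, vm@DUm)
  expect_equal(vm@linesUsed, 60L)
})

test_that("alternating lumen widths give the median width", {
  md <- ScanMetadata(750, 0.6, 60L, 80L, c("vessel", "reporter"))
  dye <- matrix(100, 60, 80)
  for (i in 1:60) dye[i, 11:(60 + (i %% 2) * 2)] <- 3000  # 50 or 52 px
  kymo <- Kymograph(array(c(dye, matrix(10, 60, 80)), c(60, 80, 2)), md)
  expect_equal(measureVesselDiameter(kymo)@DUm, 51 * 0.6)
})

test_that("an empty dye channel raises vessel-not-found", {
  md <- ScanMetadata(750, 0.6, 20L, 20L, c("vessel", "reporter"))
  kymo <- Kymograph(array(0, c(20, 20, 2)), md)
  expect_error(measureVesselDiameter(kymo), "vessel not found")
})

test_that("vessel diameter ignores bright streaks inside the lumen", {
  md <- ScanMetadata(750, 0.6, 60L, 80L, c("vessel", "reporter"))
  dye <- matrix(100, 60, 80); dye[, 11:60] <- 3000
  base <- Kymograph(array(c(dye, matrix(10, 60, 80)), c(60, 80, 2)), md)
  dye2 <- dye; dye2[20:25, 30:40] <- 5000     # bright streak inside
  withStreak <- Kymograph(array(c(dye2, matrix(10, 60, 80)), c(60, 80, 2)), md)
  expect_equal(measureVesselDiameter(withStreak)@DUm,
               measureVesselDiameter(base)@DUm)
})
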