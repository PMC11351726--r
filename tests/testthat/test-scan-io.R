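test_that("kymograph TIFF write/read round-trips the pixel grid bit-exactly", {
  sim <- simulateRecord(smallParams(seed = 5L, noiseSd = 100))
  tif <- withr::local_tempfile(fileext = ".tif")
  json <- withr::local_tempfile(fileext = ".json")
  writeKymograph(sim$kymograph, tif, json)
  back <- readKymograph(tif, json, channels = c("vessel", "reporter"))
  expect_identical(dim(back@pixels), dim(sim$kymograph@pixels))
  expect_equal(max(abs(back@pixels - sim$kymograph@pixels)), 0)
})

test_that("RGBA composites split into green reporter and magenta vessel", {
  g <- matrix(0L, 30, 24); g[10:14, 5:8] <- 200L        # streak
  r <- matrix(0L, 30, 24); r[, 3:20] <- 120L            # magenta lumen
  b <- matrix(0L, 30, 24); b[, 3:20] <- 90L
  rgba <- array(0, c(30, 24, 4))
  rgba[, , 1] <- r / 255; rgba[, , 2] <- g / 255; rgba[, , 3] <- b / 255
  rgba[, , 4] <- 1
  tif <- withr::local_tempfile(fileext = ".tif")
  suppressWarnings(tiff::writeTIFF(rgba, tif, bits.per.sample = 8L))
  md <- ScanMetadata(750, 0.6, 30L, 24L, c("vessel", "reporter"))
  kymo <- readKymograph(tif, md)
  expect_equal(channelMatrix(kymo, "reporter"), matrix(as.numeric(g), 30, 24))
  expect_equal(channelMatrix(kymo, "vessel"),
               matrix(as.numeric(pmax(r, b)), 30, 24))
})

test_that("position-major input is transposed onto the canonical layout", {
  md <- ScanMetadata(750, 0.6, 40L, 25L, "reporter")
  x <- matrix(sample(0:1000, 1000, replace = TRUE), 40, 25)
  tif <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(t(x) / 65535, tif, bits.per.sample = 16L)  # stored px-major
  kymo <- readKymograph(tif, md, orientation = "transpose")
  expect_equal(channelMatrix(kymo, "reporter"), x)
})

test_that("image/metadata dimension mismatch is a format error", {
  sim <- simulateRecord(smallParams(seed = 6L))
  tif <- withr::local_tempfile(fileext = ".tif")
  writeKymograph(sim$kymograph, tif)
  bad <- scanMetadata(sim$kymograph)
  bad@nPixels <- 300L
  bad@pixelSizeUm <- bad@pixelSizeUm  # keep valid otherwise
  expect_error(readKymograph(tif, bad), "format error")
})

test_that("native JSON metadata resolves verbatim", {
  json <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(scan_rate_hz = 650, pixel_size_um = 0.6,
                            n_lines = 1000, n_pixels = 256,
                            channels = c("vessel", "reporter")),
                       json, auto_unbox = TRUE)
  doc <- parseScanMetadata(json)
  expect_equal(doc@dialect, "native-json")
  md <- doc@resolved
  expect_equal(md@scanRateHz, 650)
  expect_equal(md@pixelSizeUm, 0.6)
  expect_equal(md@nLines, 1000L)
  expect_equal(md@nPixels, 256L)
  expect_equal(md@durationS, 1000 / 650)
})

test_that("PrairieView-style XML resolves scan rate as 1/scanLinePeriod", {
  xml <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    "<PVScan>", "<PVStateShard>",
    '<PVStateValue key="scanLinePeriod" value="0.00133333"/>',
    '<PVStateValue key="micronsPerPixel">',
    '  <IndexedValue index="XAxis" value="0.6"/>',
    "</PVStateValue>",
    '<PVStateValue key="linesPerFrame" value="1000"/>',
    '<PVStateValue key="pixelsPerLine" value="256"/>',
    '<PVStateValue key="laserPower" value="30"/>',
    "</PVStateShard>", "</PVScan>"), xml)
  expect_message(doc <- parseScanMetadata(xml), "laserPower")
  expect_equal(doc@dialect, "prairie-xml")
  expect_equal(doc@resolved@scanRateHz, 750, tolerance = 1e-5)
  expect_equal(doc@resolved@pixelSizeUm, 0.6)
})

test_that("XML without a pixel size is a named metadata error", {
  xml <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<PVScan><PVStateShard>",
               '<PVStateValue key="scanLinePeriod" value="0.0015"/>',
               '<PVStateValue key="linesPerFrame" value="100"/>',
               '<PVStateValue key="pixelsPerLine" value="64"/>',
               "</PVStateShard></PVScan>"), xml)
  expect_error(suppressMessages(parseScanMetadata(xml)),
               "pixel size not found")
})

test_that("event CSV write/read round-trips values", {
  kymo <- blobKymograph()
  ev <- detectCells(kymo, "reporter", 100, minAreaPx = 4L)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeEventsCsv(ev, csv, recordId = "rec1")
  back <- readEventsCsv(csv)
  expect_equal(nrow(back), nrow(ev))
  expect_equal(back$record_id, rep("rec1", nrow(ev)))
  for (col in c("d_um", "t_ms", "v_um_s", "mean_intensity_reporter"))
    expect_equal(back[[col]], ev[[col]], tolerance = 1e-12)
})

test_that("empty event list writes a header-only CSV", {
  kymo <- blobKymograph()
  ev <- detectCells(kymo, "reporter", 1e6)   # nothing above threshold
  csv <- withr::local_tempfile(fileext = ".csv")
  writeEventsCsv(ev, csv)
  back <- readEventsCsv(csv)
  expect_equal(nrow(back), 0L)
  expect_true(all(c("event_id", "d_um", "t_ms", "v_um_s") %in% names(back)))
})

test_that("summary JSON round-trips, including the low-confidence case", {
  md <- ScanMetadata(750, 0.6, 9000L, 64L)
  vessel <- new("VesselMeasurement", DUm = 40, pxBounds = c(5, 55),
                linesUsed = 9000L)
  s <- summarizeRecord(mkEvents(rep(1000, 15)), vessel, md)
  json <- withr::local_tempfile(fileext = ".json")
  writeSummaryJson(s, json)
  back <- readSummaryJson(json)
  expect_equal(back@concentrationPerMl, s@concentrationPerMl,
               tolerance = 1e-12)
  expect_equal(back@VMl, s@VMl, tolerance = 1e-12)
  expect_false(back@lowConfidence)

  s0 <- summarizeRecord(mkEvents(numeric(0)), vessel, md)
  writeSummaryJson(s0, json)
  back0 <- readSummaryJson(json)
  expect_true(back0@lowConfidence)
  expect_equal(back0@concentrationPerMl, 0)
  expect_true(is.na(back0@VMl))
})
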