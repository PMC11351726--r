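# two-color fixtures: reporter-detected events gated on the antibody channel

twoColorParams <- function(seed, ...) {
  smallParams(seed, TS = 30, concentrationPerMl = 1e6, noiseSd = 500,
              twoColor = TRUE, positiveFraction = 0.208, ...)
}

test_that("estimateBackground is exact on a constant background", {
  md <- ScanMetadata(750, 0.6, 50L, 40L, c("vessel", "reporter", "antibody"))
  arr <- array(100, c(50, 40, 3))
  kymo <- Kymograph(arr, md)
  bg <- estimateBackground(kymo, "antibody")
  expect_equal(bg$mean, 100)
  expect_equal(bg$sd, 0)
})

test_that("estimateBackground recovers the simulated noise distribution", {
  sim <- simulateRecord(smallParams(seed = 31L, TS = 20, noiseSd = 50,
                                    twoColor = TRUE))
  r <- analyzeKymograph(sim$kymograph)
  bg <- estimateBackground(sim$kymograph, "antibody", r$events,
                           pxRange = r$vessel@pxBounds)
  expect_equal(bg$mean, 500, tolerance = 0.01)   # declared background level
  expect_equal(bg$sd, 50, tolerance = 0.05)
})

test_that("a mask covering everything is an error", {
  md <- ScanMetadata(750, 0.6, 30L, 20L, c("vessel", "reporter"))
  kymo <- Kymograph(array(5, c(30, 20, 2)), md)
  ev <- data.frame(line_start = 0, line_end = 30, px_start = 0, px_end = 20)
  expect_error(estimateBackground(kymo, "reporter", ev), "background error")
})

test_that("background-kSD gate threshold is mean + k*sd", {
  ev <- mkEvents(rep(1000, 4))
  ev$mean_intensity_antibody <- c(100, 120, 131, 500)
  gr <- gateEvents(ev, GateConfig("antibody", k = 3),
                   list(mean = 100, sd = 10))
  expect_equal(gr@thresholdUsed, 130)
  expect_equal(gr@nPositive, 2L)      # 131 and 500
  expect_equal(gr@fractionPositive, 0.5)
})

test_that("gating is monotone in k", {
  set.seed(5)
  ev <- mkEvents(rep(1000, 50))
  ev$mean_intensity_antibody <- c(rnorm(40, 100, 15), rnorm(10, 300, 15))
  bg <- list(mean = 100, sd = 15)
  nPos <- vapply(seq(0.5, 8, by = 0.5), function(k)
    gateEvents(ev, GateConfig("antibody", k = k), bg)@nPositive, integer(1))
  expect_true(all(diff(nPos) <= 0))
})

test_that("all-negative events give fraction 0 and MFI floored at 0", {
  ev <- mkEvents(rep(1000, 3))
  ev$mean_intensity_antibody <- c(80, 90, 100)
  gr <- gateEvents(ev, GateConfig("antibody", k = 3),
                   list(mean = 100, sd = 10))
  expect_equal(gr@fractionPositive, 0)
  expect_true(is.na(gr@mfiPositive))
  expect_gte(gr@mfiAll, 0)
})

test_that("a missing gated channel is a data error", {
  expect_error(gateEvents(mkEvents(1000), GateConfig("antibody"),
                          list(mean = 0, sd = 1)), "data error")
})

test_that("dotplot rows are component means and quadrants partition events", {
  kymo <- blobKymograph()
  md <- scanMetadata(kymo)
  px <- array(0, c(20, 20, 3))
  px[, , 1:2] <- kymo@pixels
  px[5:8, 10:12, 3] <- 400    # antibody signal on the blob
  md@channelNames <- c("vessel", "reporter", "antibody")
  k3 <- Kymograph(px, md)
  ev <- detectCells(k3, "reporter", 100)
  dp <- dotplotTable(ev)
  expect_equal(nrow(dp), 1L)
  expect_equal(dp$reporter, 200)
  expect_equal(dp$antibody, 400)
  set.seed(8)
  dp2 <- data.frame(event_id = 1:100, reporter = runif(100, 0, 1000),
                    antibody = runif(100, 0, 1000))
  q <- quadrantCounts(dp2, 300, 700)
  expect_equal(sum(q), 100L)
})

test_that("simulated antibody-positive mixture is recovered by gating", {
  # pooled over replicates: fraction near the generating 20.8% and positive
  # MFI near (level - background) at SNR 5
  posTot <- 0L; nTot <- 0L; mfis <- c()
  for (i in 1:6) {
    sim <- simulateRecord(twoColorParams(4000L + i))
    r <- analyzeKymograph(sim$kymograph)
    bg <- estimateBackground(sim$kymograph, "antibody", r$events,
                             pxRange = r$vessel@pxBounds)
    gr <- gateEvents(r$events, GateConfig("antibody"), bg)
    posTot <- posTot + gr@nPositive; nTot <- nTot + gr@nTotal
    mfis <- c(mfis, gr@mfiPositive)
  }
  expect_gt(nTot, 100)
  ci <- stats::binom.test(posTot, nTot, 0.208)$conf.int
  expect_true(ci[1] <= 0.208 && 0.208 <= ci[2])
  expect_equal(mean(mfis), 3000 - 500, tolerance = 0.05)
})

test_that("reporter-negative marker-positive cells are found by the
          secondary lumen pass", {
  sim <- simulateRecord(smallParams(seed = 77L, TS = 30,
                                    concentrationPerMl = 8e5, noiseSd = 100,
                                    twoColor = TRUE, positiveFraction = 0.3,
                                    gfpNegativeFraction = 0.25))
  tr <- truthEvents(sim$truth)
  r <- analyzeKymograph(sim$kymograph)
  st <- fitThreshold(channelMatrix(sim$kymograph, "antibody"))
  ev2 <- detectCellsTwoColor(sim$kymograph,
                             reporterThreshold = r$thresholdUsed,
                             antibodyThreshold = st@baseThreshold,
                             vessel = r$vessel)
  nNegTruth <- sum(!tr$reporter_positive)
  nNegFound <- sum(!ev2$reporter_positive)
  expect_gt(nNegTruth, 0)
  expect_equal(nNegFound, nNegTruth, tolerance = 0.35)
  expect_equal(nrow(ev2), nrow(tr), tolerance = 0.15)
})
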