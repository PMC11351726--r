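#' @import methods
NULL

#' Acquisition parameters of a line-scan record
#'
#' Holds the quantities that convert pixel coordinates to physical units:
#' scan rate (lines per second) converts line indices to time, pixel size
#' converts positions along the scan line to micrometers.
#'
#' @slot scanRateHz lines per second (positive).
#' @slot pixelSizeUm micrometers per pixel along the scan line (positive).
#' @slot nLines number of scan lines in the record.
#' @slot nPixels pixels per scan line.
#' @slot channelNames ordered channel labels, e.g. \code{c("vessel","reporter")}.
#' @slot durationS record duration T in seconds; must equal
#'   \code{nLines/scanRateHz} within one line period.
#'
#' @exportClass ScanMetadata
setClass("ScanMetadata",
  representation(
    scanRateHz  = "numeric",
    pixelSizeUm = "numeric",
    nLines      = "integer",
    nPixels     = "integer",
    channelNames = "character",
    durationS   = "numeric"
  )
)

setValidity("ScanMetadata", function(object) {
  msg <- character()
  if (length(object@scanRateHz) != 1 || !is.finite(object@scanRateHz) ||
      object@scanRateHz <= 0)
    msg <- c(msg, "scanRateHz must be a positive scalar")
  if (length(object@pixelSizeUm) != 1 || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a positive scalar")
  if (length(object@nLines) != 1 || is.na(object@nLines) || object@nLines < 1L)
    msg <- c(msg, "nLines must be >= 1")
  if (length(object@nPixels) != 1 || is.na(object@nPixels) || object@nPixels < 1L)
    msg <- c(msg, "nPixels must be >= 1")
  if (length(object@channelNames) < 1 || anyDuplicated(object@channelNames))
    msg <- c(msg, "channelNames must be non-empty and unique")
  if (length(msg) == 0) {
    # duration must agree with nLines/scanRate within one line period
    linePeriod <- 1 / object@scanRateHz
    if (!is.finite(object@durationS) ||
        abs(object@durationS - object@nLines / object@scanRateHz) > linePeriod)
      msg <- c(msg, "durationS must equal nLines/scanRateHz within one line period")
  }
  if (length(msg)) msg else TRUE
})

#' Construct ScanMetadata
#'
#' @param scanRateHz scan rate in lines per second.
#' @param pixelSizeUm pixel size in micrometers.
#' @param nLines number of scan lines.
#' @param nPixels pixels per line.
#' @param channelNames ordered channel labels.
#' @param durationS record duration in seconds; defaults to
#'   \code{nLines/scanRateHz}.
#' @return A \linkS4class{ScanMetadata} object.
#' @examples
#' ScanMetadata(750, 0.6, 90000L, 96L, c("vessel", "reporter"))
#' @export
ScanMetadata <- function(scanRateHz, pixelSizeUm, nLines, nPixels,
                         channelNames = c("vessel", "reporter"),
                         durationS = nLines / scanRateHz) {
  new("ScanMetadata",
      scanRateHz = as.numeric(scanRateHz),
      pixelSizeUm = as.numeric(pixelSizeUm),
      nLines = as.integer(nLines),
      nPixels = as.integer(nPixels),
      channelNames = as.character(channelNames),
      durationS = as.numeric(durationS))
}

#' Multi-channel line-scan kymograph
#'
#' A pixel grid with one temporal axis (rows: successive scan lines) and one
#' spatial axis (columns: position along the scan line), with one plane per
#' fluorescence channel. Cells crossing the scan line appear as elliptical
#' streaks in the reporter plane; the intravascular dye plane outlines the
#' vessel lumen.
#'
#' @slot pixels numeric array \code{nLines x nPixels x nChannels}, all values
#'   non-negative.
#' @slot metadata a \linkS4class{ScanMetadata}.
#'
#' @exportClass Kymograph
setClass("Kymograph",
  representation(pixels = "array", metadata = "ScanMetadata"))

setValidity("Kymograph", function(object) {
  md <- object@metadata
  d <- dim(object@pixels)
  if (length(d) != 3)
    return("pixels must be a 3-d array (lines x pixels x channels)")
  if (d[1] != md@nLines || d[2] != md@nPixels ||
      d[3] != length(md@channelNames))
    return("pixel array dimensions must match metadata (nLines, nPixels, channels)")
  if (anyNA(object@pixels))
    return("pixel intensities must not contain NA/NaN")
  if (min(object@pixels) < 0)
    return("pixel intensities must be non-negative")
  TRUE
})

#' Construct a Kymograph
#'
#' @param pixels matrix (single channel) or 3-d array of non-negative
#'   intensities, time-major (rows = scan lines).
#' @param metadata a \linkS4class{ScanMetadata} whose dimensions match.
#' @return A \linkS4class{Kymograph}.
#' @export
Kymograph <- function(pixels, metadata) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  storage.mode(pixels) <- "double"
  if (length(dim(pixels)) == 3 &&
      dim(pixels)[3] == length(metadata@channelNames))
    dimnames(pixels) <- list(NULL, NULL, metadata@channelNames)
  new("Kymograph", pixels = pixels, metadata = metadata)
}

#' Vessel lumen measurement
#'
#' @slot DUm lumen diameter in micrometers.
#' @slot pxBounds half-open pixel range (0-based) of the lumen along the
#'   scan line.
#' @slot linesUsed number of scan lines with a detectable lumen run.
#' @exportClass VesselMeasurement
setClass("VesselMeasurement",
  representation(DUm = "numeric", pxBounds = "numeric", linesUsed = "integer"))

setValidity("VesselMeasurement", function(object) {
  if (length(object@DUm) != 1 || !is.finite(object@DUm) || object@DUm <= 0)
    return("DUm must be a positive scalar")
  if (length(object@pxBounds) != 2 || object@pxBounds[2] <= object@pxBounds[1])
    return("pxBounds must be an increasing half-open range")
  TRUE
})

#' Fitted threshold state for streak segmentation
#'
#' The threshold is fitted once on the first record of a session and then
#' rescaled to each later record's overall brightness.
#'
#' @slot baseThreshold intensity threshold fitted on the reference record.
#' @slot baseBrightness reference brightness statistic (median intensity) of
#'   the fitting record.
#' @slot scaleBounds clip factors (low, high) for the brightness rescaling,
#'   with low <= 1 <= high.
#' @exportClass ThresholdState
setClass("ThresholdState",
  representation(baseThreshold = "numeric", baseBrightness = "numeric",
                 scaleBounds = "numeric"))

setValidity("ThresholdState", function(object) {
  if (length(object@scaleBounds) != 2 ||
      object@scaleBounds[1] > 1 || object@scaleBounds[2] < 1)
    return("scaleBounds must satisfy low <= 1 <= high")
  TRUE
})

#' Per-record summary of an IVFC measurement
#'
#' Aggregates detected events into the record-level quantities n, ave(v), D,
#' T, the sampled blood volume V = pi*(D/2)^2*ave(v)*T and the circulating
#' concentration n/V.
#'
#' @slot nCells event count n.
#' @slot aveVUmS arithmetic mean of per-event velocities (um/s); NA when no
#'   usable event velocity exists.
#' @slot DUm vessel lumen diameter (um).
#' @slot TS total scanning time (s).
#' @slot VMl sampled blood volume (mL); NA when ave(v) is undefined.
#' @slot concentrationPerMl n/V (cells/mL); 0 when n = 0.
#' @slot lowConfidence TRUE when the record had no usable events.
#' @exportClass RecordSummary
setClass("RecordSummary",
  representation(nCells = "integer", aveVUmS = "numeric", DUm = "numeric",
                 TS = "numeric", VMl = "numeric",
                 concentrationPerMl = "numeric", lowConfidence = "logical"))

setValidity("RecordSummary", function(object) {
  if (object@nCells < 0L) return("nCells must be >= 0")
  if (!is.na(object@concentrationPerMl) && object@concentrationPerMl < 0)
    return("concentration must be >= 0")
  TRUE
})

#' Parameters of the synthetic kymograph generator
#'
#' Defaults follow typical intravital line-scan measurements of circulating
#' myeloid reporter cells: 40-um vessel, 750 lines/s, 120-s record, cell
#' diameter ~N(6.6, 1.4) um, velocity ~N(1063, 357) um/s (both truncated at
#' 0), baseline concentration 1.3e5 cells/mL.
#'
#' @exportClass SimulationParams
setClass("SimulationParams",
  representation(
    seed = "integer",
    DUm = "numeric", TS = "numeric", scanRateHz = "numeric",
    pixelSizeUm = "numeric", nPixels = "integer",
    concentrationPerMl = "numeric",
    vMeanUmS = "numeric", vSdUmS = "numeric",
    dMeanUm = "numeric", dSdUm = "numeric",
    backgroundLevel = "numeric", dyeLevel = "numeric",
    reporterLevel = "numeric", antibodyLevel = "numeric",
    noiseSd = "numeric",
    positiveFraction = "numeric", gfpNegativeFraction = "numeric",
    twoColor = "logical"))

setValidity("SimulationParams", function(object) {
  msg <- character()
  pos <- c(DUm = object@DUm, TS = object@TS, scanRateHz = object@scanRateHz,
           pixelSizeUm = object@pixelSizeUm,
           vMeanUmS = object@vMeanUmS, dMeanUm = object@dMeanUm)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) msg <- c(msg, paste("must be positive:", paste(bad, collapse = ", ")))
  if (object@concentrationPerMl < 0) msg <- c(msg, "concentration must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@positiveFraction < 0 || object@positiveFraction > 1)
    msg <- c(msg, "positiveFraction must be in [0, 1]")
  if (object@gfpNegativeFraction < 0 || object@gfpNegativeFraction > 1)
    msg <- c(msg, "gfpNegativeFraction must be in [0, 1]")
  if (length(msg) == 0 &&
      object@DUm / object@pixelSizeUm > object@nPixels)
    msg <- c(msg, "geometry error: vessel lumen wider than the scan line")
  if (length(msg)) msg else TRUE
})

#' Ground truth emitted by the simulator
#'
#' @slot params the generating \linkS4class{SimulationParams}.
#' @slot events data.frame of true events visible in the record (arrival
#'   time, lane, d, v, t, channel class flags, analytic bounding box,
#'   truncation flag).
#' @slot expectedRate expected event rate lambda =
#'   C * pi*(D/2)^2 * mean(v) * 1e-12 per second.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(params = "SimulationParams", events = "data.frame",
                 expectedRate = "numeric"))

#' Time course of per-record summaries
#'
#' @slot points data.frame with one row per (subject, time): subject_id,
#'   group, time_min and the RecordSummary fields.
#' @slot scheduleMin declared measurement times (minutes).
#' @slot groups group labels present.
#' @exportClass TimeCourse
setClass("TimeCourse",
  representation(points = "data.frame", scheduleMin = "numeric",
                 groups = "character"))

setValidity("TimeCourse", function(object) {
  p <- object@points
  need <- c("subject_id", "group", "time_min", "concentration_per_ml")
  if (!all(need %in% names(p)))
    return(paste("points must contain columns:", paste(need, collapse = ", ")))
  if (!all(p$time_min %in% object@scheduleMin))
    return("every time_min must be in the declared schedule")
  if (anyDuplicated(p[, c("subject_id", "time_min")]))
    return("duplicate (subject, time) point")
  if (any(p$concentration_per_ml < 0, na.rm = TRUE))
    return("concentrations must be >= 0")
  TRUE
})

#' Two-color gate configuration
#'
#' @slot channelName channel gated on (e.g. the antibody channel).
#' @slot mode "background-kSD" (threshold = background mean + k*sd) or
#'   "fixed" (explicit intensity threshold).
#' @slot k SD multiplier for background-kSD mode.
#' @slot fixedThreshold intensity threshold for fixed mode.
#' @exportClass GateConfig
setClass("GateConfig",
  representation(channelName = "character", mode = "character",
                 k = "numeric", fixedThreshold = "numeric"))

setValidity("GateConfig", function(object) {
  if (!object@mode %in% c("background-kSD", "fixed"))
    return("mode must be 'background-kSD' or 'fixed'")
  if (object@mode == "background-kSD" && (length(object@k) != 1 || object@k <= 0))
    return("k must be a positive scalar")
  if (object@mode == "fixed" && length(object@fixedThreshold) != 1)
    return("fixed mode requires a fixedThreshold")
  TRUE
})

#' Construct a GateConfig
#' @param channelName channel to gate on.
#' @param mode "background-kSD" or "fixed".
#' @param k SD multiplier (background-kSD mode).
#' @param fixedThreshold explicit threshold (fixed mode).
#' @return A \linkS4class{GateConfig}.
#' @export
GateConfig <- function(channelName, mode = c("background-kSD", "fixed"),
                       k = 3, fixedThreshold = NA_real_) {
  mode <- match.arg(mode)
  new("GateConfig", channelName = channelName, mode = mode,
      k = as.numeric(k), fixedThreshold = as.numeric(fixedThreshold))
}

#' Result of gating events on a marker channel
#'
#' @slot nTotal number of events considered.
#' @slot nPositive number above the gate.
#' @slot fractionPositive nPositive/nTotal.
#' @slot mfiPositive background-subtracted mean event intensity of the
#'   positive population (floored at 0); NA when none are positive.
#' @slot mfiAll background-subtracted mean event intensity over all events.
#' @slot thresholdUsed the intensity threshold applied.
#' @exportClass GateResult
setClass("GateResult",
  representation(nTotal = "integer", nPositive = "integer",
                 fractionPositive = "numeric", mfiPositive = "numeric",
                 mfiAll = "numeric", thresholdUsed = "numeric"))

setValidity("GateResult", function(object) {
  if (object@nPositive > object@nTotal)
    return("nPositive must be <= nTotal")
  if (!is.nan(object@fractionPositive) &&
      (object@fractionPositive < 0 || object@fractionPositive > 1))
    return("fractionPositive must be in [0, 1]")
  TRUE
})

#' Correlation and simple-regression report
#'
#' @slot r Pearson correlation coefficient.
#' @slot n number of observations.
#' @slot slope,intercept least-squares fit of y on x.
#' @slot F F-statistic of the slope with (1, n-2) df.
#' @slot pR,pF two-sided p-values for r and for the slope F-test (equal in
#'   simple regression).
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  representation(r = "numeric", n = "integer", slope = "numeric",
                 intercept = "numeric", F = "numeric", pR = "numeric",
                 pF = "numeric"))

setValidity("CorrelationResult", function(object) {
  if (abs(object@r) > 1 + 1e-12) return("r must lie in [-1, 1]")
  if (object@F < 0) return("F must be >= 0")
  TRUE
})

#' Resolved scan-metadata document
#'
#' @slot sourcePath path the metadata was read from.
#' @slot dialect "native-json" or "prairie-xml".
#' @slot raw raw key-value pairs as parsed.
#' @slot resolved the resolved \linkS4class{ScanMetadata}.
#' @exportClass MetadataDocument
setClass("MetadataDocument",
  representation(sourcePath = "character", dialect = "character",
                 raw = "list", resolved = "ScanMetadata"))
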