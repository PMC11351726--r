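#' Access the scan metadata of an object
#' @param x an object carrying a \linkS4class{ScanMetadata}.
#' @return The \linkS4class{ScanMetadata}.
#' @export
setGeneric("scanMetadata", function(x) standardGeneric("scanMetadata"))

#' Extract one channel of a kymograph as a matrix
#' @param x a \linkS4class{Kymograph}.
#' @param channel channel name or index.
#' @return Numeric matrix (nLines x nPixels).
#' @export
setGeneric("channelMatrix", function(x, channel) standardGeneric("channelMatrix"))

#' Vessel lumen diameter in micrometers
#' @param x an object with a vessel diameter.
#' @return Numeric scalar (um).
#' @export
setGeneric("vesselDiameter", function(x) standardGeneric("vesselDiameter"))

#' Circulating-cell concentration in cells/mL
#' @param x an object carrying a concentration.
#' @return Numeric scalar (cells/mL).
#' @export
setGeneric("concentration", function(x) standardGeneric("concentration"))

#' Ground-truth event table
#' @param x a \linkS4class{GroundTruth}.
#' @return data.frame of true events.
#' @export
setGeneric("truthEvents", function(x) standardGeneric("truthEvents"))

setMethod("scanMetadata", "Kymograph", function(x) x@metadata)

setMethod("channelMatrix", "Kymograph", function(x, channel) {
  if (is.character(channel)) {
    i <- match(channel, x@metadata@channelNames)
    if (is.na(i))
      stop("unknown channel '", channel, "'; available: ",
           paste(x@metadata@channelNames, collapse = ", "))
  } else i <- as.integer(channel)
  x@pixels[, , i, drop = TRUE]
})

setMethod("vesselDiameter", "VesselMeasurement", function(x) x@DUm)
setMethod("vesselDiameter", "RecordSummary", function(x) x@DUm)
setMethod("concentration", "RecordSummary", function(x) x@concentrationPerMl)
setMethod("truthEvents", "GroundTruth", function(x) x@events)

setMethod("show", "ScanMetadata", function(object) {
  cat("ScanMetadata:", object@nLines, "lines x", object@nPixels, "px,",
      object@scanRateHz, "Hz,", object@pixelSizeUm, "um/px, T =",
      signif(object@durationS, 6), "s\n")
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
})

setMethod("show", "Kymograph", function(object) {
  md <- object@metadata
  cat("Kymograph:", md@nLines, "lines x", md@nPixels, "px x",
      length(md@channelNames), "channels (",
      paste(md@channelNames, collapse = ", "), ")\n")
  cat("  scan rate", md@scanRateHz, "Hz; pixel", md@pixelSizeUm,
      "um; duration", signif(md@durationS, 6), "s\n")
  cat("  intensity range [", min(object@pixels), ",", max(object@pixels), "]\n")
})

setMethod("show", "VesselMeasurement", function(object) {
  cat("VesselMeasurement: D =", signif(object@DUm, 6), "um; lumen px [",
      object@pxBounds[1], ",", object@pxBounds[2], "); lines used:",
      object@linesUsed, "\n")
})

setMethod("show", "RecordSummary", function(object) {
  cat("RecordSummary: n =", object@nCells,
      "| ave(v) =", signif(object@aveVUmS, 6), "um/s",
      "| D =", signif(object@DUm, 6), "um",
      "| T =", object@TS, "s\n")
  cat("  V =", signif(object@VMl, 6), "mL | concentration =",
      signif(object@concentrationPerMl, 6), "cells/mL",
      if (object@lowConfidence) "(low confidence)" else "", "\n")
})

setMethod("show", "GateResult", function(object) {
  cat("GateResult:", object@nPositive, "/", object@nTotal, "positive (",
      signif(100 * object@fractionPositive, 4), "% ) at threshold",
      signif(object@thresholdUsed, 6), "\n")
  cat("  MFI(positive) =", signif(object@mfiPositive, 6),
      "| MFI(all) =", signif(object@mfiAll, 6), "\n")
})

setMethod("show", "CorrelationResult", function(object) {
  cat("CorrelationResult: r =", signif(object@r, 4), "(p =",
      signif(object@pR, 4), "), n =", object@n, "\n")
  cat("  slope =", signif(object@slope, 6), ", intercept =",
      signif(object@intercept, 6), "; F(1,", object@n - 2L, ") =",
      signif(object@F, 6), "(p =", signif(object@pF, 4), ")\n")
})

setMethod("show", "TimeCourse", function(object) {
  cat("TimeCourse:", nrow(object@points), "points;",
      length(object@scheduleMin), "timepoints; groups:",
      paste(object@groups, collapse = ", "), "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@events), "events; expected rate",
      signif(object@expectedRate, 6), "events/s\n")
})
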