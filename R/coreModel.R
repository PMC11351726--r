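# Closed-form estimators: v = d/t, sampled blood volume, concentration.
# Unit conventions: lengths in um, times per argument name, volumes internal
# um^3 reported in mL with the fixed factor 1e12 um^3/mL.

.UM3_PER_ML <- 1e12

#' Cell velocity from streak extents
#'
#' A round cell traversing the scan line covers a distance approximately
#' equal to its own diameter, so its velocity is v = d / t.
#'
#' @param dUm cell diameter (spatial streak extent), micrometers. Vectorized.
#' @param tMs traverse time (temporal streak extent), milliseconds.
#' @return Velocity in micrometers per second.
#' @examples
#' cellVelocity(10, 10)   # 1000 um/s
#' @export
cellVelocity <- function(dUm, tMs) {
  if (length(dUm) != length(tMs))
    stop("invalid measurement: d and t must have equal length")
  if (length(dUm) == 0) return(numeric(0))
  if (any(!is.finite(dUm)) || any(!is.finite(tMs)) ||
      any(dUm <= 0) || any(tMs <= 0))
    stop("invalid measurement: d (um) and t (ms) must be positive and finite")
  dUm / (tMs / 1000)
}

#' Sampled blood volume of a line-scan record
#'
#' The blood volume that crossed the scan line during the record:
#' V = pi * (D/2)^2 * ave(v) * T, converted from um^3 to mL.
#'
#' @param DUm vessel lumen diameter, micrometers.
#' @param aveVUmS mean cell velocity over the record, um/s.
#' @param TS total scanning time, seconds.
#' @return Volume in mL (1 mL = 1e12 um^3).
#' @examples
#' sampledBloodVolume(40, 1000, 120)  # 1.50796e-4 mL
#' @export
sampledBloodVolume <- function(DUm, aveVUmS, TS) {
  vals <- c(DUm, aveVUmS, TS)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid measurement: D, ave(v) and T must be positive and finite")
  pi * (DUm / 2)^2 * aveVUmS * TS / .UM3_PER_ML
}

#' Circulating-cell concentration
#'
#' Concentration = n / V, the event count divided by the sampled blood
#' volume.
#'
#' @param n number of detected cells (>= 0).
#' @param VMl sampled blood volume in mL (> 0).
#' @return Concentration in cells/mL.
#' @examples
#' cellConcentration(15, sampledBloodVolume(40, 1000, 120))  # ~9.947e4
#' @export
cellConcentration <- function(n, VMl) {
  if (!is.finite(n) || n < 0)
    stop("invalid measurement: n must be a non-negative count")
  if (!is.finite(VMl) || VMl <= 0)
    stop("invalid measurement: V must be positive")
  n / VMl
}

#' Convert pixel extents to micrometers
#'
#' A k-pixel extent has physical length k * pixelSize (count convention: a
#' 1-pixel object has nonzero size).
#'
#' @param nPx extent in pixels.
#' @param metadata a \linkS4class{ScanMetadata}.
#' @return Length in micrometers.
#' @export
pxToUm <- function(nPx, metadata) nPx * metadata@pixelSizeUm

#' Convert micrometers to pixels
#' @param um length in micrometers.
#' @param metadata a \linkS4class{ScanMetadata}.
#' @return Extent in pixels.
#' @export
umToPx <- function(um, metadata) um / metadata@pixelSizeUm

#' Convert line extents to milliseconds
#' @param nLines extent in scan lines.
#' @param metadata a \linkS4class{ScanMetadata}.
#' @return Duration in milliseconds.
#' @export
linesToMs <- function(nLines, metadata) nLines / metadata@scanRateHz * 1000

#' Convert milliseconds to scan lines
#' @param ms duration in milliseconds.
#' @param metadata a \linkS4class{ScanMetadata}.
#' @return Extent in scan lines.
#' @export
msToLines <- function(ms, metadata) ms / 1000 * metadata@scanRateHz
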