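# Two-color IVFC: background statistics on non-cell lumen pixels, k*SD
# gating of events on a marker (antibody) channel, percent-positive, MFI,
# and dot-plot / quadrant tables.

#' Background statistics of a channel outside detected cells
#'
#' Mean and SD over pixels that are not covered by any detected event
#' (bounding boxes expanded by \code{pad}), optionally restricted to the
#' vessel lumen columns.
#'
#' @param kymo a \linkS4class{Kymograph}.
#' @param channel channel name.
#' @param events events data.frame whose footprints are excluded.
#' @param pxRange optional half-open 0-based pixel range (e.g. the lumen
#'   bounds from \code{\link{measureVesselDiameter}}).
#' @param pad bounding-box expansion in pixels/lines.
#' @return list(mean, sd, nPixels).
#' @export
estimateBackground <- function(kymo, channel, events = NULL, pxRange = NULL,
                               pad = 2L) {
  ch <- channelMatrix(kymo, channel)
  nr <- nrow(ch); np <- ncol(ch)
  include <- matrix(TRUE, nr, np)
  if (!is.null(pxRange)) {
    cols <- seq_len(np)
    include[, cols <= pxRange[1] | cols > pxRange[2]] <- FALSE
  }
  if (!is.null(events) && nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      r0 <- max(1L, events$line_start[i] + 1L - pad)
      r1 <- min(nr, events$line_end[i] + pad)
      c0 <- max(1L, events$px_start[i] + 1L - pad)
      c1 <- min(np, events$px_end[i] + pad)
      include[r0:r1, c0:c1] <- FALSE
    }
  }
  vals <- ch[include]
  if (length(vals) < 2)
    stop("background error: no non-cell pixels left to estimate background")
  list(mean = mean(vals), sd = stats::sd(vals), nPixels = length(vals))
}

#' Gate events on a marker channel
#'
#' An event is positive when its mean intensity on the gated channel exceeds
#' the threshold: background mean + k*SD in background-kSD mode, or an
#' explicit intensity in fixed mode. MFI is the background-subtracted mean
#' event intensity, floored at 0, reported both over the positive population
#' and over all events.
#'
#' @param events events data.frame carrying
#'   \code{mean_intensity_<channel>} columns.
#' @param gate a \linkS4class{GateConfig}.
#' @param background list(mean, sd) from \code{\link{estimateBackground}}
#'   (required for background-kSD mode and for MFI).
#' @return A \linkS4class{GateResult}.
#' @export
gateEvents <- function(events, gate, background = NULL) {
  col <- paste0("mean_intensity_", gate@channelName)
  if (!col %in% names(events))
    stop("data error: events carry no intensity for channel '",
         gate@channelName, "'")
  thr <- if (gate@mode == "fixed") gate@fixedThreshold
         else {
           if (is.null(background))
             stop("data error: background statistics required for background-kSD gating")
           background$mean + gate@k * background$sd
         }
  mi <- events[[col]]
  pos <- mi > thr
  bgMean <- if (is.null(background)) 0 else background$mean
  nTot <- length(mi)
  nPos <- sum(pos)
  mfiAll <- if (nTot > 0) max(0, mean(mi - bgMean)) else NA_real_
  mfiPos <- if (nPos > 0) max(0, mean(mi[pos] - bgMean)) else NA_real_
  new("GateResult", nTotal = as.integer(nTot), nPositive = as.integer(nPos),
      fractionPositive = if (nTot > 0) nPos / nTot else NaN,
      mfiPositive = mfiPos, mfiAll = mfiAll, thresholdUsed = thr)
}

#' Per-event two-channel intensity table for dot plots
#'
#' @param events events data.frame.
#' @param reporterChannel,antibodyChannel channel names.
#' @return data.frame(event_id, reporter, antibody) of mean event
#'   intensities, suitable for quadrant counting.
#' @export
dotplotTable <- function(events, reporterChannel = "reporter",
                         antibodyChannel = "antibody") {
  rc <- paste0("mean_intensity_", reporterChannel)
  ac <- paste0("mean_intensity_", antibodyChannel)
  if (!all(c(rc, ac) %in% names(events)))
    stop("data error: events lack intensities for both channels")
  data.frame(event_id = events$event_id,
             reporter = events[[rc]], antibody = events[[ac]])
}

#' Quadrant counts of a dot-plot table
#'
#' @param dotplot data.frame from \code{\link{dotplotTable}}.
#' @param reporterThreshold,antibodyThreshold gate thresholds.
#' @return Named integer vector over the four quadrants; sums to the number
#'   of events.
#' @export
quadrantCounts <- function(dotplot, reporterThreshold, antibodyThreshold) {
  rp <- dotplot$reporter > reporterThreshold
  ap <- dotplot$antibody > antibodyThreshold
  c("reporter+marker-" = sum(rp & !ap),
    "reporter+marker+" = sum(rp & ap),
    "reporter-marker+" = sum(!rp & ap),
    "reporter-marker-" = sum(!rp & !ap))
}

#' Two-color event detection (reporter primary, antibody secondary)
#'
#' Detection runs on the reporter channel; the antibody channel contributes
#' intensities only. Reporter-negative marker-positive cells (which carry no
#' reporter signal) are recovered by a secondary detection pass on the
#' antibody channel restricted to the vessel lumen, keeping only components
#' that do not overlap a reporter event; these rows are flagged
#' \code{reporter_positive = FALSE}.
#'
#' @param kymo a \linkS4class{Kymograph}.
#' @param reporterThreshold,antibodyThreshold intensity thresholds for the
#'   two passes.
#' @param vessel a \linkS4class{VesselMeasurement} (restricts the secondary
#'   pass to the lumen); NULL skips the secondary pass.
#' @param reporterChannel,antibodyChannel channel names.
#' @param minAreaPx,connectivity as in \code{\link{detectCells}}.
#' @return events data.frame with an extra \code{reporter_positive} column.
#' @export
detectCellsTwoColor <- function(kymo, reporterThreshold, antibodyThreshold,
                                vessel = NULL,
                                reporterChannel = "reporter",
                                antibodyChannel = "antibody",
                                minAreaPx = 4L, connectivity = 8L) {
  prim <- detectCells(kymo, reporterChannel, reporterThreshold,
                      minAreaPx = minAreaPx, connectivity = connectivity)
  prim$reporter_positive <- rep(TRUE, nrow(prim))
  if (is.null(vessel)) return(prim)
  sec <- detectCells(kymo, antibodyChannel, antibodyThreshold,
                     minAreaPx = minAreaPx, connectivity = connectivity,
                     restrictPx = vessel@pxBounds)
  if (nrow(sec) > 0 && nrow(prim) > 0) {
    overlaps <- vapply(seq_len(nrow(sec)), function(i) {
      any(sec$line_start[i] < prim$line_end &
          sec$line_end[i] > prim$line_start &
          sec$px_start[i] < prim$px_end &
          sec$px_end[i] > prim$px_start)
    }, logical(1))
    sec <- sec[!overlaps, , drop = FALSE]
  }
  if (nrow(sec) == 0) return(prim)
  sec$reporter_positive <- FALSE
  out <- rbind(prim, sec)
  out <- out[order(out$line_start, out$px_start), , drop = FALSE]
  out$event_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write a gate result as JSON
#' @param result a \linkS4class{GateResult}.
#' @param path output path.
#' @param extra named list of extra fields to embed.
#' @return \code{path}, invisibly.
#' @export
writeGateResultJson <- function(result, path, extra = list()) {
  out <- c(list(
    n_total = result@nTotal, n_positive = result@nPositive,
    fraction_positive = result@fractionPositive,
    mfi_positive = result@mfiPositive, mfi_all = result@mfiAll,
    threshold_used = result@thresholdUsed
  ), extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
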