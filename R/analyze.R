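# One-record pipeline: vessel measurement + threshold + detection + summary.

#' Analyze one kymograph record end-to-end
#'
#' Measures the vessel lumen on the dye channel, thresholds the reporter
#' channel (fitting a new \linkS4class{ThresholdState} or brightness-adapting
#' a previously fitted one), detects cell streaks, and summarizes the record
#' into n, ave(v), D, T, V and concentration.
#'
#' @param kymo a \linkS4class{Kymograph}.
#' @param state a fitted \linkS4class{ThresholdState} from an earlier record,
#'   or NULL to fit on this record.
#' @param reporterChannel,vesselChannel channel names.
#' @param minAreaPx minimum streak area in pixels.
#' @param kFloor background-floor multiplier for threshold fitting.
#' @param connectivity component connectivity (8 or 4).
#' @param countTruncated count boundary-truncated events in n.
#' @return list(events, vessel, summary, thresholdState, thresholdUsed).
#' @examples
#' sim <- simulateRecord(simulationParams(seed = 7, TS = 10))
#' res <- analyzeKymograph(sim$kymograph)
#' res$summary
#' @export
analyzeKymograph <- function(kymo, state = NULL,
                             reporterChannel = "reporter",
                             vesselChannel = "vessel",
                             minAreaPx = 4L, kFloor = 4,
                             connectivity = 8L, countTruncated = TRUE) {
  vessel <- measureVesselDiameter(kymo, vesselChannel)
  chan <- channelMatrix(kymo, reporterChannel)
  if (is.null(state)) {
    state <- fitThreshold(chan, kFloor = kFloor)
    thr <- state@baseThreshold
  } else {
    thr <- adaptThreshold(state, chan)
  }
  events <- detectCells(kymo, reporterChannel, thr, minAreaPx = minAreaPx,
                        connectivity = connectivity, channelData = chan)
  summary <- summarizeRecord(events, vessel, kymo@metadata,
                             countTruncated = countTruncated)
  list(events = events, vessel = vessel, summary = summary,
       thresholdState = state, thresholdUsed = thr)
}
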